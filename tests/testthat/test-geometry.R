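test_that("free-edge height is affine in SSL with the printed constants", {
  expect_identical(free_edge_height(19.1), 13.3)
  # independent hand arithmetic: 13.3 + 9.6 * (ssl - 19.1)
  expect_equal(free_edge_height(18.4), 6.58, tolerance = 1e-12)
  expect_equal(free_edge_height(20.1), 22.9, tolerance = 1e-12)
})

test_that("attachment curve is the even exponential scallop", {
  expect_equal(attachment_y(0, 4.57), 4.57)
  x <- c(0.3, 1.1, 2.9)
  expect_equal(attachment_y(x, 5.1), attachment_y(-x, 5.1))
  # frozen high-precision evaluation of 4.57 * exp(0.1053 * 1^2)
  expect_equal(attachment_y(1, 4.57), 5.077470502012851, tolerance = 1e-14)
})

test_that("free-edge curve honors its boundary identities and domain", {
  m <- 10.9
  for (h in c(6.58, 13.3, 22.9)) {
    expect_equal(free_edge_y(0, h), 0)
    expect_equal(free_edge_y(m, h), h)
    expect_equal(free_edge_y(-m, h), h)
  }
  # monotone non-decreasing in |x| on [0, m]
  xs <- seq(0, m, length.out = 200)
  expect_true(all(diff(free_edge_y(xs, 13.3)) >= 0))
  # frozen arbitrary-precision oracle at x = 0.99 m, h = 13.3 (the exponents
  # are ~ -38, far below double-precision visibility of the naive form)
  expect_equal(free_edge_y(0.99 * m, 13.3), 2.6260194804015728e-16,
               tolerance = 1e-10)
  expect_error(free_edge_y(11.0, 13.3), "<= m")
})

test_that("half-width solve conserves the suturing-line arc length", {
  for (p in list(c(5.0, 19.0), c(4.57, 18.4), c(6.35, 20.1))) {
    xmax <- solve_half_width(p[1], p[2])
    expect_equal(tavsurrogate:::attachment_arclength(xmax, p[1]), p[2],
                 tolerance = 1e-8)
  }
  # monotone: longer ssl at fixed a widens the leaflet
  expect_gt(solve_half_width(5.0, 20.0), solve_half_width(5.0, 18.5))
  # brute-force arc-length tabulation oracle
  a <- 5.0; ssl <- 19.0
  xg <- seq(1e-4, 4, length.out = 40000)
  arc <- 2 * cumsum(sqrt(1 + (a * 2 * 0.1053 * xg * exp(0.1053 * xg^2))^2)) *
    (xg[2] - xg[1])
  brute <- xg[which.min(abs(arc - ssl))]
  expect_equal(solve_half_width(a, ssl), brute, tolerance = 1e-3)
})

test_that("contours are symmetric, closed, and arc-length exact", {
  d <- design_params(5.2, 3.1, 19.3)
  ct <- build_contour(d)
  ap <- ct$attachment_points; fp <- ct$free_edge_points
  # symmetry under x -> -x
  expect_equal(ap[, "y"], rev(ap[, "y"]), tolerance = 1e-12)
  expect_equal(fp[, "y"], rev(fp[, "y"]), tolerance = 1e-12)
  # edges meet at +/- half_width
  expect_equal(ap[1, ], fp[1, ], tolerance = 1e-9)
  expect_equal(ap[nrow(ap), ], fp[nrow(fp), ], tolerance = 1e-9)
  # attachment arc length equals ssl
  expect_equal(tavsurrogate:::attachment_arclength(ct$half_width, 5.2), 19.3,
               tolerance = 1e-6 * 19.3)
  # ssl is the only driver of width: same a, different ssl
  ct2 <- build_contour(design_params(5.2, 3.1, 19.9))
  expect_gt(ct2$half_width, ct$half_width)
})

test_that("the transfinite mesh hits the exact node count deterministically", {
  ct <- build_contour(design_params(5.0, 3.2, 19.1))
  msh <- mesh_leaflet(ct, 1381L)
  expect_equal(nrow(msh$nodes), 1381L)
  expect_equal(msh$nu, 199L)
  expect_equal(msh$nv, 7L)
  msh2 <- mesh_leaflet(ct, 1381L)
  expect_identical(msh$nodes, msh2$nodes)
  expect_identical(msh$triangles, msh2$triangles)
  # no degenerate triangles, consistent orientation
  areas <- tavsurrogate:::triangle_areas(msh$nodes, msh$triangles)
  expect_true(all(areas > 0))
  # total mesh area equals the shoelace area of the boundary polygon
  boundary <- rbind(msh$nodes[msh$attachment_node_ids, ],
                    msh$nodes[rev(msh$free_edge_node_ids[-c(1, length(msh$free_edge_node_ids))]), ])
  n <- nrow(boundary)
  xs <- boundary[, 1]; ys <- boundary[, 2]
  shoelace <- abs(sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys)) / 2
  expect_equal(sum(areas), shoelace, tolerance = 1e-8 * shoelace)
  # boundary node lists lie on the contour curves
  a <- 5.0
  expect_equal(msh$nodes[msh$attachment_node_ids, 2],
               attachment_y(msh$nodes[msh$attachment_node_ids, 1], a),
               tolerance = 1e-9)
  # unrealizable node counts are a config error (1381 - 2 is 7 * 197; a
  # prime-plus-2 count has no admissible grid)
  expect_error(mesh_leaflet(ct, 13L + 2L), "not realizable")
})

test_that("node ordering corresponds across designs", {
  m1 <- mesh_leaflet(build_contour(design_params(4.6, 3.0, 18.5)))
  m2 <- mesh_leaflet(build_contour(design_params(6.3, 3.4, 20.0)))
  expect_identical(m1$triangles, m2$triangles)
  expect_identical(m1$u, m2$u)
  expect_identical(m1$v, m2$v)
  expect_identical(m1$attachment_node_ids, m2$attachment_node_ids)
})

test_that("the 3D suturing line conserves arc length and starts at p", {
  cv <- build_ssl_curve(3.2, 19.1)
  expect_equal(min(cv$z_values), 0.20)  # z at theta = 0
  expect_equal(cv$arc_length, 19.1, tolerance = 1e-6 * 19.1)
  # z strictly increases with |theta|
  n <- length(cv$theta_samples)
  half <- cv$z_values[((n + 1) %/% 2):n]
  expect_true(all(diff(half) > 0))
  # brute-force radius scan with dense quadrature
  b <- 3.2; ssl <- 19.1
  th <- seq(0, pi / 3, length.out = 20000)
  arc_of_R <- function(R) {
    integ <- sqrt(R^2 + (0.2 * b * exp(b * th))^2)
    2 * sum((integ[-1] + integ[-length(th)]) / 2 * diff(th))
  }
  Rs <- seq(5, 7, by = 1e-4)
  brute <- Rs[which.min(abs(vapply(Rs, arc_of_R, 0) - ssl))]
  expect_equal(cv$radius, brute, tolerance = 1e-3)
  # infeasible: ssl shorter than the z-excursion forces a failure
  expect_error(build_ssl_curve(8, 10), "too short|bracket")
})

test_that("2D and 3D suturing-line lengths agree for random designs", {
  sp <- design_space()
  designs <- sample_designs(sp, 20, seed = 5)
  for (i in seq_len(nrow(designs))) {
    d <- designs[i, ]
    xmax <- solve_half_width(d$a, d$ssl)
    len2d <- tavsurrogate:::attachment_arclength(xmax, d$a)
    cv <- build_ssl_curve(d$b, d$ssl)
    expect_equal(len2d, d$ssl, tolerance = 1e-6 * d$ssl)
    expect_equal(cv$arc_length, d$ssl, tolerance = 1e-6 * d$ssl)
  }
})
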
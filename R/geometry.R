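# Parametric 2D leaflet contour, 1381-node transfinite mesh, and the 3D stent
# suturing line. All lengths in mm; all constructions deterministic.

# fixed contour constants
.KA <- 0.1053       # attachment-curve exponent coefficient, mm^-2
.M_FREE <- 10.9     # free-edge curve half-support, mm
.H_NOM <- 13.3      # nominal free-edge height, mm
.SSL_NOM <- 19.1    # nominal suturing-line length, mm
.R_H <- 9.6         # free-edge height sensitivity to SSL, dimensionless
.P_SSL <- 0.20      # SSL curve base height, mm
.THETA_HALF <- pi / 3  # one leaflet spans one third of the stent circumference

#' Free-edge height from suturing-line length
#'
#' The 2D free-edge height parameter h grows affinely with the suturing-line
#' length: `h = hnom + r * (ssl - SSLnom)` with hnom = 13.3 mm,
#' SSLnom = 19.1 mm and r = 9.6.
#'
#' @param ssl suturing-line length, mm.
#' @return height h, mm.
#' @examples
#' free_edge_height(19.1)  # 13.3 at the nominal length
#' @export
free_edge_height <- function(ssl) {
  if (any(!is.finite(ssl))) stop("free_edge_height: ssl must be finite", call. = FALSE)
  .H_NOM + .R_H * (ssl - .SSL_NOM)
}

#' Attachment-edge curve
#'
#' `ya(x) = a * exp(0.1053 * x^2)`; the scallop-shaped attachment (sutured)
#' edge of the flat leaflet, lowest at the center x = 0 and rising steeply
#' toward the commissures.
#'
#' @param x lateral coordinate, mm (vectorized).
#' @param a attachment coefficient, mm.
#' @return y coordinate, mm.
#' @export
attachment_y <- function(x, a) {
  a * exp(.KA * x^2)
}

# d ya / dx, used in arc-length integrands
attachment_dy <- function(x, a) {
  a * 2 * .KA * x * exp(.KA * x^2)
}

#' Free-edge curve
#'
#' `yf(x) = h * (1 - (e^(x^3 - m^3) - 1) / (e^(-m^3) - 1))` with m = 10.9 mm,
#' evaluated in log/expm1 form so the extreme exponents neither overflow nor
#' lose the boundary identities `yf(0) = 0` and `yf(m) = h`. The curve is
#' symmetric (|x| is used) and monotone non-decreasing in |x| on [0, m].
#' Within a typical solved leaflet half-width (about 3.3 mm) the curve is
#' numerically zero: the free edge is flat except in a thin boundary layer
#' near x = m.
#'
#' @param x lateral coordinate, mm; requires |x| <= m.
#' @param h free-edge height, mm (see [free_edge_height()]).
#' @param m half-support of the free-edge curve, mm.
#' @return y coordinate, mm.
#' @export
free_edge_y <- function(x, h, m = .M_FREE) {
  ax <- abs(x)
  if (any(!is.finite(ax)) || any(ax > m + 1e-12)) {
    stop("free_edge_y: requires finite |x| <= m", call. = FALSE)
  }
  ax <- pmin(ax, m)
  d <- ax^3 - m^3  # <= 0
  # 1 - (e^d - 1)/(e^{-m^3} - 1) = 1 - expm1(d)/expm1(-m^3)
  h * (1 - expm1(d) / expm1(-m^3))
}

# Arc length of the attachment curve on [-xmax, xmax] (continuous quadrature).
attachment_arclength <- function(xmax, a, rel.tol = 1e-12) {
  if (xmax <= 0) return(0)
  2 * stats::integrate(function(x) sqrt(1 + attachment_dy(x, a)^2),
                       0, xmax, rel.tol = rel.tol, abs.tol = 0,
                       subdivisions = 400L)$value
}

#' Solve the leaflet half-width from the suturing-line length
#'
#' The flat leaflet's half-width `xmax` is fixed by requiring that the arc
#' length of the attachment curve on `[-xmax, xmax]` equal the design's
#' suturing-line length (the SSL length is conserved between the flat leaflet
#' and the 3D suturing line). The arc length is strictly increasing in
#' `xmax`, so the root is unique; it is bracketed and refined to a relative
#' tolerance of 1e-8.
#'
#' @param a attachment coefficient, mm.
#' @param ssl suturing-line length, mm.
#' @return half-width xmax, mm.
#' @export
solve_half_width <- function(a, ssl) {
  stopifnot(is.finite(a), is.finite(ssl), a > 0, ssl > 0)
  f <- function(x) attachment_arclength(x, a) - ssl
  upper <- 1
  while (f(upper) < 0 && upper < 2 * .M_FREE) upper <- upper * 1.5
  if (f(upper) < 0) {
    stop("solve_half_width: no bracket for the arc-length equation within [0, 2m]",
         call. = FALSE)
  }
  stats::uniroot(f, c(0, upper), tol = 1e-10 * ssl)$root
}

#' Build the 2D leaflet contour for a design
#'
#' The contour is bounded below by the attachment curve and above by the free
#' edge. Because the printed free-edge curve is numerically flat over the
#' solved half-width, the contour's free edge is the commissure-level chord
#' shifted by the (tiny) free-edge curve: both edges meet exactly at
#' `x = +/- xmax`, and the attachment arc length equals the design's `ssl`.
#'
#' @param p one design (named vector or 1-row data frame with `a`, `b`, `ssl`).
#' @param n_points points per edge in the stored polyline.
#' @return An object of class `tav_contour`.
#' @export
build_contour <- function(p, n_points = 201L) {
  p <- as_design_df(p)
  stopifnot(nrow(p) == 1L)
  a <- p$a; ssl <- p$ssl
  h <- free_edge_height(ssl)
  xmax <- solve_half_width(a, ssl)
  x <- seq(-xmax, xmax, length.out = n_points)
  ya <- attachment_y(x, a)
  y_comm <- attachment_y(xmax, a)
  yf <- y_comm + (free_edge_y(x, h) - free_edge_y(xmax, h))
  structure(list(
    design = p,
    half_width = xmax,
    h = h,
    attachment_points = cbind(x = x, y = ya),
    free_edge_points = cbind(x = x, y = yf),
    commissure_y = y_comm
  ), class = "tav_contour")
}

#' @export
print.tav_contour <- function(x, ...) {
  cat(sprintf("TAV leaflet contour: a=%.4g mm, ssl=%.4g mm, half-width=%.6g mm, h=%.4g mm\n",
              x$design$a, x$design$ssl, x$half_width, x$h))
  invisible(x)
}

# contour free-edge curve evaluated at arbitrary x (same construction as
# build_contour's stored polyline)
contour_free_y <- function(contour, x) {
  contour$commissure_y +
    (free_edge_y(x, contour$h) - free_edge_y(contour$half_width, contour$h))
}

# Factor target_nodes = (nu - 2) * nv + 2 with nu u-columns (the two
# commissure corner columns collapse to single nodes) and nv v-rows.
# Picks the most balanced factor pair, wider along u.
mesh_grid_dims <- function(target_nodes) {
  m <- target_nodes - 2L
  if (m < 4L) stop("mesh_leaflet: target_nodes must be >= 6", call. = FALSE)
  divs <- which(m %% seq_len(m) == 0L)
  # admissible row counts: nv >= 2 and nv <= m/nv (rows are the smaller factor)
  cand <- divs[divs >= 2L & divs <= m %/% divs]
  if (length(cand) == 0L) {
    stop("mesh_leaflet: target_nodes - 2 = ", m,
         " has no factorization nv * (nu - 2) with nv >= 2; ",
         "not realizable by the structured grid", call. = FALSE)
  }
  nv <- cand[which.min(abs(cand - sqrt(m)))]
  nu <- m %/% nv + 2L
  list(nu = nu, nv = nv)
}

#' Mesh the leaflet with a fixed-topology transfinite grid
#'
#' A structured transfinite triangulation between the attachment edge (v = 0)
#' and the free edge (v = 1). The two commissure corners, where the edges
#' meet, are single nodes; interior u-columns carry `nv` nodes each, so the
#' node count is `(nu - 2) * nv + 2`. For the default 1381 nodes the grid is
#' 199 u-columns by 7 v-rows (1381 - 2 = 197 * 7). Node indices correspond to
#' fixed parametric positions, so node k refers to the same material point in
#' every design, which makes fields comparable as flat vectors.
#'
#' @param contour a [build_contour()] result.
#' @param target_nodes requested node count; must factor as above.
#' @return An object of class `tav_mesh` with fields `nodes` (N x 2, mm),
#'   `triangles` (M x 3, 1-based), `u`, `v` (per-node parametric coordinates),
#'   `attachment_node_ids`, `free_edge_node_ids`, `commissure_node_ids`.
#' @export
mesh_leaflet <- function(contour, target_nodes = 1381L) {
  stopifnot(inherits(contour, "tav_contour"))
  dims <- mesh_grid_dims(as.integer(target_nodes))
  nu <- dims$nu; nv <- dims$nv
  xmax <- contour$half_width
  a <- contour$design$a
  uu <- seq(0, 1, length.out = nu)
  vv <- seq(0, 1, length.out = nv)
  xcol <- -xmax + uu * 2 * xmax
  ya <- attachment_y(xcol, a)
  yf <- contour_free_y(contour, xcol)

  N <- (nu - 2L) * nv + 2L
  nodes <- matrix(0, N, 2L)
  u_par <- numeric(N); v_par <- numeric(N)
  # index layout: 1 = left commissure; then columns i = 2..nu-1 (each nv
  # nodes, v from 0 to 1); N = right commissure
  idx <- function(i, j) {
    if (i == 1L) return(1L)
    if (i == nu) return(N)
    1L + (i - 2L) * nv + j
  }
  nodes[1L, ] <- c(xcol[1L], ya[1L]); u_par[1L] <- 0; v_par[1L] <- 0.5
  nodes[N, ] <- c(xcol[nu], ya[nu]); u_par[N] <- 1; v_par[N] <- 0.5
  for (i in 2:(nu - 1L)) {
    for (j in seq_len(nv)) {
      k <- idx(i, j)
      v <- vv[j]
      nodes[k, ] <- c(xcol[i], (1 - v) * ya[i] + v * yf[i])
      u_par[k] <- uu[i]; v_par[k] <- v
    }
  }

  tris <- vector("list", 2L * (nu - 1L))
  tcount <- 0L
  add_tri <- function(p, q, r) {
    tcount <<- tcount + 1L
    tris[[tcount]] <<- c(p, q, r)
  }
  # left fan
  for (j in seq_len(nv - 1L)) add_tri(1L, idx(2L, j), idx(2L, j + 1L))
  # interior strips
  for (i in 2:(nu - 2L)) {
    for (j in seq_len(nv - 1L)) {
      p1 <- idx(i, j); p2 <- idx(i + 1L, j)
      p3 <- idx(i + 1L, j + 1L); p4 <- idx(i, j + 1L)
      add_tri(p1, p2, p3)
      add_tri(p1, p3, p4)
    }
  }
  # right fan
  for (j in seq_len(nv - 1L)) add_tri(idx(nu - 1L, j), N, idx(nu - 1L, j + 1L))
  triangles <- do.call(rbind, tris[seq_len(tcount)])

  attachment_ids <- c(1L, vapply(2:(nu - 1L), idx, integer(1), j = 1L), N)
  free_ids <- c(1L, vapply(2:(nu - 1L), idx, integer(1), j = nv), N)
  structure(list(
    nodes = nodes,
    triangles = triangles,
    u = u_par, v = v_par,
    nu = nu, nv = nv,
    attachment_node_ids = attachment_ids,
    free_edge_node_ids = free_ids,
    commissure_node_ids = c(1L, N),
    design = contour$design,
    contour = contour
  ), class = "tav_mesh")
}

#' @export
print.tav_mesh <- function(x, ...) {
  cat(sprintf("TAV leaflet mesh: %d nodes (%d x %d grid, corner columns collapsed), %d triangles\n",
              nrow(x$nodes), x$nu, x$nv, nrow(x$triangles)))
  invisible(x)
}

# signed triangle areas (positive = counter-clockwise)
triangle_areas <- function(nodes, triangles) {
  p1 <- nodes[triangles[, 1L], , drop = FALSE]
  p2 <- nodes[triangles[, 2L], , drop = FALSE]
  p3 <- nodes[triangles[, 3L], , drop = FALSE]
  0.5 * ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2]))
}

#' Build the 3D stent suturing line for a design
#'
#' In cylindrical coordinates on the stent cylinder the suturing line is
#' `z(theta) = p * exp(b * |theta|)` with p = 0.20 mm, over
#' `theta in [-pi/3, pi/3]` (one of three identical leaflets). The stent
#' radius is the free variable: it is solved so the 3D arc length of the
#' curve equals the design's `ssl` (conservation of suturing-line length
#' between 2D and 3D), to 1e-6 relative.
#'
#' @param b dimensionless shape coefficient.
#' @param ssl suturing-line length, mm.
#' @param n_samples sample count of the stored polyline.
#' @return An object of class `tav_ssl_curve` with `radius` (mm),
#'   `theta_samples`, `z_values`, and the cumulative arc length `s_values`.
#' @export
build_ssl_curve <- function(b, ssl, n_samples = 401L) {
  stopifnot(is.finite(b), is.finite(ssl), ssl > 0)
  zprime <- function(th) .P_SSL * b * exp(b * abs(th))  # |dz/dtheta|
  arclen <- function(R) {
    2 * stats::integrate(function(th) sqrt(R^2 + zprime(th)^2),
                         0, .THETA_HALF, rel.tol = 1e-12, abs.tol = 0,
                         subdivisions = 400L)$value
  }
  upper <- ssl / (2 * .THETA_HALF)  # radius if the curve were flat
  f <- function(R) arclen(R) - ssl
  if (f(upper) < 0) stop("build_ssl_curve: failed to bracket the radius", call. = FALSE)
  if (f(1e-9) > 0) {
    stop("build_ssl_curve: ssl too short for the z-excursion at this b", call. = FALSE)
  }
  R <- stats::uniroot(f, c(1e-9, upper), tol = 1e-10 * ssl)$root
  theta <- seq(-.THETA_HALF, .THETA_HALF, length.out = n_samples)
  z <- .P_SSL * exp(b * abs(theta))
  # cumulative arc length along the stored polyline parameterization
  ds <- sqrt(R^2 + zprime(theta)^2)
  s <- c(0, cumsum((ds[-1] + ds[-n_samples]) / 2 * diff(theta)))
  structure(list(
    b = b, ssl = ssl, p = .P_SSL, radius = R,
    theta_samples = theta, z_values = z, s_values = s,
    arc_length = arclen(R)
  ), class = "tav_ssl_curve")
}

#' @export
print.tav_ssl_curve <- function(x, ...) {
  cat(sprintf("Stent suturing line: b=%.4g, ssl=%.6g mm, radius=%.6g mm, z(0)=%.3g mm\n",
              x$b, x$ssl, x$radius, x$p))
  invisible(x)
}

# Point on the SSL curve at a normalized arc-length fraction f in [0, 1]
# (f = 0 at theta = -pi/3). Returns (x, y, z) on the stent cylinder, with the
# leaflet centered at angular coordinate 0 and the stent axis along z.
ssl_point_at_fraction <- function(curve, f) {
  stot <- curve$s_values[length(curve$s_values)]
  th <- stats::approx(curve$s_values / stot, curve$theta_samples, xout = f,
                      rule = 2)$y
  z <- curve$p * exp(curve$b * abs(th))
  cbind(x = curve$radius * cos(th), y = curve$radius * sin(th), z = z)
}
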
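test_that("circumcircle radius matches closed forms and brute force", {
  # equilateral triangle of side s: R = s / sqrt(3)
  s <- 2.5
  tri <- rbind(c(0, 0, 0), c(s, 0, 0), c(s / 2, s * sqrt(3) / 2, 0))
  expect_equal(circumcircle_radius(tri), s / sqrt(3), tolerance = 1e-12)
  # brute-force circumcenter solve for (1,0,0), (-1,0,0), (0,1,0)
  pts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0))
  expect_equal(circumcircle_radius(pts), 1, tolerance = 1e-12)
  # invariance under rigid rotation + translation
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- t(Rz %*% t(pts)) + matrix(c(3, -2, 5), 3, 3, byrow = TRUE)
  expect_equal(circumcircle_radius(moved), 1, tolerance = 1e-12)
  expect_error(circumcircle_radius(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "collinear")
})

test_that("shape errors reproduce the defining formulas", {
  # 2-node toy: distances 3 and 4 mm, R = 10 mm
  truth <- rbind(c(0, 0, 0), c(1, 1, 1))
  pred <- rbind(c(3, 0, 0), c(1, 5, 1))
  e <- shape_errors(truth, pred, R = 10)
  expect_equal(e$mean_e, 3.5)
  expect_equal(e$n_mean_e, 35)
  expect_equal(e$max_e, 4)
  expect_equal(e$n_max_e, 40)
  # identity
  e0 <- shape_errors(truth, truth, R = 10)
  expect_equal(unlist(e0), c(mean_e = 0, n_mean_e = 0, max_e = 0, n_max_e = 0))
  # rigid translation by d gives MeanE = MaxE = d
  d <- c(0.3, -0.4, 1.2)
  et <- shape_errors(truth, truth + matrix(d, 2, 3, byrow = TRUE), R = 5)
  expect_equal(et$mean_e, sqrt(sum(d^2)), tolerance = 1e-12)
  expect_equal(et$max_e, et$mean_e, tolerance = 1e-12)
  expect_error(shape_errors(truth, pred[1, , drop = FALSE], 10), "equal-sized")
})

test_that("stress errors reproduce the defining formulas", {
  truth <- c(10, -20, 5)
  pred <- c(12, -18, 5)
  e <- stress_errors(truth, pred)
  expect_equal(e$mean_e, 4 / 3, tolerance = 1e-14)
  expect_equal(e$n_mean_e, (4 / 3) / 30 * 100, tolerance = 1e-12)
  expect_equal(e$max_e, 2)
  expect_equal(e$n_max_e, 10)
  # identity
  expect_equal(unlist(stress_errors(truth, truth)),
               c(mean_e = 0, n_mean_e = 0, max_e = 0, n_max_e = 0))
  # sign flip of both fields leaves the peak comparison unchanged
  ef <- stress_errors(-truth, -pred)
  expect_equal(ef$max_e, e$max_e)
  expect_equal(ef$n_max_e, e$n_max_e)
  # constant truth field: NMeanE undefined, flagged
  expect_error(stress_errors(rep(3, 5), 1:5), "constant")
})

test_that("metrics agree with naive brute-force loops on random instances", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    truth <- matrix(rnorm(3 * n), n, 3)
    pred <- truth + matrix(rnorm(3 * n, sd = 0.3), n, 3)
    R <- runif(1, 5, 15)
    a <- shape_errors(truth, pred, R)
    b <- naive_shape_errors(truth, pred, R)
    for (k in names(a)) {
      expect_equal(a[[k]], b[[k]], tolerance = 1e-12)
    }
    st <- rnorm(n, sd = 10)
    sp <- st + rnorm(n)
    if (max(st) > min(st)) {
      a <- stress_errors(st, sp)
      b <- naive_stress_errors(st, sp)
      for (k in names(a)) {
        expect_equal(a[[k]], b[[k]], tolerance = 1e-12)
      }
    }
  }
})

test_that("shape MeanE never exceeds MaxE", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(2:30, 1)
    truth <- matrix(rnorm(3 * n), n, 3)
    pred <- truth + matrix(rnorm(3 * n, sd = runif(1, 0.01, 2)), n, 3)
    e <- shape_errors(truth, pred, R = runif(1, 1, 20))
    expect_lte(e$mean_e, e$max_e)
  }
})

test_that("the CV protocol is seeded, exhaustive, and reproducible", {
  ds <- small_dataset()
  cv1 <- monte_carlo_cv(ds, "mean_baseline", "shape", rho = 80, repeats = 3,
                        seed = 5)
  cv2 <- monte_carlo_cv(ds, "mean_baseline", "shape", rho = 80, repeats = 3,
                        seed = 5)
  expect_identical(cv1$summary, cv2$summary)
  expect_identical(cv1$per_repeat, cv2$per_repeat)
  cv3 <- monte_carlo_cv(ds, "mean_baseline", "shape", rho = 80, repeats = 3,
                        seed = 6)
  expect_false(identical(cv1$summary$mean, cv3$summary$mean))
  expect_true(all(cv1$summary$sd >= 0))
  expect_equal(nrow(cv1$summary), 4L)  # four shape metrics
  expect_error(monte_carlo_cv(ds, "mean_baseline", "shape", rho = 0), "rho")
  # stress CV reports all four metrics for the three components
  cvs <- monte_carlo_cv(ds, "mean_baseline", "stress", rho = 80, repeats = 2,
                        seed = 5)
  expect_equal(nrow(cvs$summary), 12L)
  expect_setequal(unique(cvs$summary$component), c("S11", "S22", "S12"))
  # metric extraction
  m <- cv_metric(cv1, "mean_e", "shape")
  expect_true(m[["mean"]] > 0)
  expect_error(cv_metric(cv1, "mean_e", "S11"), "no such")
})

test_that("a dataset of identical samples gives a zero-error baseline", {
  ds <- small_dataset()
  clone <- ds
  clone$shapes <- matrix(ds$shapes[1, ], nrow = 8, ncol = ncol(ds$shapes),
                         byrow = TRUE)
  clone$stresses <- matrix(ds$stresses[1, ], nrow = 8, ncol = ncol(ds$stresses),
                           byrow = TRUE)
  clone$designs <- ds$designs[rep(1, 8), ]
  clone$designs$design_id <- 1:8
  cv <- monte_carlo_cv(clone, "mean_baseline", "shape", rho = 75, repeats = 2,
                       seed = 1)
  expect_equal(cv_metric(cv, "mean_e", "shape")[["mean"]], 0, tolerance = 1e-12)
})

test_that("the mean-predictor report has one row per repeat and test sample", {
  ds <- small_dataset()
  n <- nrow(ds$designs)
  rep3 <- mean_predictor_report(ds, "shape", rho = 80, repeats = 3, seed = 2)
  n_test <- n - round(0.8 * n)
  expect_equal(nrow(rep3), 3L * n_test)
  expect_true(all(rep3$mean_e >= 0))
  reps <- mean_predictor_report(ds, "stress", rho = 80, repeats = 2, seed = 2)
  expect_equal(nrow(reps), 2L * n_test * 3L)  # three stress components
})

test_that("training-set error does not exceed test-set error on average", {
  ds <- small_dataset()
  n <- nrow(ds$designs)
  set.seed(31)
  diffs <- replicate(5, {
    tr <- sample(n, round(0.8 * n))
    te <- setdiff(seq_len(n), tr)
    m <- fit_surrogate(ds$designs[tr, ], ds$stresses[tr, ], "mean_baseline",
                       "stress")
    err <- function(idx) {
      preds <- predict(m, ds$designs[idx, ])
      mean(vapply(seq_along(idx), function(k) {
        truth <- unflatten_field(ds$stresses[idx[k], ])
        pred <- unflatten_field(preds[k, ])
        stress_errors(truth[, 1], pred[, 1])$mean_e
      }, 0))
    }
    err(te) - err(tr)
  })
  expect_gte(mean(diffs), 0)
})
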
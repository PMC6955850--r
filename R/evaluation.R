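# Shape and stress error metrics and the Monte-Carlo cross-validation
# protocol (random rho% train / complement test splits, repeated, metric
# mean +/- sd across repeats), plus the mean-predictor baseline.

#' Circumcircle radius of three 3D points
#'
#' Radius of the unique circle through three non-collinear points; used to
#' normalize shape errors by the valve size (the circle through the three
#' commissures).
#'
#' @param pts 3 x 3 matrix, one point per row, mm.
#' @return radius, mm.
#' @examples
#' circumcircle_radius(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0)))  # 1
#' @export
circumcircle_radius <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(nrow(pts) == 3L, ncol(pts) == 3L)
  ab <- pts[2L, ] - pts[1L, ]
  ac <- pts[3L, ] - pts[1L, ]
  bc <- pts[3L, ] - pts[2L, ]
  cr <- c(ab[2] * ac[3] - ab[3] * ac[2],
          ab[3] * ac[1] - ab[1] * ac[3],
          ab[1] * ac[2] - ab[2] * ac[1])
  area2 <- sqrt(sum(cr^2))  # 2 * triangle area
  if (area2 < 1e-12 * max(sum(ab^2), sum(ac^2), 1e-300)) {
    stop("circumcircle_radius: the three points are collinear", call. = FALSE)
  }
  sqrt(sum(ab^2) * sum(ac^2) * sum(bc^2)) / (2 * area2)
}

# the valve's three commissures from one leaflet's true deformed shape:
# the leaflet's first commissure node rotated by 0, 120 and 240 degrees
# about the valve axis (three-fold symmetry)
valve_commissures <- function(shape, commissure_id) {
  p <- shape[commissure_id, ]
  rot <- function(phi) {
    c(cos(phi) * p[1] - sin(phi) * p[2],
      sin(phi) * p[1] + cos(phi) * p[2],
      p[3])
  }
  rbind(rot(0), rot(2 * pi / 3), rot(4 * pi / 3))
}

#' Shape error metrics
#'
#' Node-wise Euclidean distance errors between a true and a predicted
#' deformed mesh: `MeanE` (mean distance, mm), `NMeanE = MeanE / R * 100%`,
#' `MaxE` (largest distance, mm), and `NMaxE = MaxE / R * 100%`, where `R`
#' is the circumcircle radius of the valve's three commissures on the true
#' shape.
#'
#' @param truth,pred N x 3 nodal coordinate matrices, mm.
#' @param R normalizing circumcircle radius, mm.
#' @return named list `mean_e`, `n_mean_e`, `max_e`, `n_max_e`.
#' @export
shape_errors <- function(truth, pred, R) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  if (!all(dim(truth) == dim(pred)) || ncol(truth) != 3L) {
    stop("shape_errors: truth and pred must be equal-sized N x 3 matrices",
         call. = FALSE)
  }
  stopifnot(is.finite(R), R > 0)
  d <- sqrt(rowSums((truth - pred)^2))
  mean_e <- mean(d)
  max_e <- max(d)
  list(mean_e = mean_e, n_mean_e = mean_e / R * 100,
       max_e = max_e, n_max_e = max_e / R * 100)
}

#' Stress error metrics for one component
#'
#' `MeanE` is the mean absolute nodal difference (kPa); `NMeanE` normalizes
#' it by the true field's range `max(S) - min(S)`; `MaxE` compares the peak
#' absolute stresses `|max|S| - max|S~||` (the peak locations may differ);
#' `NMaxE = MaxE / max|S| * 100%`. A constant true field has no range, so
#' `NMeanE` is undefined and raises an error rather than returning zero.
#'
#' @param truth,pred length-N stress vectors, kPa.
#' @return named list `mean_e`, `n_mean_e`, `max_e`, `n_max_e`.
#' @export
stress_errors <- function(truth, pred) {
  truth <- as.numeric(truth); pred <- as.numeric(pred)
  if (length(truth) != length(pred)) {
    stop("stress_errors: truth and pred must have equal length", call. = FALSE)
  }
  rng <- max(truth) - min(truth)
  if (rng <= 0) {
    stop("stress_errors: constant true field, NMeanE undefined", call. = FALSE)
  }
  mean_e <- mean(abs(truth - pred))
  peak_t <- max(abs(truth))
  max_e <- abs(peak_t - max(abs(pred)))
  list(mean_e = mean_e, n_mean_e = mean_e / rng * 100,
       max_e = max_e, n_max_e = max_e / peak_t * 100)
}

# per-sample metric rows for one target family
sample_metrics <- function(target, truth_flat, pred_flat, commissure_id) {
  if (target == "shape") {
    truth <- unflatten_field(truth_flat)
    pred <- unflatten_field(pred_flat)
    R <- circumcircle_radius(valve_commissures(truth, commissure_id))
    e <- shape_errors(truth, pred, R)
    data.frame(metric = c("mean_e", "n_mean_e", "max_e", "n_max_e"),
               component = "shape",
               value = unlist(e), row.names = NULL)
  } else {
    truth <- unflatten_field(truth_flat)
    pred <- unflatten_field(pred_flat)
    comp <- c("S11", "S22", "S12")
    do.call(rbind, lapply(1:3, function(j) {
      e <- stress_errors(truth[, j], pred[, j])
      data.frame(metric = c("mean_e", "n_mean_e", "max_e", "n_max_e"),
                 component = comp[j],
                 value = unlist(e), row.names = NULL)
    }))
  }
}

#' Monte-Carlo cross-validation of a surrogate family
#'
#' In each repeat, `rho`% of the designs are drawn (without replacement,
#' seeded) as the training set, the model family is fully trained on them,
#' and the metrics are computed on every held-out design and averaged. The
#' result reports the mean and standard deviation of each metric across
#' repeats. Per-repeat seeds are derived deterministically from the master
#' seed, so the whole protocol is reproducible.
#'
#' @param dataset a [generate_dataset()] result.
#' @param family `"model_a"`, `"model_d"`, or `"mean_baseline"`.
#' @param target `"shape"` or `"stress"`.
#' @param rho training percentage in (0, 100).
#' @param repeats number of Monte-Carlo repeats.
#' @param seed master seed.
#' @param cfg a [train_config()] shared by all repeats (its seed field is
#'   replaced by the per-repeat seed).
#' @param epochs_a model-a per-phase epochs (see [fit_surrogate()]).
#' @param keep_per_sample keep the per-test-sample metric values.
#' @return An object of class `tav_cv_result`: a `summary` data frame
#'   (metric, component, mean, sd) plus per-repeat values and the protocol
#'   parameters.
#' @export
monte_carlo_cv <- function(dataset, family = c("model_a", "model_d", "mean_baseline"),
                           target = c("shape", "stress"),
                           rho = 90, repeats = 10L, seed = 0L,
                           cfg = train_config(),
                           epochs_a = c(ae = cfg$epochs, map = cfg$epochs,
                                        finetune = cfg$epochs),
                           keep_per_sample = FALSE) {
  stopifnot(inherits(dataset, "tav_dataset"))
  family <- match.arg(family)
  target <- match.arg(target)
  if (!(rho > 0 && rho < 100)) stop("monte_carlo_cv: need 0 < rho < 100", call. = FALSE)
  n <- nrow(dataset$designs)
  if (n < 2L) stop("monte_carlo_cv: need >= 2 samples", call. = FALSE)
  fields <- if (target == "shape") dataset$shapes else dataset$stresses
  commissure_id <- dataset$mesh$commissure_node_ids[1L]
  n_train <- max(1L, round(rho / 100 * n))
  if (n_train >= n) n_train <- n - 1L

  rep_seeds <- vapply(seq_len(repeats), function(r) derive_seed(seed, 100L + r),
                      integer(1))
  per_repeat <- vector("list", repeats)
  per_sample <- if (keep_per_sample) vector("list", repeats) else NULL
  for (r in seq_len(repeats)) {
    train_idx <- with_seed(rep_seeds[r], sample.int(n, n_train))
    test_idx <- setdiff(seq_len(n), train_idx)
    cfg_r <- cfg; cfg_r$seed <- derive_seed(rep_seeds[r], 7L)
    model <- tryCatch(
      fit_surrogate(dataset$designs[train_idx, ], fields[train_idx, , drop = FALSE],
                    family = family, target = target, cfg = cfg_r,
                    epochs_a = epochs_a),
      error = function(e) {
        stop("monte_carlo_cv: training failed in repeat ", r, ": ",
             conditionMessage(e), call. = FALSE)
      })
    preds <- predict(model, dataset$designs[test_idx, ])
    rows <- lapply(seq_along(test_idx), function(k) {
      m <- sample_metrics(target, fields[test_idx[k], ], preds[k, ], commissure_id)
      m$sample <- test_idx[k]
      m
    })
    rows <- do.call(rbind, rows)
    agg <- stats::aggregate(value ~ metric + component, rows, mean)
    agg$repeat_id <- r
    per_repeat[[r]] <- agg
    if (keep_per_sample) {
      rows$repeat_id <- r
      per_sample[[r]] <- rows
    }
  }
  all_rep <- do.call(rbind, per_repeat)
  summ <- merge(
    stats::aggregate(value ~ metric + component, all_rep, mean),
    stats::aggregate(value ~ metric + component, all_rep, stats::sd),
    by = c("metric", "component"), suffixes = c("_mean", "_sd"))
  names(summ) <- c("metric", "component", "mean", "sd")
  summ$sd[is.na(summ$sd)] <- 0
  structure(list(summary = summ, per_repeat = all_rep,
                 per_sample = if (keep_per_sample) do.call(rbind, per_sample),
                 family = family, target = target, rho = rho,
                 repeats = repeats, seed = seed),
            class = "tav_cv_result")
}

#' @export
print.tav_cv_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo CV: %s / %s, rho = %g%%, %d repeats (seed %d)\n",
              x$family, x$target, x$rho, x$repeats, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Extract one metric from a CV result
#' @param cv a `tav_cv_result`.
#' @param metric one of `"mean_e"`, `"n_mean_e"`, `"max_e"`, `"n_max_e"`.
#' @param component `"shape"`, `"S11"`, `"S22"`, or `"S12"`.
#' @return named numeric `c(mean, sd)`.
#' @export
cv_metric <- function(cv, metric, component = "shape") {
  row <- cv$summary[cv$summary$metric == metric &
                      cv$summary$component == component, ]
  if (nrow(row) != 1L) stop("cv_metric: no such metric/component", call. = FALSE)
  c(mean = row$mean, sd = row$sd)
}

#' Per-test-sample MeanE distribution of the mean-predictor baseline
#'
#' Evaluates the "predict the training mean" baseline: in each repeat the
#' training-set mean field is used as the prediction for every held-out
#' design, and each held-out design contributes one MeanE value. The pooled
#' values are the histogram-ready distribution that reveals how much the
#' fields vary across the design space.
#'
#' @inheritParams monte_carlo_cv
#' @return data frame with columns `repeat_id`, `sample`, `component`,
#'   `mean_e` (`repeats x test-set size` rows per component).
#' @export
mean_predictor_report <- function(dataset, target = c("shape", "stress"),
                                  rho = 90, repeats = 10L, seed = 0L) {
  target <- match.arg(target)
  cv <- monte_carlo_cv(dataset, family = "mean_baseline", target = target,
                       rho = rho, repeats = repeats, seed = seed,
                       keep_per_sample = TRUE)
  ps <- cv$per_sample
  ps <- ps[ps$metric == "mean_e", c("repeat_id", "sample", "component", "value")]
  names(ps)[4L] <- "mean_e"
  rownames(ps) <- NULL
  ps
}

#' Write a CV summary as CSV
#'
#' Rows are metric/component pairs; columns are the across-repeat mean and
#' standard deviation, mirroring the usual tabular reporting of surrogate
#' errors.
#'
#' @param cv a `tav_cv_result`.
#' @param path output CSV path.
#' @export
write_cv_csv <- function(cv, path) {
  stopifnot(inherits(cv, "tav_cv_result"))
  utils::write.csv(cv$summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
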
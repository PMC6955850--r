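#' TAV leaflet design space
#'
#' A transcatheter aortic valve (TAV) leaflet design is described by three
#' parameters: `a`, the attachment-curve coefficient (mm); `b`, the
#' dimensionless exponential shape coefficient of the stent suturing line
#' (SSL); and `ssl`, the suturing-line length (mm). The feasible ranges are
#' closed intervals; the default bounds are the validated porcine-pericardium
#' leaflet design ranges (a in [4.57, 6.35] mm, b in [3.0, 3.4],
#' ssl in [18.4, 20.1] mm).
#'
#' @param a,b,ssl length-2 numeric `(min, max)` bounds for each parameter.
#' @return An object of class `tav_design_space`: a list with a `bounds`
#'   matrix (rows `a`, `b`, `ssl`; columns `min`, `max`) and a `units`
#'   character vector.
#' @examples
#' sp <- design_space()
#' sp$bounds
#' @export
design_space <- function(a = c(4.57, 6.35), b = c(3.0, 3.4),
                         ssl = c(18.4, 20.1)) {
  bounds <- rbind(a = as.numeric(a), b = as.numeric(b), ssl = as.numeric(ssl))
  colnames(bounds) <- c("min", "max")
  if (any(!is.finite(bounds))) {
    stop("design_space: bounds must be finite", call. = FALSE)
  }
  if (any(bounds[, "min"] >= bounds[, "max"])) {
    stop("design_space: every parameter needs min < max (degenerate bounds are not allowed)",
         call. = FALSE)
  }
  structure(list(bounds = bounds,
                 units = c(a = "mm", b = "1", ssl = "mm")),
            class = "tav_design_space")
}

#' @export
print.tav_design_space <- function(x, ...) {
  cat("TAV design space (closed bounds):\n")
  print(cbind(as.data.frame(x$bounds), unit = x$units))
  invisible(x)
}

#' Construct a design-parameter table
#'
#' @param a,b,ssl numeric vectors (recycled to a common length).
#' @return A `data.frame` with columns `design_id`, `a`, `b`, `ssl`.
#' @export
design_params <- function(a, b, ssl) {
  d <- data.frame(a = as.numeric(a), b = as.numeric(b), ssl = as.numeric(ssl))
  data.frame(design_id = seq_len(nrow(d)), d)
}

as_design_df <- function(p) {
  if (is.numeric(p) && !is.null(names(p))) {
    p <- as.data.frame(as.list(p[c("a", "b", "ssl")]))
  }
  p <- as.data.frame(p)
  miss <- setdiff(c("a", "b", "ssl"), names(p))
  if (length(miss)) {
    stop("design parameters need columns a, b, ssl (missing: ",
         paste(miss, collapse = ", "), ")", call. = FALSE)
  }
  if (is.null(p$design_id)) p$design_id <- seq_len(nrow(p))
  p[, c("design_id", "a", "b", "ssl")]
}

#' Validate design parameters against a design space
#'
#' A design is valid iff every parameter lies inside its closed bound.
#' Non-finite parameter values are an error, not `FALSE`: they indicate a
#' malformed design rather than an out-of-range one.
#'
#' @param p a design (named vector with `a`, `b`, `ssl`) or a data frame of
#'   designs.
#' @param space a [design_space()].
#' @return logical vector, one entry per design.
#' @export
validate_params <- function(p, space = design_space()) {
  stopifnot(inherits(space, "tav_design_space"))
  p <- as_design_df(p)
  vals <- as.matrix(p[, c("a", "b", "ssl")])
  if (any(!is.finite(vals))) {
    stop("validate_params: non-finite design parameter value", call. = FALSE)
  }
  b <- space$bounds
  ok <- rep(TRUE, nrow(vals))
  for (j in 1:3) {
    ok <- ok & vals[, j] >= b[j, "min"] & vals[, j] <= b[j, "max"]
  }
  unname(ok)
}

#' The eight extreme designs of a design space
#'
#' Returns the `2^k` corner designs of the bounds hypercube (8 for the
#' default three-parameter space). These are the extreme leaflet shapes that
#' bracket the design space.
#'
#' @inheritParams validate_params
#' @return data frame of corner designs, one per row.
#' @export
extreme_designs <- function(space = design_space()) {
  stopifnot(inherits(space, "tav_design_space"))
  b <- space$bounds
  g <- expand.grid(a = b["a", ], b = b["b", ], ssl = b["ssl", ],
                   KEEP.OUT.ATTRS = FALSE)
  design_params(g$a, g$b, g$ssl)
}

#' Sample designs from the design space
#'
#' Three sampling schemes are supported: `"latin-hypercube"` (space-filling,
#' the default used to build training datasets), `"uniform-random"`, and
#' `"grid"` (a full tensor grid; `n` must be a perfect cube so that each axis
#' gets `n^(1/3)` levels spanning the closed bounds). Sampling is
#' deterministic given `(scheme, n, seed)`.
#'
#' @inheritParams validate_params
#' @param n number of designs (>= 1).
#' @param scheme sampling scheme.
#' @param seed integer RNG seed.
#' @return data frame of `n` valid designs.
#' @export
sample_designs <- function(space = design_space(), n,
                           scheme = c("latin-hypercube", "uniform-random", "grid"),
                           seed = 0L) {
  stopifnot(inherits(space, "tav_design_space"))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    stop("sample_designs: n must be a count >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.character(scheme) && length(scheme) == 1L &&
      !scheme %in% c("latin-hypercube", "uniform-random", "grid")) {
    stop("sample_designs: unknown scheme '", scheme, "'", call. = FALSE)
  }
  scheme <- match.arg(scheme)
  b <- space$bounds
  lo <- b[, "min"]; hi <- b[, "max"]
  u <- switch(scheme,
    "latin-hypercube" = with_seed(seed, lhs::randomLHS(n, 3L)),
    "uniform-random" = with_seed(seed, matrix(stats::runif(3L * n), n, 3L)),
    "grid" = {
      k <- round(n^(1 / 3))
      if (k^3 != n) {
        stop("sample_designs: grid scheme needs n to be a perfect cube (got n = ",
             n, ")", call. = FALSE)
      }
      levels01 <- if (k == 1L) 0.5 else seq(0, 1, length.out = k)
      as.matrix(expand.grid(levels01, levels01, levels01,
                            KEEP.OUT.ATTRS = FALSE))
    })
  vals <- sweep(sweep(u, 2L, hi - lo, `*`), 2L, lo, `+`)
  design_params(vals[, 1L], vals[, 2L], vals[, 3L])
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Write / read designs as CSV
#'
#' Serializes a design table with the canonical header
#' `design_id,a,b,ssl`.
#'
#' @param designs data frame of designs.
#' @param path CSV file path.
#' @export
write_designs_csv <- function(designs, path) {
  designs <- as_design_df(designs)
  utils::write.csv(designs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_designs_csv
#' @export
read_designs_csv <- function(path) {
  as_design_df(utils::read.csv(path))
}
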
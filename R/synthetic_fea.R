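# Deterministic pseudo-FEA generator. Maps each design to a mounted and
# pressurized 3D leaflet shape plus nodal in-plane stress fields with the
# structure valve-closure FE results have (fixed attachment edge, belly
# bulge under pressure, S11 dominating S22 and S12, smooth dependence on the
# design parameters). It is explicitly NOT a mechanics solver: its contract
# is structural fidelity of the outputs, not force balance.

#' Configuration of the synthetic field generator
#'
#' @param pressure transvalvular closure pressure, mmHg. Displacements scale
#'   linearly with it; 0 means no closure deformation.
#' @param noise_sd relative standard deviation of multiplicative Gaussian
#'   noise on the stress fields (0 = noise-free, the default: FE training
#'   data carries no appreciable noise).
#' @param seed integer seed for the noise stream.
#' @param stress_scale named numeric `(s11, s22, s12)` magnitude
#'   coefficients, kPa. The S11 coefficient must be the largest, matching
#'   the observed dominance of the circumferential stress component.
#' @param low_rank logical. When `TRUE`, all generated fields are exact
#'   linear combinations of 8 fixed basis fields with design-dependent
#'   coefficients -- ground truth on which an 8-code autoencoder can reach
#'   (near-)zero reconstruction error; used as an oracle for the surrogate
#'   pipeline.
#' @param n_nodes mesh node count.
#' @return An object of class `tav_synth_config`.
#' @export
synthetic_config <- function(pressure = 120, noise_sd = 0, seed = 0L,
                             stress_scale = c(s11 = 600, s22 = 150, s12 = 100),
                             low_rank = FALSE, n_nodes = 1381L) {
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("synthetic_config: noise_sd must be >= 0", call. = FALSE)
  }
  stress_scale <- stress_scale[c("s11", "s22", "s12")]
  if (any(is.na(stress_scale))) {
    stop("synthetic_config: stress_scale needs named entries s11, s22, s12",
         call. = FALSE)
  }
  if (stress_scale["s11"] <= max(stress_scale["s22"], stress_scale["s12"])) {
    stop("synthetic_config: the s11 scale must be the largest", call. = FALSE)
  }
  structure(list(pressure = pressure, noise_sd = noise_sd,
                 seed = as.integer(seed), stress_scale = stress_scale,
                 low_rank = isTRUE(low_rank), n_nodes = as.integer(n_nodes)),
            class = "tav_synth_config")
}

# normalized design coordinates in [0,1] relative to the default space
design_unit <- function(design, space = design_space()) {
  b <- space$bounds
  c(a = unname((design$a - b["a", 1]) / (b["a", 2] - b["a", 1])),
    b = unname((design$b - b["b", 1]) / (b["b", 2] - b["b", 1])),
    ssl = unname((design$ssl - b["ssl", 1]) / (b["ssl", 2] - b["ssl", 1])))
}

#' Mount the flat leaflet on the stent suturing line
#'
#' Places every attachment-edge node exactly on the 3D suturing-line curve at
#' its matching normalized arc-length fraction, and builds the free edge as a
#' commissure-to-commissure curve pulled toward the valve axis (the
#' coaptation line) with a droop proportional to the free-edge height.
#' Interior nodes blend between the two edges along the mesh's parametric
#' v coordinate. The mapping is smooth in the design parameters and fully
#' deterministic.
#'
#' @param mesh a [mesh_leaflet()] result.
#' @param curve a [build_ssl_curve()] result built from the same design.
#' @return N x 3 matrix of mounted nodal coordinates, mm.
#' @export
mount_leaflet <- function(mesh, curve) {
  stopifnot(inherits(mesh, "tav_mesh"), inherits(curve, "tav_ssl_curve"))
  d <- mesh$design
  if (abs(d$b - curve$b) > 1e-9 || abs(d$ssl - curve$ssl) > 1e-9) {
    stop("mount_leaflet: mesh and suturing-line curve come from different designs",
         call. = FALSE)
  }
  # normalized arc-length fraction of each attachment node along the 2D edge
  att_ids <- mesh$attachment_node_ids
  xmax <- mesh$contour$half_width
  a <- d$a
  xg <- seq(-xmax, xmax, length.out = 4001L)
  integrand <- sqrt(1 + attachment_dy(xg, a)^2)
  cums <- c(0, cumsum((integrand[-1] + integrand[-length(xg)]) / 2 * diff(xg)))
  frac_of_x <- stats::approxfun(xg, cums / cums[length(cums)])
  att_frac <- frac_of_x(mesh$nodes[att_ids, 1L])
  att_frac[1L] <- 0; att_frac[length(att_frac)] <- 1
  att3d <- ssl_point_at_fraction(curve, att_frac)

  # free-edge target: chord between the commissures pulled toward the axis
  h <- mesh$contour$h
  du <- design_unit(d)
  R <- curve$radius
  thc <- .THETA_HALF
  z_comm <- curve$p * exp(curve$b * thc)
  free_curve <- function(t) {
    pull <- 0.85 + 0.05 * (du[["b"]] - 0.5)   # fraction of the chord-to-axis gap closed
    droop <- 0.05 * h + 0.3                   # mm, downward-free-edge sag scale
    cbind(x = R * cos(thc) * (1 - pull * sin(pi * t)),
          y = R * sin(thc) * (2 * t - 1),
          z = z_comm + droop * 0.15 * sin(pi * t))
  }

  # per-u-column edge anchors; interior nodes blend along v
  n <- nrow(mesh$nodes)
  out <- matrix(0, n, 3L)
  # attachment anchors indexed by column: att_ids is ordered by u
  u_cols <- mesh$nodes[att_ids, 1L]  # strictly increasing x
  att_anchor <- att3d
  free_anchor <- free_curve(mesh$u[att_ids])
  # map every node's u to its column via matching u of attachment ordering
  col_of_u <- stats::approxfun(mesh$u[att_ids], seq_along(att_ids))
  ci <- round(col_of_u(mesh$u))
  v <- mesh$v
  out[, 1L] <- (1 - v) * att_anchor[ci, 1L] + v * free_anchor[ci, 1L]
  out[, 2L] <- (1 - v) * att_anchor[ci, 2L] + v * free_anchor[ci, 2L]
  out[, 3L] <- (1 - v) * att_anchor[ci, 3L] + v * free_anchor[ci, 3L]
  # corners carry v = 0.5 parametrically but are attachment nodes; pin them
  out[att_ids, ] <- att3d
  colnames(out) <- c("x", "y", "z")
  out
}

#' Apply the pseudo-closure displacement field
#'
#' Adds a belly-bulge displacement to a mounted leaflet: radially inward and
#' downward motion proportional to the closure pressure and to a smooth bump
#' in the parametric coordinates that vanishes identically on the attachment
#' edge (the suture line stays fixed, as on a rigid stent). The bump
#' amplitude is a smooth function of the design parameters.
#'
#' @param mounted N x 3 coordinates from [mount_leaflet()].
#' @param cfg a [synthetic_config()].
#' @param design the design row.
#' @param mesh the mesh the coordinates live on (provides u, v).
#' @return N x 3 deformed coordinates, mm.
#' @export
apply_pseudo_closure <- function(mounted, cfg, design, mesh) {
  stopifnot(inherits(cfg, "tav_synth_config"), inherits(mesh, "tav_mesh"))
  du <- design_unit(design)
  u <- mesh$u; v <- mesh$v
  bump <- v^2 * sin(pi * u)
  bump[mesh$attachment_node_ids] <- 0  # exact zero on the suture line
  amp <- 1.4 * (0.75 + 0.18 * du[["a"]] + 0.12 * sin(1.1 * du[["b"]] + 0.5) +
                  0.10 * du[["ssl"]] + 0.08 * du[["a"]] * du[["ssl"]])
  scale <- (cfg$pressure / 120) * amp * bump
  rho <- sqrt(mounted[, 1L]^2 + mounted[, 2L]^2)
  rho <- pmax(rho, 1e-9)
  er <- cbind(mounted[, 1L] / rho, mounted[, 2L] / rho, 0)
  disp <- -0.75 * scale * er
  disp[, 3L] <- disp[, 3L] - 0.35 * scale
  mounted + disp
}

# fixed smooth basis functions over the parametric coordinates; used by the
# low-rank mode (and nowhere else) so that fields are exactly rank-8
lowrank_basis_fun <- function(u, v) {
  cbind(1,
        u - 0.5,
        v - 0.5,
        (u - 0.5) * (v - 0.5),
        sin(pi * u),
        sin(pi * v),
        cos(pi * u),
        (u - 0.5)^2)
}

# 3N x 8 basis matrix for one field family; the three N-blocks of basis k use
# rotated function indices so the blocks differ, but the span stays rank 8
lowrank_basis_matrix <- function(mesh, block_scales = c(1, 1, 1)) {
  Fm <- lowrank_basis_fun(mesh$u, mesh$v)  # N x 8
  n <- nrow(Fm)
  B <- matrix(0, 3L * n, 8L)
  for (k in 1:8) {
    B[seq_len(n), k] <- block_scales[1L] * Fm[, k]
    B[n + seq_len(n), k] <- block_scales[2L] * Fm[, (k %% 8L) + 1L]
    B[2L * n + seq_len(n), k] <- block_scales[3L] * Fm[, ((k + 1L) %% 8L) + 1L]
  }
  B
}

# smooth design-dependent coefficients, first coefficient held constant so
# the coefficient vector's direction determines it uniquely
lowrank_coefs <- function(design, family = c("shape", "stress")) {
  family <- match.arg(family)
  du <- design_unit(design)
  a <- du[["a"]]; b <- du[["b"]]; s <- du[["ssl"]]
  base <- c(1.5,
            0.6 * (a - 0.5),
            0.5 * (b - 0.5),
            0.45 * (s - 0.5),
            0.35 * sin(1.3 * a + 0.4),
            0.3 * a * s,
            0.3 * cos(1.1 * b),
            0.25 * sin(0.9 * s + 0.2))
  if (family == "stress") {
    base <- c(1.5,
              0.55 * (s - 0.5),
              0.5 * sin(1.2 * a),
              0.4 * (b - 0.5),
              0.35 * a * b,
              0.3 * cos(1.4 * s),
              0.28 * (a - 0.5),
              0.22 * sin(1.6 * b + 0.3))
  }
  base
}

#' Synthesize nodal in-plane stress fields
#'
#' Produces smooth analytic S11, S22, S12 nodal fields on the deformed
#' leaflet: S11 peaks near the attachment edge and the commissures (the
#' load-bearing suture region), S22 peaks in the belly, and S12 is
#' antisymmetric across the leaflet midline. Each component is modulated by
#' a smooth function of the design parameters and scaled by
#' `cfg$stress_scale`, which keeps the dataset-mean |S11| strictly above
#' mean |S22| and mean |S12|. Optional multiplicative Gaussian noise
#' (sd = `cfg$noise_sd`) is seeded and reproducible.
#'
#' @param deformed N x 3 deformed coordinates (kept for interface symmetry;
#'   the analytic fields are functions of the parametric coordinates).
#' @param mesh the leaflet mesh (provides u, v).
#' @param design the design row.
#' @param cfg a [synthetic_config()].
#' @param sample_seed seed for this sample's noise draw (defaults to
#'   `cfg$seed`).
#' @return N x 3 matrix with columns `S11`, `S22`, `S12`, kPa.
#' @export
synth_stress_field <- function(deformed, mesh, design, cfg,
                               sample_seed = cfg$seed) {
  stopifnot(inherits(cfg, "tav_synth_config"), inherits(mesh, "tav_mesh"))
  u <- mesh$u; v <- mesh$v
  du <- design_unit(design)
  a <- du[["a"]]; b <- du[["b"]]; s <- du[["ssl"]]
  sc <- cfg$stress_scale
  w_comm <- exp(-((u - 0) / 0.18)^2) + exp(-((u - 1) / 0.18)^2)
  w_att <- exp(-(v / 0.45)^2)
  m1 <- 1 + 0.25 * (a - 0.5) + 0.15 * sin(2.0 * b) + 0.2 * (s - 0.5) + 0.1 * a * b
  g1 <- (0.25 + 0.75 * w_att * (0.5 + 0.5 * w_comm)) * m1
  w_belly <- exp(-(((u - 0.5) / 0.35)^2 + ((v - 0.55) / 0.4)^2))
  m2 <- 1 + 0.2 * cos(1.3 * a) + 0.25 * (b - 0.5) + 0.12 * s^2
  g2 <- (0.2 + 0.8 * w_belly) * m2
  m3 <- 1 + 0.18 * (a - 0.5) - 0.2 * (b - 0.5) + 0.15 * sin(1.7 * s)
  g3 <- 1.6 * (u - 0.5) * exp(-((v - 0.3) / 0.5)^2) * m3
  S <- cbind(S11 = sc[["s11"]] * g1, S22 = sc[["s22"]] * g2,
             S12 = sc[["s12"]] * g3)
  if (cfg$noise_sd > 0) {
    eps <- with_seed(sample_seed,
                     matrix(stats::rnorm(length(S)), nrow(S), ncol(S)))
    S <- S * (1 + cfg$noise_sd * eps)
  }
  S
}

#' Flatten / unflatten nodal fields
#'
#' Fields are stored as flat vectors of length 3N in block order: the three
#' coordinate blocks `(x, y, z)` for shapes, or the three component blocks
#' `(S11, S22, S12)` for stresses.
#'
#' @param m N x 3 matrix.
#' @return length-3N numeric (or the N x 3 matrix for the inverse).
#' @export
flatten_field <- function(m) as.numeric(m)

#' @rdname flatten_field
#' @param x length-3N numeric vector.
#' @param names optional column names.
#' @export
unflatten_field <- function(x, names = NULL) {
  n <- length(x) / 3L
  m <- matrix(x, n, 3L)
  if (!is.null(names)) colnames(m) <- names
  m
}

#' Generate a synthetic dataset of field samples
#'
#' Runs the full pseudo-FEA chain (contour, mesh, suturing line, mounting,
#' pseudo-closure, stress synthesis) for each design. All samples share the
#' node count and node ordering, so shapes and stresses are comparable flat
#' vectors of length 3N (4143 for the default 1381-node mesh). In low-rank
#' mode the fields are instead exact combinations of 8 fixed basis fields
#' (see [synthetic_config()]).
#'
#' @param designs data frame of valid designs.
#' @param cfg a [synthetic_config()].
#' @return An object of class `tav_dataset`: designs, `shapes` (n x 3N),
#'   `stresses` (n x 3N), the reference mesh, and a manifest recording the
#'   seed and configuration.
#' @export
generate_dataset <- function(designs, cfg = synthetic_config()) {
  designs <- as_design_df(designs)
  stopifnot(inherits(cfg, "tav_synth_config"))
  if (!all(validate_params(designs))) {
    bad <- which(!validate_params(designs))
    stop("generate_dataset: designs outside the design space: design_id ",
         paste(designs$design_id[bad], collapse = ", "), call. = FALSE)
  }
  n <- nrow(designs)
  sample_seeds <- with_seed(cfg$seed, sample.int(2147483646L, n))

  # reference mesh at the design-space center fixes the shared (u, v) layout
  sp <- design_space()
  mid <- design_params(mean(sp$bounds["a", ]), mean(sp$bounds["b", ]),
                       mean(sp$bounds["ssl", ]))
  mesh_ref <- mesh_leaflet(build_contour(mid), cfg$n_nodes)
  N <- nrow(mesh_ref$nodes)

  shapes <- matrix(0, n, 3L * N)
  stresses <- matrix(0, n, 3L * N)

  if (cfg$low_rank) {
    Bshape <- lowrank_basis_matrix(mesh_ref, block_scales = c(4, 4, 2.5))
    Bstress <- lowrank_basis_matrix(
      mesh_ref, block_scales = cfg$stress_scale / 3)
    for (i in seq_len(n)) {
      d <- designs[i, ]
      shapes[i, ] <- as.numeric(Bshape %*% lowrank_coefs(d, "shape"))
      stresses[i, ] <- as.numeric(Bstress %*% lowrank_coefs(d, "stress"))
    }
    if (cfg$noise_sd > 0) {
      for (i in seq_len(n)) {
        eps <- with_seed(sample_seeds[i],
                         stats::rnorm(3L * N + 3L * N))
        shapes[i, ] <- shapes[i, ] * (1 + cfg$noise_sd * eps[seq_len(3L * N)])
        stresses[i, ] <- stresses[i, ] * (1 + cfg$noise_sd * eps[3L * N + seq_len(3L * N)])
      }
    }
  } else {
    for (i in seq_len(n)) {
      d <- designs[i, ]
      res <- tryCatch({
        mesh <- mesh_leaflet(build_contour(d), cfg$n_nodes)
        curve <- build_ssl_curve(d$b, d$ssl)
        mounted <- mount_leaflet(mesh, curve)
        deformed <- apply_pseudo_closure(mounted, cfg, d, mesh)
        stress <- synth_stress_field(deformed, mesh, d, cfg,
                                     sample_seed = sample_seeds[i])
        list(shape = deformed, stress = stress)
      }, error = function(e) {
        stop("generate_dataset: design_id ", d$design_id, ": ",
             conditionMessage(e), call. = FALSE)
      })
      shapes[i, ] <- flatten_field(res$shape)
      stresses[i, ] <- flatten_field(res$stress)
    }
  }

  structure(list(
    designs = designs,
    shapes = shapes,
    stresses = stresses,
    mesh = mesh_ref,
    n_nodes = N,
    manifest = list(
      version = "1.0",
      seed = cfg$seed,
      node_count = N,
      field_length = 3L * N,
      config = unclass(cfg),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    )
  ), class = "tav_dataset")
}

#' @export
print.tav_dataset <- function(x, ...) {
  cat(sprintf("TAV field dataset: %d designs, %d nodes (field length %d)%s\n",
              nrow(x$designs), x$n_nodes, 3L * x$n_nodes,
              if (isTRUE(x$manifest$config$low_rank)) ", low-rank mode" else ""))
  invisible(x)
}

#' Extract one sample's fields as matrices
#'
#' @param dataset a `tav_dataset`.
#' @param i sample index.
#' @return list with `design`, `shape` (N x 3), `stress` (N x 3).
#' @export
get_sample <- function(dataset, i) {
  stopifnot(inherits(dataset, "tav_dataset"))
  list(design = dataset$designs[i, ],
       shape = unflatten_field(dataset$shapes[i, ], c("x", "y", "z")),
       stress = unflatten_field(dataset$stresses[i, ], c("S11", "S22", "S12")))
}
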
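# Persistence: legacy VTK unstructured-grid export (ASCII or binary) for
# ParaView, dataset containers (directory of Feather arrays + JSON
# manifest), surrogate checkpoints, and run configuration round-trips.

.DATASET_VERSION <- "1.0"
.MODEL_VERSION <- "1.0"

#' Export a mesh with nodal fields as a legacy VTK unstructured grid
#'
#' Writes a `.vtk` file loadable by ParaView/VTK readers. Nodes may be 2D
#' (padded with z = 0) or 3D; point-data arrays keep their names verbatim
#' (1-component scalars or 3-component vectors per array).
#'
#' @param nodes N x 2 or N x 3 coordinate matrix.
#' @param triangles M x 3 1-based node indices.
#' @param point_fields named list of length-N vectors or N x 3 matrices.
#' @param path output path.
#' @param ascii write the ASCII dialect (default); otherwise binary
#'   (big-endian, per the legacy VTK format).
#' @param title dataset title line.
#' @return the path, invisibly.
#' @export
export_vtk <- function(nodes, triangles, point_fields = list(), path,
                       ascii = TRUE, title = "tavsurrogate field export") {
  nodes <- as.matrix(nodes)
  if (ncol(nodes) == 2L) nodes <- cbind(nodes, 0)
  if (ncol(nodes) != 3L) stop("export_vtk: nodes must be N x 2 or N x 3", call. = FALSE)
  triangles <- as.matrix(triangles)
  if (ncol(triangles) != 3L) stop("export_vtk: triangles must be M x 3", call. = FALSE)
  if (max(triangles) > nrow(nodes) || min(triangles) < 1L) {
    stop("export_vtk: triangle indices out of range", call. = FALSE)
  }
  n <- nrow(nodes); m <- nrow(triangles)
  for (nm in names(point_fields)) {
    f <- point_fields[[nm]]
    len <- if (is.matrix(f)) nrow(f) else length(f)
    if (len != n) stop("export_vtk: field '", nm, "' length does not match node count",
                       call. = FALSE)
  }

  con <- file(path, open = "wb")
  on.exit(close(con))
  wline <- function(s) writeChar(paste0(s, "\n"), con, eos = NULL)
  wnum <- function(x, ncol_out) {
    if (ascii) {
      tx <- format(x, digits = 17, scientific = TRUE, trim = TRUE)
      tx <- matrix(tx, ncol = ncol_out)
      wline(paste(apply(tx, 1L, paste, collapse = " "), collapse = "\n"))
    } else {
      writeBin(as.numeric(t(matrix(x, ncol = ncol_out))), con,
               size = 8L, endian = "big")
      wline("")
    }
  }
  wint <- function(x, ncol_out) {
    if (ascii) {
      tx <- matrix(as.character(x), ncol = ncol_out)
      wline(paste(apply(tx, 1L, paste, collapse = " "), collapse = "\n"))
    } else {
      writeBin(as.integer(t(matrix(x, ncol = ncol_out))), con,
               size = 4L, endian = "big")
      wline("")
    }
  }

  wline("# vtk DataFile Version 3.0")
  wline(title)
  wline(if (ascii) "ASCII" else "BINARY")
  wline("DATASET UNSTRUCTURED_GRID")
  wline(sprintf("POINTS %d double", n))
  wnum(nodes, 3L)
  wline(sprintf("CELLS %d %d", m, 4L * m))
  wint(cbind(3L, triangles - 1L), 4L)
  wline(sprintf("CELL_TYPES %d", m))
  wint(rep(5L, m), 1L)
  if (length(point_fields)) {
    wline(sprintf("POINT_DATA %d", n))
    wline(sprintf("FIELD FieldData %d", length(point_fields)))
    for (nm in names(point_fields)) {
      f <- point_fields[[nm]]
      ncomp <- if (is.matrix(f)) ncol(f) else 1L
      wline(sprintf("%s %d %d double", nm, ncomp, n))
      wnum(as.matrix(f), ncomp)
    }
  }
  invisible(path)
}

#' Read a legacy VTK unstructured grid written by [export_vtk()]
#'
#' Supports the ASCII and binary dialects emitted by this package's writer
#' (POINTS / CELLS / CELL_TYPES / POINT_DATA FIELD sections).
#'
#' @param path `.vtk` file path.
#' @return list with `nodes` (N x 3), `triangles` (M x 3, 1-based), and
#'   `point_fields` (named list).
#' @export
read_vtk <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  rline <- function() {
    chars <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "\n") break
      chars <- c(chars, ch)
    }
    paste(chars, collapse = "")
  }
  header <- rline()
  if (!startsWith(header, "# vtk DataFile")) {
    stop("read_vtk: not a legacy VTK file", call. = FALSE)
  }
  rline()  # title
  mode <- rline()
  ascii <- identical(mode, "ASCII")
  ds <- rline()
  if (!identical(ds, "DATASET UNSTRUCTURED_GRID")) {
    stop("read_vtk: unsupported dataset type '", ds, "'", call. = FALSE)
  }
  rnum <- function(count) {
    if (ascii) {
      vals <- numeric(0)
      while (length(vals) < count) {
        vals <- c(vals, scan(text = rline(), quiet = TRUE))
      }
      vals
    } else {
      v <- readBin(con, "numeric", count, size = 8L, endian = "big")
      rline()  # trailing newline
      v
    }
  }
  rint <- function(count) {
    if (ascii) as.integer(rnum(count))
    else {
      v <- readBin(con, "integer", count, size = 4L, endian = "big")
      rline()
      v
    }
  }

  nodes <- NULL; triangles <- NULL; point_fields <- list()
  repeat {
    ln <- rline()
    if (!nzchar(ln)) {
      if (seek(con) >= file.size(path)) break
      next
    }
    tok <- strsplit(ln, "\\s+")[[1L]]
    if (tok[1L] == "POINTS") {
      n <- as.integer(tok[2L])
      nodes <- matrix(rnum(3L * n), n, 3L, byrow = TRUE)
    } else if (tok[1L] == "CELLS") {
      m <- as.integer(tok[2L])
      raw <- matrix(rint(4L * m), m, 4L, byrow = TRUE)
      triangles <- raw[, 2:4, drop = FALSE] + 1L
    } else if (tok[1L] == "CELL_TYPES") {
      rint(as.integer(tok[2L]))
    } else if (tok[1L] == "POINT_DATA") {
      n_pd <- as.integer(tok[2L])
      fl <- rline()
      ftok <- strsplit(fl, "\\s+")[[1L]]
      k <- as.integer(ftok[3L])
      for (j in seq_len(k)) {
        hd <- strsplit(rline(), "\\s+")[[1L]]
        nm <- hd[1L]; ncomp <- as.integer(hd[2L]); cnt <- as.integer(hd[3L])
        vals <- rnum(ncomp * cnt)
        point_fields[[nm]] <- if (ncomp == 1L) vals
          else matrix(vals, cnt, ncomp, byrow = TRUE)
      }
    }
    if (seek(con) >= file.size(path)) break
  }
  list(nodes = nodes, triangles = triangles, point_fields = point_fields)
}

mat_to_df <- function(m) as.data.frame(m)
df_to_mat <- function(df) unname(as.matrix(df))

#' Save / load a field dataset
#'
#' The dataset container is a directory of Feather arrays (designs, shapes,
#' stresses, mesh tables) plus a JSON manifest carrying the generator seed,
#' configuration, node count, and a format version that is checked on load.
#' Array round trips are lossless.
#'
#' @param dataset a `tav_dataset`.
#' @param path directory path.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "tav_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  arrow::write_feather(dataset$designs, file.path(path, "designs.feather"))
  arrow::write_feather(mat_to_df(dataset$shapes), file.path(path, "shapes.feather"))
  arrow::write_feather(mat_to_df(dataset$stresses), file.path(path, "stresses.feather"))
  m <- dataset$mesh
  arrow::write_feather(
    data.frame(x = m$nodes[, 1L], y = m$nodes[, 2L], u = m$u, v = m$v),
    file.path(path, "mesh_nodes.feather"))
  arrow::write_feather(mat_to_df(m$triangles), file.path(path, "mesh_triangles.feather"))
  meta <- dataset$manifest
  meta$mesh <- list(nu = m$nu, nv = m$nv,
                    attachment_node_ids = m$attachment_node_ids,
                    free_edge_node_ids = m$free_edge_node_ids,
                    commissure_node_ids = m$commissure_node_ids,
                    design = as.list(m$design))
  jsonlite::write_json(meta, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_dataset
#' @return `load_dataset()` returns the restored `tav_dataset`.
#' @export
load_dataset <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    stop("load_dataset: missing manifest.json in '", path, "'", call. = FALSE)
  }
  meta <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (is.null(meta$version) || !identical(meta$version, .DATASET_VERSION)) {
    stop("load_dataset: unsupported dataset version '", meta$version,
         "' (this build reads version ", .DATASET_VERSION, ")", call. = FALSE)
  }
  designs <- as.data.frame(arrow::read_feather(file.path(path, "designs.feather")))
  shapes <- df_to_mat(arrow::read_feather(file.path(path, "shapes.feather")))
  stresses <- df_to_mat(arrow::read_feather(file.path(path, "stresses.feather")))
  nd <- as.data.frame(arrow::read_feather(file.path(path, "mesh_nodes.feather")))
  tri <- df_to_mat(arrow::read_feather(file.path(path, "mesh_triangles.feather")))
  storage.mode(tri) <- "integer"
  mm <- meta$mesh
  mesh <- structure(list(
    nodes = unname(cbind(nd$x, nd$y)),
    triangles = tri, u = nd$u, v = nd$v,
    nu = mm$nu, nv = mm$nv,
    attachment_node_ids = as.integer(mm$attachment_node_ids),
    free_edge_node_ids = as.integer(mm$free_edge_node_ids),
    commissure_node_ids = as.integer(mm$commissure_node_ids),
    design = as.data.frame(mm$design)
  ), class = "tav_mesh")
  manifest <- meta[setdiff(names(meta), "mesh")]
  structure(list(designs = designs, shapes = shapes, stresses = stresses,
                 mesh = mesh, n_nodes = nrow(nd), manifest = manifest),
            class = "tav_dataset")
}

#' Save / load a trained surrogate checkpoint
#'
#' A checkpoint is a directory: `architecture.json` (layer sizes and
#' activations), one Feather array per weight/bias, the standardization
#' constants, and a manifest (kind, format version).
#'
#' @param model a `tav_surrogate`.
#' @param path directory path.
#' @export
save_surrogate <- function(model, path) {
  stopifnot(inherits(model, "tav_surrogate"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(version = .MODEL_VERSION, kind = model$kind,
                   baseline = is.null(model$net))
  if (is.null(model$net)) {
    arrow::write_feather(data.frame(mean_field = model$mean_field),
                         file.path(path, "mean_field.feather"))
  } else {
    jsonlite::write_json(
      list(dims = model$net$spec$dims, acts = model$net$spec$acts,
           kind = model$net$spec$kind),
      file.path(path, "architecture.json"), auto_unbox = TRUE, digits = NA)
    for (l in seq_along(model$net$W)) {
      arrow::write_feather(mat_to_df(model$net$W[[l]]),
                           file.path(path, sprintf("W%02d.feather", l)))
      arrow::write_feather(data.frame(b = as.numeric(model$net$b[[l]])),
                           file.path(path, sprintf("b%02d.feather", l)))
    }
    arrow::write_feather(
      data.frame(center = model$y_scaler$center, scale = model$y_scaler$scale),
      file.path(path, "y_scaler.feather"))
  }
  manifest$space_bounds <- as.data.frame(model$space$bounds)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_surrogate
#' @return `load_surrogate()` returns the restored model.
#' @export
load_surrogate <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) {
    stop("load_surrogate: missing manifest.json in '", path, "'", call. = FALSE)
  }
  meta <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(meta$version, .MODEL_VERSION)) {
    stop("load_surrogate: unsupported checkpoint version '", meta$version, "'",
         call. = FALSE)
  }
  sb <- as.matrix(meta$space_bounds)
  rownames(sb) <- c("a", "b", "ssl")
  space <- design_space(a = sb["a", ], b = sb["b", ], ssl = sb["ssl", ])
  if (isTRUE(meta$baseline)) {
    mf <- as.data.frame(arrow::read_feather(file.path(path, "mean_field.feather")))
    return(structure(list(kind = meta$kind, mean_field = mf$mean_field,
                          space = space, trained = TRUE),
                     class = "tav_surrogate"))
  }
  arch <- jsonlite::read_json(file.path(path, "architecture.json"),
                              simplifyVector = TRUE)
  spec <- new_net_spec(arch$dims, arch$acts, arch$kind)
  L <- length(arch$acts)
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- df_to_mat(arrow::read_feather(file.path(path, sprintf("W%02d.feather", l))))
    b[[l]] <- as.numeric(
      as.data.frame(arrow::read_feather(file.path(path, sprintf("b%02d.feather", l))))$b)
  }
  net <- structure(list(W = W, b = b, act = arch$acts, spec = spec),
                   class = "tav_net")
  ysc <- as.data.frame(arrow::read_feather(file.path(path, "y_scaler.feather")))
  new_surrogate(meta$kind, net, list(center = ysc$center, scale = ysc$scale),
                space)
}

#' Run configuration
#'
#' Bundles every knob of a full pipeline run (design-space bounds, sampling,
#' synthetic generator, training, evaluation) into one serializable object.
#' `save_config()` / `load_config()` round-trip it exactly through JSON
#' (or YAML, by file extension).
#'
#' @param space a [design_space()].
#' @param n_designs,scheme,sample_seed sampling settings.
#' @param synth a [synthetic_config()].
#' @param train a [train_config()].
#' @param rho_list,repeats evaluation settings.
#' @param out_dir output directory.
#' @return An object of class `tav_run_config`.
#' @export
run_config <- function(space = design_space(), n_designs = 984L,
                       scheme = "latin-hypercube", sample_seed = 0L,
                       synth = synthetic_config(), train = train_config(),
                       rho_list = c(50, 70, 90), repeats = 10L,
                       out_dir = "tav_run") {
  structure(list(space = space, n_designs = as.integer(n_designs),
                 scheme = scheme, sample_seed = as.integer(sample_seed),
                 synth = synth, train = train,
                 rho_list = as.numeric(rho_list), repeats = as.integer(repeats),
                 out_dir = out_dir),
            class = "tav_run_config")
}

config_to_list <- function(cfg) {
  list(space = list(a = as.numeric(cfg$space$bounds["a", ]),
                    b = as.numeric(cfg$space$bounds["b", ]),
                    ssl = as.numeric(cfg$space$bounds["ssl", ])),
       n_designs = cfg$n_designs, scheme = cfg$scheme,
       sample_seed = cfg$sample_seed,
       synth = unclass(cfg$synth), train = unclass(cfg$train),
       rho_list = cfg$rho_list, repeats = cfg$repeats, out_dir = cfg$out_dir)
}

list_to_config <- function(x) {
  synth <- x$synth
  ss <- unlist(synth$stress_scale)
  names(ss) <- c("s11", "s22", "s12")
  tr <- x$train
  run_config(
    space = design_space(a = x$space$a, b = x$space$b, ssl = x$space$ssl),
    n_designs = x$n_designs, scheme = x$scheme, sample_seed = x$sample_seed,
    synth = synthetic_config(pressure = synth$pressure, noise_sd = synth$noise_sd,
                             seed = synth$seed, stress_scale = ss,
                             low_rank = isTRUE(synth$low_rank),
                             n_nodes = synth$n_nodes),
    train = train_config(epochs = tr$epochs, batch_size = tr$batch_size,
                         lr = tr$lr, beta1 = tr$beta1, beta2 = tr$beta2,
                         epsilon = tr$epsilon, seed = tr$seed,
                         refit_output = isTRUE(tr$refit_output), ridge = tr$ridge),
    rho_list = x$rho_list, repeats = x$repeats, out_dir = x$out_dir)
}

#' @rdname run_config
#' @param cfg a `tav_run_config`.
#' @param path file path ending in `.json`, `.yaml`, or `.yml`.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "tav_run_config"))
  x <- config_to_list(cfg)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15L)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  list_to_config(x)
}
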
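#' Trajectory, cloud and measure serialization
#'
#' Trajectories are written as plain CSV (`step,t,xi1,xi2,xi3,i`) with a
#' sidecar JSON file of run metadata (switching semantics, parameters, seed,
#' switch steps) and, optionally, a single-column CSV of switch steps.
#' Point clouds and empirical measures are written as `x,y,z[,weight]` CSV.
#' All files are UTF-8, comma-separated, with a header row and no row names.
#'
#' @param traj an `ifs_trajectory`.
#' @param path output CSV path; the metadata file replaces the extension
#'   with `_meta.json`, the jumps file with `_jumps.csv`.
#' @param meta named list of extra metadata (e.g. seed) merged into the JSON.
#' @param jumps also write the switch-step CSV.
#' @return The main CSV path, invisibly.
#' @export
write_trajectory <- function(traj, path, meta = list(), jumps = TRUE) {
  stopifnot(inherits(traj, "ifs_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  base <- sub("\\.csv$", "", path)
  par <- attr(traj, "params")
  par_meta <- if (inherits(par, "ifs_maps"))
    list(kind = "reduced", a = par$reduced$a, b = par$reduced$b,
         c = par$reduced$c)
  else if (inherits(par, "reduced_params"))
    list(kind = "reduced", a = par$a, b = par$b, c = par$c)
  else c(list(kind = "kinetic"), unclass(par))
  info <- c(list(semantics = attr(traj, "semantics"),
                 coordinates = attr(traj, "coordinates"),
                 steps = nrow(traj) - 1L,
                 n_jumps = length(attr(traj, "jump_steps")),
                 params = par_meta), meta)
  jsonlite::write_json(info, paste0(base, "_meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (jumps)
    utils::write.csv(data.frame(jump_step = attr(traj, "jump_steps")),
                     paste0(base, "_jumps.csv"), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("step", "t", "xi1", "xi2", "xi3", "i") %in% names(df)))
  base <- sub("\\.csv$", "", path)
  meta_path <- paste0(base, "_meta.json")
  jumps_path <- paste0(base, "_jumps.csv")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  js <- if (file.exists(jumps_path))
    utils::read.csv(jumps_path)$jump_step else which(diff(df$i) != 0)
  .new_trajectory(df, meta$params, meta$semantics %||% NA_character_,
                  js, meta$coordinates %||% NA_character_)
}

#' @param cloud a [point_cloud()] or [empirical_measure()].
#' @rdname write_trajectory
#' @export
write_point_cloud <- function(cloud, path) {
  if (inherits(cloud, "empirical_measure")) {
    df <- data.frame(x = cloud$points[, 1], y = cloud$points[, 2],
                     z = cloud$points[, 3], weight = cloud$weights)
  } else {
    m <- .cloud_matrix(cloud)
    df <- data.frame(x = m[, 1], y = m[, 2], z = m[, 3])
    w <- attr(cloud, "weights")
    if (!is.null(w)) df$weight <- w
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_point_cloud <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  point_cloud(as.matrix(df[, c("x", "y", "z")]), weights = df$weight)
}

#' Write a point set or a parametric surface mesh as ASCII PLY
#'
#' Minimal PLY writer for 3-D viewers: vertices only for a cloud, vertices
#' plus quad faces for a surface evaluated on an (alpha, beta) grid.
#'
#' @param vertices n x 3 numeric matrix.
#' @param path output path.
#' @param grid_dims optional `c(n_alpha, n_beta)`; when given, quad faces are
#'   emitted assuming the vertices enumerate a regular grid column-major.
#' @return `path`, invisibly.
#' @export
write_ply <- function(vertices, path, grid_dims = NULL) {
  if (!is.matrix(vertices)) vertices <- matrix(vertices, ncol = 3)
  n <- nrow(vertices)
  faces <- NULL
  if (!is.null(grid_dims)) {
    na <- grid_dims[1]; nb <- grid_dims[2]
    stopifnot(na * nb == n)
    idx <- matrix(seq_len(n) - 1L, na, nb)
    faces <- do.call(rbind, lapply(seq_len(nb - 1L), function(j) {
      cbind(idx[-na, j], idx[-1, j], idx[-1, j + 1], idx[-na, j + 1])
    }))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", n),
               "property float x", "property float y", "property float z",
               if (!is.null(faces)) paste("element face", nrow(faces)),
               if (!is.null(faces)) "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(vertices, 1, paste, collapse = " "), con)
  if (!is.null(faces))
    writeLines(paste(4, faces[, 1], faces[, 2], faces[, 3], faces[, 4]), con)
  invisible(path)
}
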
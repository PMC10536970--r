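#' @title File interfaces
#' @description Standard XYZ (Angstrom on disk, Bohr in memory) with an
#'   extended variant carrying per-atom force columns in nN; a documented
#'   JSON schema for model surfaces; finite-difference Hessians from a
#'   gradient callable; YAML run configuration; JSON run manifests. All
#'   conversion happens at the I/O boundary only.
#' @name interfaces
NULL

#' Read a (possibly extended) XYZ file
#'
#' Standard layout: atom-count line, comment line, then one
#' `element x y z` row per atom (Angstrom); the extended variant appends
#' three force columns (nN). Malformed counts or rows raise an error
#' naming the line.
#'
#' @param path file path.
#' @return a [geometry()] (coordinates in Bohr); when force columns are
#'   present, attribute `forces` holds the 3N vector in Hartree/Bohr and
#'   attribute `comment` the comment line.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  if (length(lines) < 2) stop("XYZ file too short: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop("line 1: invalid atom count '", lines[1], "'", call. = FALSE)
  if (length(lines) < n + 2)
    stop("count line says ", n, " atoms but only ", length(lines) - 2,
         " atom rows are present", call. = FALSE)
  rows <- lines[3:(n + 2)]
  atoms <- character(n)
  coords <- numeric(3 * n)
  forces <- NULL
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(rows[i]), "\\s+")[[1]]
    if (!(length(tok) %in% c(4L, 7L)))
      stop("line ", i + 2, ": expected 4 or 7 fields, got ", length(tok),
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(tok[-1]))
    if (anyNA(vals))
      stop("line ", i + 2, ": non-numeric coordinate/force field",
           call. = FALSE)
    atoms[i] <- tok[1]
    coords[(3 * i - 2):(3 * i)] <- vals[1:3]
    if (length(tok) == 7L) {
      if (is.null(forces)) forces <- numeric(3 * n)
      forces[(3 * i - 2):(3 * i)] <- vals[4:6]
    }
  }
  g <- geometry(unit_convert(coords, "Angstrom", "Bohr"), atoms)
  if (!is.null(forces))
    attr(g, "forces") <- unit_convert(forces, "nN", "Hartree/Bohr")
  attr(g, "comment") <- lines[2]
  g
}

.format_xyz_frame <- function(geom, forces = NULL, comment = "") {
  stopifnot(length(geom$atoms) > 0)
  n <- length(geom$atoms)
  xyz <- matrix(unit_convert(geom$coords, "Bohr", "Angstrom"), ncol = 3,
                byrow = TRUE)
  if (is.null(forces)) {
    rows <- sprintf("%-3s %16.8f %16.8f %16.8f", geom$atoms,
                    xyz[, 1], xyz[, 2], xyz[, 3])
  } else {
    fn <- matrix(unit_convert(as.numeric(forces), "Hartree/Bohr", "nN"),
                 ncol = 3, byrow = TRUE)
    rows <- sprintf("%-3s %16.8f %16.8f %16.8f %16.8f %16.8f %16.8f",
                    geom$atoms, xyz[, 1], xyz[, 2], xyz[, 3],
                    fn[, 1], fn[, 2], fn[, 3])
  }
  c(as.character(n), comment, rows)
}

#' Write a geometry as (extended) XYZ
#'
#' @param path output path.
#' @param geom a [geometry()] with atoms.
#' @param forces optional 3N force vector (Hartree/Bohr), written as
#'   three extra per-atom columns in nN.
#' @param comment comment line.
#' @return invisibly, `path`.
#' @export
write_xyz <- function(path, geom, forces = NULL, comment = "") {
  writeLines(.format_xyz_frame(geom, forces, comment), path)
  invisible(path)
}

#' Write a multi-frame extended-XYZ trajectory
#'
#' @param path output path.
#' @param geoms list of [geometry()]s.
#' @param forces optional list of 3N force vectors (Hartree/Bohr).
#' @param comments character vector of per-frame comments.
#' @return invisibly, `path`.
#' @export
write_xyz_trajectory <- function(path, geoms, forces = NULL,
                                 comments = NULL) {
  out <- unlist(lapply(seq_along(geoms), function(i) {
    .format_xyz_frame(geoms[[i]],
                      if (!is.null(forces)) forces[[i]],
                      if (!is.null(comments)) comments[i] else "")
  }))
  writeLines(out, path)
  invisible(path)
}

#' Finite-difference Hessian from a gradient callable
#'
#' Central differences column by column, symmetrized by averaging; on a
#' quadratic surface the result is exact to round-off, and the truncation
#' error elsewhere is second order in the step.
#'
#' @param gradient_fn function taking a coordinate vector and returning
#'   the gradient.
#' @param q geometry or coordinate vector.
#' @param step displacement per coordinate (Bohr), default 1e-3.
#' @return symmetric matrix.
#' @export
finite_difference_hessian <- function(gradient_fn, q, step = 1e-3) {
  x <- .as_coords(q)
  n <- length(x)
  h <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xp <- x; xp[i] <- xp[i] + step
    xm <- x; xm[i] <- xm[i] - step
    col <- tryCatch((gradient_fn(xp) - gradient_fn(xm)) / (2 * step),
                    error = function(e)
                      stop("gradient evaluation failed while displacing ",
                           "coordinate ", i, ": ", conditionMessage(e),
                           call. = FALSE))
    if (length(col) != n)
      stop("gradient callable returned length ", length(col),
           " at coordinate ", i, ", expected ", n, call. = FALSE)
    h[, i] <- col
  }
  .sympart(h)
}

# ---- surface JSON schema ----------------------------------------------------

.surface_to_list <- function(s) {
  if (inherits(s, "quadratic_surface")) {
    list(type = "quadratic",
         units = list(energy = "Hartree", length = "Bohr"),
         q_ref = s$q_ref$coords, atoms = s$q_ref$atoms,
         e_ref = s$e_ref, g_ref = s$g_ref,
         h_ref = as.numeric(t(s$h_ref)),   # row-major
         n_dof = s$n_dof)
  } else if (inherits(s, "morse_surface")) {
    list(type = "morse-sum",
         units = list(energy = "Hartree", length = "Bohr"),
         D = s$D, a = s$a, center = s$center$coords,
         atoms = s$center$atoms, e0 = s$e0, n_dof = s$n_dof)
  } else if (inherits(s, "quartic_surface")) {
    list(type = "quartic-perturbed-quadratic",
         units = list(energy = "Hartree", length = "Bohr"),
         h = as.numeric(t(s$h)), c4 = s$c4, center = s$center$coords,
         atoms = s$center$atoms, e0 = s$e0, n_dof = s$n_dof)
  } else if (inherits(s, "poly_surface")) {
    list(type = "polynomial",
         units = list(energy = "Hartree", length = "Bohr"),
         powers = as.numeric(t(s$powers)), n_terms = nrow(s$powers),
         coef = s$coef, origin = s$origin$coords,
         atoms = s$origin$atoms, n_dof = s$n_dof)
  } else {
    stop("surface of class ", class(s)[1], " is not serializable",
         call. = FALSE)
  }
}

.surface_from_list <- function(x) {
  n <- x$n_dof
  atoms <- as.character(x$atoms %||% character())
  rowmajor <- function(v, nr, nc) matrix(as.numeric(v), nr, nc, byrow = TRUE)
  switch(x$type,
    "quadratic" = quadratic_surface(
      geometry(x$q_ref, atoms), x$e_ref, x$g_ref, rowmajor(x$h_ref, n, n)),
    "morse-sum" = morse_surface(x$D, x$a, geometry(x$center, atoms), x$e0),
    "quartic-perturbed-quadratic" = quartic_surface(
      rowmajor(x$h, n, n), x$c4, geometry(x$center, atoms), x$e0),
    "polynomial" = poly_surface(
      rowmajor(x$powers, x$n_terms, n), x$coef, geometry(x$origin, atoms)),
    stop("unknown surface type '", x$type, "'", call. = FALSE))
}

#' Serialize a two-state pair to / from JSON
#'
#' Schema: an object with `state0` and `state1`, each carrying a `type`
#' tag, a `units` field (always Hartree/Bohr), the reference point, and
#' the type-specific parameters; matrices are stored row-major.
#'
#' @param pes a [two_state_pes()] of serializable surfaces.
#' @param path output (input) file path.
#' @return `write_pes_json`: invisibly `path`; `read_pes_json`: a
#'   [two_state_pes()].
#' @export
write_pes_json <- function(pes, path) {
  obj <- list(schema = "lgmf-two-state-pes-1",
              state0 = .surface_to_list(pes$state0),
              state1 = .surface_to_list(pes$state1),
              q_ref = pes$q_ref$coords)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pes_json
#' @export
read_pes_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "lgmf-two-state-pes-1"))
    stop("not a recognized two-state surface file: ", path, call. = FALSE)
  two_state_pes(.surface_from_list(x$state0), .surface_from_list(x$state1),
                q_ref = geometry(x$q_ref,
                                 as.character(x$state0$atoms %||% character())))
}

# ---- run configuration and manifest ----------------------------------------

#' Read a YAML run configuration
#'
#' Keys: `mode` (`quad-scan`, `lgmf-ramp` or `fixtures`), exactly one
#' surface source (`surface_json` or `backend`), an optional `lgmf` block
#' (passed to [lgmf_config()]), an optional `lambda_grid` block
#' (`from`, `to`, `n`), `output_dir`, `log_level`.
#'
#' @param path YAML file.
#' @return validated list of class `"lgmf_run_config"`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$mode) ||
      !x$mode %in% c("quad-scan", "lgmf-ramp", "fixtures"))
    stop("config must set mode to quad-scan, lgmf-ramp or fixtures",
         call. = FALSE)
  n_src <- sum(!is.null(x$surface_json), !is.null(x$backend))
  if (x$mode != "fixtures" && n_src != 1L)
    stop("config must name exactly one surface source ",
         "(surface_json or backend), found ", n_src, call. = FALSE)
  if (x$mode == "quad-scan" && is.null(x$lambda_grid))
    stop("mode quad-scan requires a lambda_grid block", call. = FALSE)
  x$output_dir <- x$output_dir %||% "."
  x$log_level <- x$log_level %||% "info"
  class(x) <- "lgmf_run_config"
  x
}

#' Write a JSON run manifest
#'
#' Echoes the resolved configuration plus per-ramp termination reasons
#' and per-point diagnostics so a run is reproducible and inspectable.
#'
#' @param path output path.
#' @param config the [lgmf_config()] (or lambda grid description) used.
#' @param ramps named list of `"force_ramp"`s.
#' @param extra optional named list merged into the manifest.
#' @return invisibly, `path`.
#' @export
write_run_manifest <- function(path, config, ramps, extra = list()) {
  ramp_info <- lapply(ramps, function(r) {
    list(branch = r$branch, termination_reason = r$termination_reason,
         n_points = length(r$points),
         points = as.data.frame(r))
  })
  obj <- c(list(package = "lgmf",
                config = unclass(config),
                ramps = ramp_info),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
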
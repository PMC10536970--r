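#' Molecular or abstract geometry
#'
#' A point in the configuration space the two surfaces share: a numeric
#' coordinate vector of length 3N (Bohr internally), optionally annotated
#' with element symbols when the coordinates are atomic Cartesians.
#' Abstract model surfaces use an empty `atoms` vector.
#'
#' @param coords numeric vector of coordinates (Bohr).
#' @param atoms character vector of element symbols; if nonempty its length
#'   must be `length(coords) / 3`.
#' @return object of class `"geometry"` with fields `coords`, `atoms`,
#'   `n_dof`.
#' @examples
#' geometry(c(0, 0, 0, 1.8, 0, 0), atoms = c("O", "H"))
#' geometry(c(0.1, -0.2))   # abstract 2-dof space
#' @export
geometry <- function(coords, atoms = character()) {
  coords <- as.numeric(coords)
  if (length(coords) < 1L || anyNA(coords))
    stop("coordinates must be a nonempty numeric vector", call. = FALSE)
  atoms <- as.character(atoms)
  if (length(atoms) > 0L && length(coords) != 3L * length(atoms))
    stop("with ", length(atoms), " atoms the coordinate vector must have ",
         3L * length(atoms), " components, got ", length(coords),
         call. = FALSE)
  structure(list(coords = coords, atoms = atoms, n_dof = length(coords)),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  if (length(x$atoms)) {
    cat("<geometry> ", length(x$atoms), " atoms (",
        paste(x$atoms, collapse = " "), "), ", x$n_dof, " dof\n", sep = "")
  } else {
    cat("<geometry> abstract, ", x$n_dof, " dof\n", sep = "")
  }
  invisible(x)
}

# accept either a geometry or a bare numeric vector everywhere
.as_coords <- function(q) {
  if (inherits(q, "geometry")) q$coords else as.numeric(q)
}

.as_geometry <- function(q, atoms = character()) {
  if (inherits(q, "geometry")) q else geometry(q, atoms)
}

.check_dim <- function(surface_dim, q, what = "surface") {
  n <- length(.as_coords(q))
  if (n != surface_dim)
    stop("dimension mismatch: ", what, " has ", surface_dim,
         " dof but geometry has ", n, call. = FALSE)
  invisible(n)
}
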
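#' @title Molecular-frame utilities
#' @description Projection onto the complement of rigid-body motions,
#'   construction of experimentally realizable force pairs, and
#'   least-squares decomposition of an optimal force over a force-pair
#'   dictionary.
#' @name mech_utils
NULL

#' Translation/rotation null-space projector
#'
#' Orthogonal projector onto the complement of the rigid-body subspace:
#' three uniform translations plus the small-rotation generators
#' linearized at the instantaneous geometry (two for collinear
#' molecules). Overall translations and infinitesimal rotations carry no
#' internal force, so meaningful applied-force vectors live in the range
#' of this projector.
#'
#' @param geom a [geometry()] with at least two atoms.
#' @return symmetric idempotent 3N x 3N matrix.
#' @export
tr_projector <- function(geom) {
  geom <- .as_geometry(geom)
  na <- length(geom$atoms)
  if (na < 2)
    stop("translation/rotation projection needs at least two atoms",
         call. = FALSE)
  n <- geom$n_dof
  r <- matrix(geom$coords, ncol = 3, byrow = TRUE)
  rc <- sweep(r, 2, colMeans(r))
  gen <- matrix(0, n, 6)
  for (k in 1:3) gen[seq(k, n, by = 3), k] <- 1          # translations
  for (k in 1:3) {                                       # rotations e_k x r
    ax <- c(0, 0, 0); ax[k] <- 1
    v <- t(apply(rc, 1, function(ri) c(ax[2] * ri[3] - ax[3] * ri[2],
                                       ax[3] * ri[1] - ax[1] * ri[3],
                                       ax[1] * ri[2] - ax[2] * ri[1])))
    gen[, 3 + k] <- as.numeric(t(v))
  }
  sv <- svd(gen)
  keep <- sv$d > 1e-8 * max(sv$d)
  basis <- sv$u[, keep, drop = FALSE]
  diag(n) - tcrossprod(basis)
}

#' Force-pair vector
#'
#' Equal and opposite forces on two atoms along their connecting axis:
#' the building block of experimentally applicable molecular forces.
#' `"pulling"` stretches the pair (forces directed outward along the
#' axis), `"pushing"` compresses it. Net force and net torque vanish by
#' construction.
#'
#' @param geom a [geometry()] with atoms.
#' @param i,j distinct atom indices.
#' @param magnitude force magnitude on each atom (any force unit; the
#'   output is in the same unit).
#' @param sign `"pulling"` or `"pushing"`.
#' @return 3N force vector.
#' @export
force_pair_vector <- function(geom, i, j, magnitude = 1,
                              sign = c("pulling", "pushing")) {
  sign <- match.arg(sign)
  geom <- .as_geometry(geom)
  na <- length(geom$atoms)
  if (na < 2) stop("force pairs require an atomic geometry", call. = FALSE)
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("force-pair atoms must be distinct", call. = FALSE)
  if (min(i, j) < 1 || max(i, j) > na)
    stop("atom index out of range", call. = FALSE)
  r <- matrix(geom$coords, ncol = 3, byrow = TRUE)
  axis <- r[j, ] - r[i, ]
  d <- sqrt(sum(axis^2))
  if (d < 1e-10)
    stop("atoms ", i, " and ", j, " are coincident: pair axis undefined",
         call. = FALSE)
  u <- axis / d
  s <- if (sign == "pulling") -1 else 1   # pulling: force on i away from j
  f <- numeric(geom$n_dof)
  f[(3 * i - 2):(3 * i)] <- s * magnitude * u
  f[(3 * j - 2):(3 * j)] <- -s * magnitude * u
  f
}

#' Decompose a force over a force-pair dictionary
#'
#' Least-squares coefficients of the translation/rotation-projected
#' target force over unit-magnitude pulling pair vectors, with the
#' residual norm quantifying how well the candidate pairs realize the
#' force (system dependent). A rank-deficient dictionary falls back to
#' the minimum-norm solution with a warning.
#'
#' @param f 3N target force vector.
#' @param geom a [geometry()] with atoms.
#' @param pairs two-column matrix (or list of length-2 vectors) of atom
#'   index pairs.
#' @return list: `coefficients` (data frame `atom_i`, `atom_j`,
#'   `coefficient`), `residual_norm`, `ranking` (pair order by absolute
#'   contribution), `projected_force`.
#' @export
decompose_into_pairs <- function(f, geom, pairs) {
  geom <- .as_geometry(geom)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2 || nrow(pairs) < 1)
    stop("pairs must be a nonempty two-column index matrix", call. = FALSE)
  proj <- tr_projector(geom)
  fp <- drop(proj %*% as.numeric(f))
  d <- vapply(seq_len(nrow(pairs)),
              function(k) force_pair_vector(geom, pairs[k, 1], pairs[k, 2]),
              numeric(geom$n_dof))
  d <- matrix(d, nrow = geom$n_dof)
  sv <- svd(d)
  rank <- sum(sv$d > 1e-10 * max(sv$d))
  if (rank < ncol(d)) {
    warning("force-pair dictionary is rank deficient (rank ", rank,
            " of ", ncol(d), "); returning the minimum-norm solution")
    dinv <- sv$v[, seq_len(rank), drop = FALSE] %*%
      ((1 / sv$d[seq_len(rank)]) *
         t(sv$u[, seq_len(rank), drop = FALSE]))
    x <- drop(dinv %*% fp)
  } else {
    x <- drop(qr.coef(qr(d), fp))
  }
  res <- .norm2(fp - drop(d %*% x))
  list(coefficients = data.frame(atom_i = pairs[, 1], atom_j = pairs[, 2],
                                 coefficient = x),
       residual_norm = res,
       ranking = order(abs(x), decreasing = TRUE),
       projected_force = fp)
}

#' Export a pair decomposition as CSV
#'
#' Columns: `atom_i`, `atom_j`, `coefficient_nN`, `cumulative_residual`
#' (residual norm, in nN, after keeping the pairs up to and including
#' each row, ranked by contribution).
#'
#' @param decomposition result of [decompose_into_pairs()] computed on a
#'   force in Hartree/Bohr.
#' @param geom the geometry used.
#' @param pairs the index pairs used.
#' @param path output path.
#' @return invisibly, the data frame written.
#' @export
export_pair_decomposition <- function(decomposition, geom, pairs, path) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  x <- decomposition$coefficients$coefficient
  ord <- decomposition$ranking
  d <- vapply(seq_len(nrow(pairs)),
              function(k) force_pair_vector(geom, pairs[k, 1], pairs[k, 2]),
              numeric(.as_geometry(geom)$n_dof))
  d <- matrix(d, nrow = .as_geometry(geom)$n_dof)
  cum <- vapply(seq_along(ord), function(m) {
    keep <- ord[seq_len(m)]
    .norm2(decomposition$projected_force -
             drop(d[, keep, drop = FALSE] %*% x[keep]))
  }, 0)
  df <- data.frame(
    atom_i = pairs[ord, 1], atom_j = pairs[ord, 2],
    coefficient_nN = unit_convert(x[ord], "Hartree/Bohr", "nN"),
    cumulative_residual = unit_convert(cum, "Hartree/Bohr", "nN"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
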
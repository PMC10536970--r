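#' @title Force ramps
#' @description Ordered families of optimal points for one continuation
#'   branch (gap-increasing or gap-decreasing), shared by the closed-form
#'   lambda scan and the iterative engine.
#' @name ramp
NULL

new_force_ramp <- function(branch, points, termination_reason = "ceiling",
                           source = "lgmf") {
  structure(list(branch = branch, points = points,
                 termination_reason = termination_reason, source = source),
            class = "force_ramp")
}

#' Ramp summary table
#'
#' @param x a `"force_ramp"`.
#' @param row.names,optional,... ignored (data.frame method contract).
#' @return data.frame with one row per point: `index`, `branch`,
#'   `force` (Hartree/Bohr), `force_nN`, `gap_variation` (Hartree),
#'   `gap_variation_kcalmol`, `cos_alpha`, and — where the source
#'   provides them — `lambda`, `singular_flag`, `n_corrector_iters`,
#'   `verified`.
#' @export
as.data.frame.force_ramp <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  pts <- x$points
  getn <- function(field, default = NA_real_) {
    vapply(pts, function(p) {
      v <- p[[field]]
      if (is.null(v)) default else as.numeric(v)
    }, 0)
  }
  df <- data.frame(
    index = seq_along(pts),
    branch = rep(x$branch, length(pts)),
    force = getn("force_magnitude"),
    gap_variation = getn("gap_variation"),
    cos_alpha = getn("cos_alpha")
  )
  df$force_nN <- unit_convert(df$force, "Hartree/Bohr", "nN")
  df$gap_variation_kcalmol <- unit_convert(df$gap_variation, "Hartree",
                                           "kcal/mol")
  if (x$source == "lambda_scan") {
    df$lambda <- getn("lambda")
    df$singular_flag <- vapply(pts, function(p) isTRUE(p$singular_flag), TRUE)
  } else {
    df$n_corrector_iters <- getn("n_corrector_iters", 0)
    df$verified <- vapply(pts, function(p) isTRUE(p$verified_exact), TRUE)
  }
  df
}

#' @export
print.force_ramp <- function(x, ...) {
  cat("<force_ramp> ", x$branch, " branch, ", length(x$points),
      " points (", x$source, "), termination: ", x$termination_reason,
      "\n", sep = "")
  print(utils::head(as.data.frame(x), 8))
  if (length(x$points) > 8) cat("...\n")
  invisible(x)
}

#' Export a ramp as CSV (plus optional extended-XYZ trajectory)
#'
#' CSV columns follow the fixed contract: `index`, `branch`, `force_nN`,
#' `gap_variation_kcalmol`, `cos_alpha`, plus `lambda`/`singular_flag`
#' for scans or `n_corrector_iters`/`verified` for engine ramps. When the
#' ramp geometries carry atoms and `xyz_path` is given, the optimal
#' structures are written as an extended-XYZ trajectory with per-atom
#' force columns.
#'
#' @param ramp a `"force_ramp"`.
#' @param path CSV output path.
#' @param xyz_path optional extended-XYZ trajectory path.
#' @return invisibly, the data frame written.
#' @export
export_ramp_csv <- function(ramp, path, xyz_path = NULL) {
  df <- as.data.frame(ramp)
  keep <- intersect(c("index", "branch", "force_nN",
                      "gap_variation_kcalmol", "cos_alpha", "lambda",
                      "singular_flag", "n_corrector_iters", "verified"),
                    names(df))
  utils::write.csv(df[keep], path, row.names = FALSE, quote = FALSE)
  if (!is.null(xyz_path)) {
    geoms <- lapply(ramp$points, function(p) p$q %||% p$q_opt)
    forces <- lapply(ramp$points, function(p) p$force_vector)
    ok <- !vapply(geoms, is.null, TRUE)
    write_xyz_trajectory(xyz_path, geoms[ok], forces[ok],
                         comments = sprintf("force_nN=%.8g",
                                            df$force_nN[ok]))
  }
  invisible(df[keep])
}
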
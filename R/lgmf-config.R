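#' LGMF run configuration
#'
#' Controls of the iterative optimal-force ramp. Force quantities may be
#' given in `"nN"` (reporting convention) or `"Hartree/Bohr"` (internal);
#' they are stored internally in atomic units.
#'
#' @param force_step increment of the applied force magnitude between
#'   consecutive optimized points; the control parameter. Default 0.05 nN
#'   (tens-to-hundreds of pN), small enough that the local second-order
#'   model stays valid between points.
#' @param force_max ramp ceiling; default 2 nN, the range over which the
#'   rigid-molecule studies ramp.
#' @param force_unit unit of `force_step`/`force_max`.
#' @param cos_tolerance convergence threshold on `|cos(grad dE,
#'   grad ||F||^2)|`; the practical criterion lies between 0.99 and
#'   0.999 (default), values up to 1 are accepted for high-precision
#'   validation runs.
#' @param force_budget permitted relative deviation of the achieved from
#'   the scheduled force magnitude, in (0, 0.05]; default the 5% rule.
#' @param corrector_constant initial proportionality constant of the
#'   corrector displacement; adapted on the fly (halved when the
#'   perpendicular gap-gradient grows, doubled after three consecutive
#'   decreases).
#' @param corrector_max_iter iteration cap of the corrector.
#' @param hessian_policy `"exact-every-point"` (re-evaluate both Hessians
#'   at each expansion) or `"bfgs"` (rank-two quasi-Newton updates from
#'   gradient differences, exact only at the start or when an update's
#'   curvature condition fails).
#' @param max_reexpand cap on re-expansions after a failed exact
#'   verification or force-budget violation at one scheduled force.
#' @param seed integer; only ever used by fixture generation, never by
#'   the optimizer, which is deterministic given its inputs.
#' @return object of class `"lgmf_config"`.
#' @export
lgmf_config <- function(force_step = 0.05, force_max = 2,
                        force_unit = "nN",
                        cos_tolerance = 0.999, force_budget = 0.05,
                        corrector_constant = 1.0,
                        corrector_max_iter = 200,
                        hessian_policy = c("exact-every-point", "bfgs"),
                        max_reexpand = 25, seed = 1L) {
  hessian_policy <- match.arg(hessian_policy)
  force_step <- unit_convert(force_step, force_unit, "Hartree/Bohr")
  force_max <- unit_convert(force_max, force_unit, "Hartree/Bohr")
  if (!(force_step > 0)) stop("force_step must be > 0", call. = FALSE)
  if (force_max < 0) stop("force_max must be >= 0", call. = FALSE)
  if (cos_tolerance < 0.99 || cos_tolerance > 1)
    stop("cos_tolerance must lie in [0.99, 1]", call. = FALSE)
  if (!(force_budget > 0 && force_budget <= 0.05))
    stop("force_budget must lie in (0, 0.05]", call. = FALSE)
  if (corrector_constant <= 0) stop("corrector_constant must be > 0",
                                    call. = FALSE)
  structure(list(force_step = force_step, force_max = force_max,
                 cos_tolerance = cos_tolerance, force_budget = force_budget,
                 corrector_constant = corrector_constant,
                 corrector_max_iter = as.integer(corrector_max_iter),
                 hessian_policy = hessian_policy,
                 max_reexpand = as.integer(max_reexpand),
                 seed = as.integer(seed)),
            class = "lgmf_config")
}

#' @export
print.lgmf_config <- function(x, ...) {
  cat("<lgmf_config>\n",
      "  force_step  ", format(unit_convert(x$force_step, "Hartree/Bohr", "nN")),
      " nN\n",
      "  force_max   ", format(unit_convert(x$force_max, "Hartree/Bohr", "nN")),
      " nN\n",
      "  cos_tolerance ", x$cos_tolerance,
      ", force_budget ", x$force_budget, "\n",
      "  corrector: constant ", x$corrector_constant,
      ", max_iter ", x$corrector_max_iter, "\n",
      "  hessian_policy ", x$hessian_policy, "\n", sep = "")
  invisible(x)
}

.lgmf_log <- function(...) {
  if (isTRUE(getOption("lgmf.verbose", FALSE))) message(...)
}
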
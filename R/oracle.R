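#' Dense constrained-search oracle (1 or 2 degrees of freedom)
#'
#' Independent check of the optimizers: extracts the level set
#' `||grad E0(q)|| = force_magnitude` around the state-0 minimum by radial
#' root finding along a dense fan of directions, evaluates the gap
#' variation on it, and polishes the best direction with a golden-section
#' refinement. Restricted to <= 2 dof by design; higher-dimensional
#' validation goes through the closed-form quadratic solver instead.
#'
#' @param pes a [two_state_pes()] with `n_dof <= 2` whose state 0 has a
#'   minimum at the pes reference.
#' @param force_magnitude target external-force magnitude (Hartree/Bohr).
#' @param resolution number of angular samples (2D); ignored in 1D.
#' @param box half-width of the search box around the reference (Bohr).
#' @return list with elements `increase` and `decrease`, each a list
#'   `(q, gap_variation, force_magnitude, branch)`.
#' @export
brute_force_optimum <- function(pes, force_magnitude, resolution = 720,
                                box = 4) {
  n <- pes$n_dof
  if (n > 2)
    stop("brute_force_optimum supports at most 2 dof, got ", n, call. = FALSE)
  if (force_magnitude < 0) stop("force_magnitude must be >= 0", call. = FALSE)
  q0 <- pes$q_ref$coords

  if (force_magnitude == 0) {
    pt <- list(q = geometry(q0, pes$q_ref$atoms), gap_variation = 0,
               force_magnitude = 0)
    return(list(increase = c(pt, branch = "increase"),
                decrease = c(pt, branch = "decrease")))
  }

  fmag <- function(q) sqrt(sum(surface_eval(pes$state0, q)$gradient^2))

  # smallest radius along direction u with ||grad E0|| = F, NA if unreachable
  radial_root <- function(u) {
    f <- function(r) fmag(q0 + r * u) - force_magnitude
    rs <- seq(0, box, length.out = 65)
    vals <- vapply(rs, f, 0)
    k <- which(vals[-1] * vals[-length(vals)] <= 0)[1]
    if (is.na(k)) return(NA_real_)
    stats::uniroot(f, c(rs[k], rs[k + 1]), tol = 1e-13)$root
  }

  gap_at_dir <- function(u) {
    r <- radial_root(u)
    if (is.na(r)) return(NA_real_)
    gap_variation(pes, q0 + r * u)
  }

  if (n == 1) {
    dirs <- list(1, -1)
    gv <- vapply(dirs, function(u) gap_at_dir(u), 0)
    if (all(is.na(gv)))
      stop("constraint unreachable: no point with the requested force ",
           "magnitude inside the search box", call. = FALSE)
    pack <- function(i, branch) {
      u <- dirs[[i]]; r <- radial_root(u)
      list(q = geometry(q0 + r * u, pes$q_ref$atoms),
           gap_variation = gv[i], force_magnitude = force_magnitude,
           branch = branch)
    }
    return(list(increase = pack(which.max(gv), "increase"),
                decrease = pack(which.min(gv), "decrease")))
  }

  theta <- seq(0, 2 * pi, length.out = resolution + 1)[-(resolution + 1)]
  gv <- vapply(theta, function(t) gap_at_dir(c(cos(t), sin(t))), 0)
  if (all(is.na(gv)))
    stop("constraint unreachable: no point with the requested force ",
         "magnitude inside the search box", call. = FALSE)

  polish <- function(i0, maximize) {
    t0 <- theta[i0]; w <- 2 * pi / resolution
    f <- function(t) {
      g <- gap_at_dir(c(cos(t), sin(t)))
      if (is.na(g)) if (maximize) -Inf else Inf else g
    }
    opt <- stats::optimize(f, c(t0 - w, t0 + w), maximum = maximize,
                           tol = 1e-12)
    t_best <- if (maximize) opt$maximum else opt$minimum
    u <- c(cos(t_best), sin(t_best))
    r <- radial_root(u)
    list(q = geometry(q0 + r * u, pes$q_ref$atoms),
         gap_variation = gap_variation(pes, q0 + r * u),
         force_magnitude = force_magnitude,
         branch = if (maximize) "increase" else "decrease")
  }

  list(increase = polish(which.max(gv), TRUE),
       decrease = polish(which.min(gv), FALSE))
}
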
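#' @title Seeded model-surface generators
#' @description Deterministic fixtures for validating the solvers: random
#'   quadratic state pairs built by spectral synthesis (random orthogonal
#'   eigenbasis times a prescribed eigenvalue spectrum, so conditioning is
#'   controlled), and an anharmonic 2D pair with one soft and one stiff
#'   direction reproducing the low-frequency failure mode of the single
#'   second-order approach. Defaults mimic typical molecular scales: force
#'   constants of a few tenths to ~1.5 Hartree/Bohr^2, an excited-state
#'   gradient of ~0.1 Hartree/Bohr and a vertical gap near 140 kcal/mol.
#' @name fixtures
NULL

# run code under a local RNG stream without disturbing the caller's
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Haar-ish random orthogonal matrix via QR with sign fix
.random_orthogonal <- function(n) {
  qr_ <- qr(matrix(stats::rnorm(n * n), n, n))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))), n)
}

.random_spd_hessian <- function(n, spectrum) {
  ev <- stats::runif(n, spectrum[1], spectrum[2])
  u <- .random_orthogonal(n)
  .sympart(u %*% (ev * t(u)))
}

#' Seeded random quadratic two-state pair
#'
#' State 0 is a positive-definite quadratic with its minimum at the origin
#' and zero gradient (the precondition of the closed-form solver); state 1
#' is a quadratic with a random symmetric Hessian whose eigenvalues lie in
#' `spectrum1` and a random-direction gradient of norm `g1_scale`.
#' Identical seeds give bit-identical pairs.
#'
#' @param n_dof dimension (>= 1).
#' @param seed integer seed.
#' @param spectrum0 eigenvalue range for the state-0 Hessian; the lower
#'   bound must be positive.
#' @param spectrum1 eigenvalue range for the state-1 Hessian.
#' @param g1_scale norm of the state-1 gradient at the reference
#'   (Hartree/Bohr).
#' @param gap0 vertical gap at the reference (Hartree); the default is
#'   roughly a 140 kcal/mol excitation.
#' @return a [two_state_pes()] of two [quadratic_surface()]s.
#' @export
make_quadratic_pair <- function(n_dof, seed,
                                spectrum0 = c(0.2, 1.5),
                                spectrum1 = c(0.15, 1.8),
                                g1_scale = 0.1,
                                gap0 = 0.223) {
  stopifnot(n_dof >= 1)
  if (spectrum0[1] <= 0)
    stop("spectrum0 lower bound must be positive: state 0 must be expanded ",
         "at a true minimum", call. = FALSE)
  .with_seed(seed, {
    h0 <- .random_spd_hessian(n_dof, spectrum0)
    h1 <- .random_spd_hessian(n_dof, spectrum1)
    g1 <- stats::rnorm(n_dof)
    nrm <- sqrt(sum(g1^2))
    g1 <- if (nrm > 0 && g1_scale > 0) g1 / nrm * g1_scale else numeric(n_dof)
    origin <- geometry(numeric(n_dof))
    two_state_pes(
      quadratic_surface(origin, e_ref = 0, g_ref = numeric(n_dof), h_ref = h0),
      quadratic_surface(origin, e_ref = gap0, g_ref = g1, h_ref = h1)
    )
  })
}

#' Anharmonic 2D soft/stiff-mode model pair
#'
#' A two-dimensional pair with one soft direction (x, force constant
#' `k_soft`) and one stiff direction (y, `k_stiff`), quartic hardening
#' along x and a cubic x^2 y coupling on the ground state, plus a gently
#' anharmonic excited state with an in-"plane" gradient. Along the soft
#' mode the single second-order prediction degrades quickly with force,
#' which is exactly the regime the iterative algorithm is for.
#'
#' @param k_soft,k_stiff harmonic force constants of state 0
#'   (Hartree/Bohr^2).
#' @param quartic quartic coefficient along x (state 0).
#' @param coupling x^2 y coupling coefficient (state 0).
#' @param gap0 vertical gap at the minimum (Hartree).
#' @return a [two_state_pes()] of two [poly_surface()]s with the state-0
#'   minimum at the origin.
#' @export
make_model2d_pair <- function(k_soft = 0.05, k_stiff = 1.0,
                              quartic = 0.08, coupling = 0.06,
                              gap0 = 0.223) {
  origin <- geometry(c(0, 0))
  # E0 = k_soft/2 x^2 + k_stiff/2 y^2 + quartic x^4 + coupling x^2 y
  s0 <- poly_surface(
    powers = rbind(c(2, 0), c(0, 2), c(4, 0), c(2, 1)),
    coef = c(k_soft / 2, k_stiff / 2, quartic, coupling),
    origin = origin
  )
  # E1 = gap0 + 0.06 x + 0.03 y + 0.09/2 x^2 + 0.85/2 y^2 + 0.05 x^4
  s1 <- poly_surface(
    powers = rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 0), c(0, 2), c(4, 0)),
    coef = c(gap0, 0.06, 0.03, 0.045, 0.425, 0.05),
    origin = origin
  )
  two_state_pes(s0, s1, q_ref = origin)
}

#' Morse-based anharmonic pair (1D or separable N-D)
#'
#' Ground state is a sum of Morse wells; excited state a displaced,
#' softened Morse sum, giving a gap with both linear and curvature
#' contributions and realistic softening at extension.
#'
#' @param n_dof dimension.
#' @param D,a state-0 Morse parameters (recycled).
#' @param shift displacement of the state-1 minimum (recycled).
#' @param soften multiplicative softening of state-1 `a` (recycled).
#' @param gap0 vertical gap at the state-0 minimum before the state-1
#'   offset correction (Hartree).
#' @return a [two_state_pes()].
#' @export
make_morse_pair <- function(n_dof = 1, D = 0.18, a = 1.0,
                            shift = 0.25, soften = 0.85, gap0 = 0.223) {
  center0 <- geometry(numeric(n_dof))
  s0 <- morse_surface(D, a, center0)
  center1 <- geometry(rep_len(shift, n_dof))
  s1 <- morse_surface(D, rep_len(a, n_dof) * rep_len(soften, n_dof),
                      center1, e0 = gap0)
  two_state_pes(s0, s1, q_ref = center0)
}

#' Second-order expansion of a two-state pair at a point
#'
#' Builds the quadratic pair whose surfaces are the local second-order
#' expansions of `pes` at `q` — the model the predictor/corrector works
#' on, and the "single second-order approach" when `q` is the minimum.
#'
#' @param pes a [two_state_pes()].
#' @param q expansion point (defaults to the pes reference).
#' @return a [two_state_pes()] of two [quadratic_surface()]s.
#' @export
quadratic_expansion <- function(pes, q = NULL) {
  q <- .as_geometry(q %||% pes$q_ref)
  p0 <- surface_eval(pes$state0, q, hessian = TRUE)
  p1 <- surface_eval(pes$state1, q, hessian = TRUE)
  two_state_pes(
    quadratic_surface(q, p0$energy, p0$gradient, p0$hessian),
    quadratic_surface(q, p1$energy, p1$gradient, p1$hessian)
  )
}
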
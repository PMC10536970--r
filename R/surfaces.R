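#' @title Potential energy surfaces
#' @description Evaluable single-state surfaces: exact quadratics (the
#'   second-order expansion the closed-form solver operates on), analytic
#'   anharmonic models (Morse sums, quartic-perturbed quadratics, low-order
#'   polynomials), and a backend adapter for external engines. All surfaces
#'   answer [surface_eval()] with energy, gradient and (optionally) Hessian
#'   in atomic units.
#' @name surfaces
NULL

.sympart <- function(h) (h + t(h)) / 2

.check_symmetric <- function(h, tol = 1e-10, what = "hessian") {
  if (!is.matrix(h) || nrow(h) != ncol(h))
    stop(what, " must be a square matrix", call. = FALSE)
  s <- max(abs(h))
  if (s > 0 && max(abs(h - t(h))) > tol * s)
    stop(what, " is not symmetric within tolerance", call. = FALSE)
  .sympart(h)
}

#' Evaluated point on a surface
#'
#' @param energy energy (Hartree).
#' @param gradient gradient vector (Hartree/Bohr).
#' @param hessian optional symmetric matrix (Hartree/Bohr^2).
#' @return object of class `"surface_point"`.
#' @export
surface_point <- function(energy, gradient, hessian = NULL) {
  if (!is.null(hessian)) hessian <- .check_symmetric(hessian)
  structure(list(energy = as.numeric(energy),
                 gradient = as.numeric(gradient),
                 hessian = hessian),
            class = "surface_point")
}

#' Evaluate a surface at a geometry
#'
#' @param surface a surface object (`quadratic_surface`, `morse_surface`,
#'   `quartic_surface`, `poly_surface`, `backend_surface`).
#' @param q [geometry()] or numeric coordinate vector.
#' @param hessian logical; also return the Hessian.
#' @return a [surface_point()].
#' @export
surface_eval <- function(surface, q, hessian = FALSE) {
  UseMethod("surface_eval")
}

#' Dimension of a surface's coordinate space
#' @param surface a surface object.
#' @return integer number of degrees of freedom.
#' @export
surface_dim <- function(surface) surface$n_dof

# ---- quadratic surface ------------------------------------------------------

#' Exact quadratic (second-order) surface
#'
#' Energy is the exact second-order polynomial
#' `E(q) = e_ref + g_ref' dq + dq' h_ref dq / 2` with `dq = q - q_ref`:
#' the local expansion every step of the iterative algorithm works with,
#' and the global form on which the closed-form solver is exact.
#'
#' @param q_ref reference geometry (expansion point).
#' @param e_ref reference energy (Hartree).
#' @param g_ref gradient at `q_ref` (Hartree/Bohr).
#' @param h_ref symmetric Hessian at `q_ref` (Hartree/Bohr^2).
#' @return object of class `c("quadratic_surface", "pes_surface")`.
#' @examples
#' s <- quadratic_surface(0, e_ref = 10, g_ref = 0, h_ref = 1)
#' surface_eval(s, 0.5)$energy   # 10.125
#' @export
quadratic_surface <- function(q_ref, e_ref, g_ref, h_ref) {
  q_ref <- .as_geometry(q_ref)
  n <- q_ref$n_dof
  g_ref <- as.numeric(g_ref)
  if (length(g_ref) != n) stop("gradient length must match q_ref", call. = FALSE)
  h_ref <- .check_symmetric(as.matrix(h_ref))
  if (nrow(h_ref) != n) stop("Hessian dimension must match q_ref", call. = FALSE)
  structure(list(q_ref = q_ref, e_ref = as.numeric(e_ref),
                 g_ref = g_ref, h_ref = h_ref, n_dof = n),
            class = c("quadratic_surface", "pes_surface"))
}

#' @export
surface_eval.quadratic_surface <- function(surface, q, hessian = FALSE) {
  .check_dim(surface$n_dof, q)
  dq <- .as_coords(q) - surface$q_ref$coords
  hdq <- drop(surface$h_ref %*% dq)
  surface_point(
    energy = surface$e_ref + sum(surface$g_ref * dq) + 0.5 * sum(dq * hdq),
    gradient = surface$g_ref + hdq,
    hessian = if (hessian) surface$h_ref else NULL
  )
}

# ---- anharmonic model surfaces ---------------------------------------------

#' Sum-of-Morse anharmonic surface
#'
#' `E(q) = e0 + sum_i D_i (1 - exp(-a_i (q_i - m_i)))^2`: separable, with
#' the softening-at-extension anharmonicity characteristic of bond
#' stretches. Gradient and Hessian are analytic; the minimum is at `m`.
#'
#' @param D well depths (Hartree), recycled to `n_dof`.
#' @param a range parameters (1/Bohr), recycled.
#' @param center minimum position `m`.
#' @param e0 energy at the minimum.
#' @return object of class `c("morse_surface", "pes_surface")`.
#' @export
morse_surface <- function(D, a, center, e0 = 0) {
  center <- .as_geometry(center)
  n <- center$n_dof
  D <- rep_len(as.numeric(D), n); a <- rep_len(as.numeric(a), n)
  if (any(D <= 0) || any(a <= 0)) stop("D and a must be positive", call. = FALSE)
  obj <- structure(list(D = D, a = a, center = center, e0 = as.numeric(e0),
                        n_dof = n),
                   class = c("morse_surface", "pes_surface"))
  stopifnot(sqrt(sum(surface_eval(obj, center)$gradient^2)) < 1e-8)
  obj
}

#' @export
surface_eval.morse_surface <- function(surface, q, hessian = FALSE) {
  .check_dim(surface$n_dof, q)
  x <- .as_coords(q) - surface$center$coords
  ex <- exp(-surface$a * x)
  D <- surface$D; a <- surface$a
  e <- surface$e0 + sum(D * (1 - ex)^2)
  g <- 2 * D * a * ex * (1 - ex)
  h <- if (hessian) diag(2 * D * a^2 * (2 * ex^2 - ex), nrow = surface$n_dof)
       else NULL
  surface_point(e, g, h)
}

#' Quartic-perturbed quadratic surface
#'
#' `E(q) = e0 + dq' h dq / 2 + sum_i c4_i dq_i^4`, minimum at `center`
#' when `h` is positive definite and `c4 >= 0`.
#'
#' @param h symmetric quadratic part (Hartree/Bohr^2).
#' @param c4 quartic coefficients, recycled to `n_dof`.
#' @param center minimum position.
#' @param e0 energy at the minimum.
#' @return object of class `c("quartic_surface", "pes_surface")`.
#' @export
quartic_surface <- function(h, c4, center, e0 = 0) {
  center <- .as_geometry(center)
  n <- center$n_dof
  h <- .check_symmetric(as.matrix(h))
  if (nrow(h) != n) stop("Hessian dimension must match center", call. = FALSE)
  c4 <- rep_len(as.numeric(c4), n)
  obj <- structure(list(h = h, c4 = c4, center = center, e0 = as.numeric(e0),
                        n_dof = n),
                   class = c("quartic_surface", "pes_surface"))
  stopifnot(sqrt(sum(surface_eval(obj, center)$gradient^2)) < 1e-8)
  obj
}

#' @export
surface_eval.quartic_surface <- function(surface, q, hessian = FALSE) {
  .check_dim(surface$n_dof, q)
  dq <- .as_coords(q) - surface$center$coords
  hdq <- drop(surface$h %*% dq)
  e <- surface$e0 + 0.5 * sum(dq * hdq) + sum(surface$c4 * dq^4)
  g <- hdq + 4 * surface$c4 * dq^3
  h <- if (hessian) surface$h + diag(12 * surface$c4 * dq^2,
                                     nrow = surface$n_dof) else NULL
  surface_point(e, g, h)
}

#' Low-order polynomial surface
#'
#' `E(q) = sum_k coef_k * prod_i dq_i^powers[k, i]` with `dq = q - origin`.
#' Used for small coupled model surfaces (the 2D soft/stiff-mode fixture);
#' gradient and Hessian are analytic.
#'
#' @param powers integer matrix, one monomial per row, one column per dof.
#' @param coef numeric coefficients, one per monomial.
#' @param origin expansion origin.
#' @return object of class `c("poly_surface", "pes_surface")`.
#' @export
poly_surface <- function(powers, coef, origin) {
  origin <- .as_geometry(origin)
  powers <- as.matrix(powers)
  storage.mode(powers) <- "double"
  if (any(powers < 0) || any(powers != round(powers)))
    stop("powers must be non-negative integers", call. = FALSE)
  if (ncol(powers) != origin$n_dof)
    stop("powers must have one column per dof", call. = FALSE)
  if (nrow(powers) != length(coef))
    stop("one coefficient per monomial required", call. = FALSE)
  structure(list(powers = powers, coef = as.numeric(coef), origin = origin,
                 n_dof = origin$n_dof),
            class = c("poly_surface", "pes_surface"))
}

#' @export
surface_eval.poly_surface <- function(surface, q, hessian = FALSE) {
  .check_dim(surface$n_dof, q)
  dq <- .as_coords(q) - surface$origin$coords
  P <- surface$powers; cf <- surface$coef
  n <- surface$n_dof
  # monomial values for the rows of Pm; zero powers skipped so 0^0 = 1
  mono <- function(Pm) {
    v <- rep(1, nrow(Pm))
    for (i in seq_len(n)) {
      p <- Pm[, i]
      nz <- p > 0
      if (any(nz)) v[nz] <- v[nz] * dq[i]^p[nz]
    }
    v
  }
  e <- sum(cf * mono(P))
  g <- numeric(n)
  for (i in seq_len(n)) {
    p <- P[, i]
    act <- p > 0
    if (!any(act)) next
    Pi <- P[act, , drop = FALSE]; Pi[, i] <- Pi[, i] - 1
    g[i] <- sum(cf[act] * p[act] * mono(Pi))
  }
  h <- NULL
  if (hessian) {
    h <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in i:n) {
      p <- P[, i]
      pj <- P[, j]
      if (i == j) {
        act <- p > 1
        if (any(act)) {
          Pij <- P[act, , drop = FALSE]; Pij[, i] <- Pij[, i] - 2
          h[i, i] <- sum(cf[act] * p[act] * (p[act] - 1) * mono(Pij))
        }
      } else {
        act <- p > 0 & pj > 0
        if (any(act)) {
          Pij <- P[act, , drop = FALSE]
          Pij[, i] <- Pij[, i] - 1; Pij[, j] <- Pij[, j] - 1
          h[i, j] <- h[j, i] <- sum(cf[act] * p[act] * pj[act] * mono(Pij))
        }
      }
    }
  }
  surface_point(e, g, h)
}

# ---- backend adapter --------------------------------------------------------

#' Adapter for an external energy/gradient backend
#'
#' Wraps a user-supplied callable `fun(coords, want_hessian)` returning a
#' list with `energy`, `gradient` and optionally `hessian`. When the
#' backend declares no analytic Hessian, Hessian requests are served by
#' central finite differences of the backend gradient.
#'
#' @param fun the evaluation callable.
#' @param n_dof dimension of the coordinate space.
#' @param analytic_gradient,analytic_hessian capability flags.
#' @param fd_step finite-difference step (Bohr) for the Hessian fallback.
#' @return object of class `c("backend_surface", "pes_surface")`.
#' @export
backend_surface <- function(fun, n_dof, analytic_gradient = TRUE,
                            analytic_hessian = FALSE, fd_step = 1e-3) {
  stopifnot(is.function(fun), n_dof >= 1)
  structure(list(fun = fun, n_dof = as.integer(n_dof),
                 analytic_gradient = isTRUE(analytic_gradient),
                 analytic_hessian = isTRUE(analytic_hessian),
                 fd_step = fd_step),
            class = c("backend_surface", "pes_surface"))
}

#' @export
surface_eval.backend_surface <- function(surface, q, hessian = FALSE) {
  .check_dim(surface$n_dof, q)
  x <- .as_coords(q)
  out <- surface$fun(x, hessian && surface$analytic_hessian)
  if (length(out$gradient) != surface$n_dof)
    stop("backend returned a gradient of length ", length(out$gradient),
         ", expected ", surface$n_dof, call. = FALSE)
  h <- out$hessian
  if (hessian && is.null(h)) {
    h <- finite_difference_hessian(
      function(z) {
        g <- surface$fun(z, FALSE)$gradient
        if (length(g) != surface$n_dof)
          stop("backend returned a gradient of length ", length(g),
               ", expected ", surface$n_dof, call. = FALSE)
        g
      },
      x, step = surface$fd_step)
  }
  surface_point(out$energy, out$gradient, h)
}

# ---- two-state container ----------------------------------------------------

#' Pair of surfaces for the initial ("0") and final ("1") electronic state
#'
#' The object the gap-tuning machinery operates on. Both states share one
#' coordinate space; `q_ref` is the shared reference (by default the
#' state-0 expansion point), and `gap_at_ref` caches the vertical gap
#' `E1(q_ref) - E0(q_ref)` from which gap variations are measured.
#'
#' @param state0,state1 evaluable surfaces of equal dimension.
#' @param q_ref reference geometry; defaults to state0's reference/center
#'   when it has one.
#' @return object of class `"two_state_pes"`.
#' @export
two_state_pes <- function(state0, state1, q_ref = NULL) {
  n0 <- surface_dim(state0); n1 <- surface_dim(state1)
  if (n0 != n1)
    stop("state dimensions differ: ", n0, " vs ", n1, call. = FALSE)
  if (is.null(q_ref))
    q_ref <- state0$q_ref %||% state0$center %||% state0$origin
  if (is.null(q_ref))
    stop("q_ref must be given when state0 carries no reference point",
         call. = FALSE)
  q_ref <- .as_geometry(q_ref)
  .check_dim(n0, q_ref, "state0")
  gap0 <- surface_eval(state1, q_ref)$energy -
          surface_eval(state0, q_ref)$energy
  structure(list(state0 = state0, state1 = state1, q_ref = q_ref,
                 gap_at_ref = gap0, n_dof = n0),
            class = "two_state_pes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.two_state_pes <- function(x, ...) {
  cat("<two_state_pes> ", x$n_dof, " dof; state0: ",
      class(x$state0)[1], ", state1: ", class(x$state1)[1],
      "; gap at reference ", format(x$gap_at_ref), " Hartree\n", sep = "")
  invisible(x)
}

#' Energy gap and gap variation
#'
#' `energy_gap` is `E1(q) - E0(q)`; `gap_variation` subtracts the gap at
#' the reference structure, the quantity the external force is tuning.
#'
#' @param pes a [two_state_pes()].
#' @param q geometry or coordinate vector.
#' @return numeric scalar (Hartree).
#' @export
energy_gap <- function(pes, q) {
  .check_dim(pes$n_dof, q, "pes")
  surface_eval(pes$state1, q)$energy - surface_eval(pes$state0, q)$energy
}

#' @rdname energy_gap
#' @export
gap_variation <- function(pes, q) energy_gap(pes, q) - pes$gap_at_ref

#' External force holding a structure as equilibrium on state 0
#'
#' Under an applied force the relaxed structure satisfies
#' `grad E0(q) = F_ext` (internal and external forces cancel), so the
#' force that holds `q` is the state-0 gradient there.
#'
#' @param pes a [two_state_pes()].
#' @param q geometry or coordinate vector.
#' @return list with `vector` (Hartree/Bohr) and `magnitude` (Euclidean
#'   norm).
#' @export
external_force <- function(pes, q) {
  .check_dim(pes$n_dof, q, "pes")
  g <- surface_eval(pes$state0, q)$gradient
  list(vector = g, magnitude = sqrt(sum(g^2)))
}
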
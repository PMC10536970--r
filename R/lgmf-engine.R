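#' @title Iterative optimal-force engine
#' @description The LGMF loop on general surfaces: from an optimized
#'   point, a predictor displacement raises the model force magnitude by
#'   one increment; a corrector walks along the component of the
#'   gap gradient perpendicular to the force-magnitude gradient, staying
#'   on the constant-force level set of the local model, until the two
#'   gradients are parallel; the converged point is then verified with
#'   exact gradients (and Hessians per policy) and, on failure, the
#'   expansion is refreshed there and the corrector resumes. Each branch
#'   grows until the force ceiling.
#' @name lgmf_engine
NULL

.norm2 <- function(v) sqrt(sum(v^2))

# model quantities under the second-order expansion held in exp0/exp1
.model_g0 <- function(exp0, dq) exp0$gradient + drop(exp0$hessian %*% dq)

#' Approximate gradients under a local expansion
#'
#' Gap gradient and force-magnitude-squared gradient at displacement `dq`
#' from the expansion point, both under the second-order model:
#' `grad dE = (g1 + H1 dq) - (g0 + H0 dq)` and
#' `grad ||F||^2 = 2 H0 (g0 + H0 dq)`.
#'
#' @param exp0,exp1 [surface_point()]s (with Hessians) at the expansion
#'   point for the two states.
#' @param dq displacement from the expansion point.
#' @return list `grad_gap`, `grad_force_sq`.
#' @export
approx_gradients <- function(exp0, exp1, dq) {
  g0 <- .model_g0(exp0, dq)
  list(grad_gap = (exp1$gradient + drop(exp1$hessian %*% dq)) - g0,
       grad_force_sq = 2 * drop(exp0$hessian %*% g0))
}

#' Orthogonal decomposition against a constraint normal
#'
#' Splits `v` into its component along `w` and the exact orthogonal
#' remainder.
#'
#' @param v vector to decompose.
#' @param w reference (constraint-normal) vector; must be nonzero.
#' @return list `parallel`, `perp`.
#' @export
split_perp <- function(v, w) {
  nw <- .norm2(w)
  if (nw < 1e-12)
    stop("constraint normal is numerically zero: decomposition undefined",
         call. = FALSE)
  wh <- w / nw
  par <- sum(v * wh) * wh
  list(parallel = par, perp = v - par)
}

#' Predictor displacement reaching a force-magnitude increment
#'
#' Scales a displacement along `direction` so that, under the local
#' second-order model, the external-force magnitude grows by exactly
#' `target_delta_force`: the positive root of
#' `||g0 + s H0 d|| = ||g0|| + delta`, a safeguarded scalar solve (the
#' quadratic in `s` is solved in closed form).
#'
#' @param exp0 state-0 [surface_point()] with Hessian at the expansion
#'   point.
#' @param direction search direction (need not be normalized).
#' @param target_delta_force desired increase of the force magnitude
#'   (Hartree/Bohr), >= 0.
#' @return displacement vector `s * direction / ||direction||`.
#' @export
predictor_step <- function(exp0, direction, target_delta_force) {
  nd <- .norm2(direction)
  if (nd < 1e-14) stop("direction must be nonzero", call. = FALSE)
  if (target_delta_force < 0)
    stop("target_delta_force must be >= 0", call. = FALSE)
  if (target_delta_force == 0) return(numeric(length(direction)))
  dh <- direction / nd
  v <- drop(exp0$hessian %*% dh)
  a <- sum(v^2)
  if (a < 1e-24)
    stop("force magnitude does not increase along this direction ",
         "(H0 annihilates it); flip or change the direction",
         call. = FALSE)
  g0 <- exp0$gradient
  b <- 2 * sum(g0 * v)
  cc <- -(2 * .norm2(g0) * target_delta_force + target_delta_force^2)
  s <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  s * dh
}

#' Force-budget check
#'
#' The achieved force magnitude at a converged point may deviate from the
#' scheduled value by at most the configured relative budget (the 5%
#' rule); beyond that the constant-force condition must be recalculated
#' with the updated surface information and the optimization restarted
#' from the point.
#'
#' @param achieved_force,scheduled_force magnitudes (Hartree/Bohr);
#'   `scheduled_force` must be > 0.
#' @param config an [lgmf_config()].
#' @return `"ok"` or `"recalibrate"`.
#' @export
enforce_force_budget <- function(achieved_force, scheduled_force, config) {
  if (!(scheduled_force > 0))
    stop("scheduled_force must be > 0", call. = FALSE)
  if (abs(achieved_force - scheduled_force) <=
      config$force_budget * scheduled_force) "ok" else "recalibrate"
}

#' BFGS rank-two Hessian update
#'
#' Standard direct update from a displacement and the corresponding
#' gradient difference; the secant condition `H' dq = y` holds exactly
#' and symmetry is preserved. A violated curvature condition raises an
#' error of class `"lgmf_curvature_error"`, on which the engine skips the
#' update and requests an exact Hessian instead.
#'
#' @param h current symmetric Hessian.
#' @param dq displacement between consecutive optimized points.
#' @param y gradient difference between the same points.
#' @return updated symmetric matrix.
#' @export
bfgs_update <- function(h, dq, y) {
  h <- .check_symmetric(as.matrix(h))
  dq <- as.numeric(dq); y <- as.numeric(y)
  sy <- sum(dq * y)
  if (sy <= 1e-12 * .norm2(dq) * .norm2(y))
    stop(structure(class = c("lgmf_curvature_error", "error", "condition"),
                   list(message = "BFGS curvature condition dq'y > 0 violated",
                        call = sys.call())))
  hdq <- drop(h %*% dq)
  shs <- sum(dq * hdq)
  if (shs <= 0)
    stop(structure(class = c("lgmf_curvature_error", "error", "condition"),
                   list(message = "current Hessian has non-positive curvature along dq",
                        call = sys.call())))
  .sympart(h - tcrossprod(hdq) / shs + tcrossprod(y) / sy)
}

# retraction onto the constant-force level set of the local model:
# 1D move along the constraint normal, radial rescale as fallback
.retract <- function(exp0, dq, target) {
  g0m <- .model_g0(exp0, dq)
  gf <- 2 * drop(exp0$hessian %*% g0m)
  nf <- .norm2(gf)
  if (nf > 1e-14) {
    nh <- gf / nf
    hv <- drop(exp0$hessian %*% nh)
    a <- sum(hv^2); b <- 2 * sum(g0m * hv); cc <- sum(g0m^2) - target^2
    disc <- b^2 - 4 * a * cc
    if (a > 1e-24 && disc >= 0) {
      r <- sqrt(disc)
      t1 <- (-b + r) / (2 * a); t2 <- (-b - r) / (2 * a)
      t <- if (abs(t1) <= abs(t2)) t1 else t2
      return(dq + t * nh)
    }
  }
  # fallback: rescale the model force vector itself, displacing along
  # H0^-1 g0m, which reaches any magnitude exactly
  ng <- .norm2(g0m)
  if (ng < 1e-14) {
    if (target < 1e-14) return(dq)
    return(NULL)
  }
  corr <- tryCatch(solve(exp0$hessian, g0m), error = function(e) NULL)
  if (is.null(corr)) return(NULL)
  dq + (target / ng - 1) * corr
}

.model_gap <- function(exp0, exp1, dq) {
  (exp1$energy - exp0$energy) + sum((exp1$gradient - exp0$gradient) * dq) +
    0.5 * sum(dq * drop((exp1$hessian - exp0$hessian) %*% dq))
}

#' One corrector step
#'
#' Evaluates the model gap and force-magnitude gradients at `dq`; if they
#' are parallel within `cos_tolerance` the point is converged. Otherwise
#' the displacement is advanced along the perpendicular component of the
#' gap gradient — scaled by the adaptive step constant times the inverse
#' curvature of the constrained Lagrangian along that direction — and
#' retracted onto the constant-force level set. A trial that worsens the
#' model gap (in the branch's sense) is rejected and the constant halved
#' before retrying; the perpendicular norm drives the longer-term
#' adaptation of the constant in the surrounding loop.
#'
#' @param exp0,exp1 state expansions ([surface_point()]s with Hessians).
#' @param dq current displacement from the expansion point.
#' @param target_force scheduled force magnitude (Hartree/Bohr).
#' @param config an [lgmf_config()].
#' @param branch_sign `+1` to increase the gap, `-1` to decrease it.
#' @param step_constant current adaptive proportionality constant.
#' @return list `dq`, `cos_alpha`, `converged`, `perp_norm`,
#'   `perp_decreased`, `step_constant` (after any halving), `stalled`
#'   (no acceptable step found).
#' @export
corrector_iterate <- function(exp0, exp1, dq, target_force, config,
                              branch_sign = 1,
                              step_constant = config$corrector_constant) {
  gr <- approx_gradients(exp0, exp1, dq)
  gg <- gr$grad_gap; gf <- gr$grad_force_sq
  ngg <- .norm2(gg)
  if (ngg < 1e-14 || .norm2(gf) < 1e-14)
    return(list(dq = dq, cos_alpha = 1, converged = TRUE, perp_norm = 0,
                perp_decreased = TRUE, step_constant = step_constant,
                stalled = FALSE))
  ca <- sum(gg * gf) / (ngg * .norm2(gf))
  if (abs(ca) >= config$cos_tolerance)
    return(list(dq = dq, cos_alpha = ca, converged = TRUE,
                perp_norm = .norm2(split_perp(gg, gf)$perp),
                perp_decreased = TRUE, step_constant = step_constant,
                stalled = FALSE))

  perp <- split_perp(gg, gf)$perp
  pn <- .norm2(perp)
  ph <- perp / pn
  nf2 <- sum(gf * gf)
  lam <- sum(gg * gf) / nf2
  # model Lagrangian Hessian: curvature of the gap along the level set
  w <- (exp1$hessian - exp0$hessian) -
    2 * lam * (exp0$hessian %*% exp0$hessian)

  pack <- function(trial, cc) {
    gr2 <- approx_gradients(exp0, exp1, trial)
    pn2 <- .norm2(split_perp(gr2$grad_gap, gr2$grad_force_sq)$perp)
    ca2 <- sum(gr2$grad_gap * gr2$grad_force_sq) /
      (.norm2(gr2$grad_gap) * .norm2(gr2$grad_force_sq))
    list(dq = trial, cos_alpha = ca2,
         converged = abs(ca2) >= config$cos_tolerance,
         perp_norm = pn2, perp_decreased = pn2 < pn,
         step_constant = cc, stalled = FALSE)
  }

  # near parallelism, polish with a tangent-space (bordered KKT) Newton
  # step, which is quadratically convergent; fall back to the first-order
  # scheme if it does not reduce the perpendicular residual
  if (abs(ca) >= 0.99) {
    n <- length(dq)
    kkt <- rbind(cbind(w, gf), c(gf, 0))
    rhs <- c(-(gg - lam * gf), 0)
    delta <- tryCatch(solve(kkt, rhs)[seq_len(n)], error = function(e) NULL)
    if (!is.null(delta)) {
      nd <- .norm2(delta)
      capn <- 4 * max(.norm2(dq), 1e-12)
      if (nd > capn) delta <- delta * (capn / nd)
      trial <- .retract(exp0, dq + delta, target_force)
      if (!is.null(trial)) {
        out <- pack(trial, step_constant)
        if (out$perp_norm < pn) return(out)
      }
    }
  }

  # first-order phase: ascend (descend) along the perpendicular gap
  # gradient with a curvature-scaled step and Armijo backtracking
  kap <- sum(ph * drop(w %*% ph))
  base <- branch_sign * (pn / max(abs(kap), 1e-8)) * ph
  cap <- 4 * max(.norm2(dq), 1e-12)
  nb <- .norm2(base)
  if (nb > cap) base <- base * (cap / nb)

  m_cur <- .model_gap(exp0, exp1, dq)
  cc <- step_constant
  floor_cc <- 1e-8 * config$corrector_constant
  repeat {
    trial <- .retract(exp0, dq + cc * base, target_force)
    if (!is.null(trial)) {
      m_tr <- .model_gap(exp0, exp1, trial)
      moved <- .norm2(trial - dq)
      armijo <- branch_sign * (m_tr - m_cur) >=
        1e-4 * pn * moved - 1e-15 * max(1, abs(m_cur))
      if (moved > 0 && armijo) return(pack(trial, cc))
    }
    if (cc <= floor_cc)
      return(list(dq = dq, cos_alpha = ca, converged = FALSE,
                  perp_norm = pn, perp_decreased = FALSE,
                  step_constant = cc, stalled = TRUE))
    cc <- max(cc / 2, floor_cc)
  }
}

# full corrector loop: halve the constant when the perpendicular norm
# grows, double (capped) after three consecutive decreases
.corrector_loop <- function(exp0, exp1, dq, target_force, config,
                            branch_sign) {
  dq <- .retract(exp0, dq, target_force)
  if (is.null(dq))
    return(list(converged = FALSE, dq = NULL, cos_alpha = NA_real_,
                iters = 0L))
  cc <- config$corrector_constant
  cap <- config$corrector_constant  # doubling only recovers from halvings
  streak <- 0L
  best_cos <- 0; best_dq <- dq
  for (it in seq_len(config$corrector_max_iter)) {
    st <- corrector_iterate(exp0, exp1, dq, target_force, config,
                            branch_sign, cc)
    if (abs(st$cos_alpha) > abs(best_cos)) {
      best_cos <- st$cos_alpha; best_dq <- st$dq
    }
    if (st$converged)
      return(list(converged = TRUE, dq = st$dq, cos_alpha = st$cos_alpha,
                  iters = it))
    if (st$stalled)
      return(list(converged = FALSE, dq = best_dq, cos_alpha = best_cos,
                  iters = it))
    cc <- st$step_constant   # possibly halved on rejected trials
    if (st$perp_decreased) {
      streak <- streak + 1L
      if (streak >= 3L) { cc <- min(cc * 2, cap); streak <- 0L }
    } else {
      streak <- 0L
    }
    dq <- st$dq
  }
  list(converged = FALSE, dq = best_dq, cos_alpha = best_cos,
       iters = config$corrector_max_iter)
}

#' Exact verification of a candidate optimal point
#'
#' Recomputes both state gradients directly from the surfaces at `q1`
#' (and the Hessians per the configured policy, or uses the supplied
#' quasi-Newton ones) and evaluates the parallelism condition with exact
#' quantities. On failure the exact expansions are returned so the caller
#' can resume the corrector from the refreshed model.
#'
#' @param pes a [two_state_pes()].
#' @param q1 candidate geometry (or coordinate vector).
#' @param config an [lgmf_config()].
#' @param hessians optional list `h0`, `h1` of quasi-Newton Hessians used
#'   when `hessian_policy = "bfgs"`.
#' @return list `verified`, `cos_alpha`, `force_magnitude`, `point0`,
#'   `point1` (surface points with the Hessians used).
#' @export
verify_exact <- function(pes, q1, config, hessians = NULL) {
  use_qn <- config$hessian_policy == "bfgs" && !is.null(hessians)
  p0 <- surface_eval(pes$state0, q1, hessian = !use_qn)
  p1 <- surface_eval(pes$state1, q1, hessian = !use_qn)
  if (use_qn) {
    p0$hessian <- hessians$h0
    p1$hessian <- hessians$h1
  }
  gg <- p1$gradient - p0$gradient
  gf <- 2 * drop(p0$hessian %*% p0$gradient)
  ca <- .cos_angle(gg, gf)
  list(verified = abs(ca) >= config$cos_tolerance, cos_alpha = ca,
       force_magnitude = .norm2(p0$gradient), point0 = p0, point1 = p1)
}

# expansion bookkeeping: exact or BFGS-updated Hessians at a new point
.expand_at <- function(pes, q, config, prev = NULL) {
  exact <- config$hessian_policy == "exact-every-point" || is.null(prev)
  p0 <- surface_eval(pes$state0, q, hessian = exact)
  p1 <- surface_eval(pes$state1, q, hessian = exact)
  if (!exact) {
    dq <- q - prev$q
    h0 <- tryCatch(bfgs_update(prev$h0, dq, p0$gradient - prev$g0),
                   lgmf_curvature_error = function(e) {
                     .lgmf_log("state-0 BFGS update skipped (",
                               conditionMessage(e), "); exact Hessian used")
                     NULL
                   })
    h1 <- tryCatch(bfgs_update(prev$h1, dq, p1$gradient - prev$g1),
                   lgmf_curvature_error = function(e) {
                     .lgmf_log("state-1 BFGS update skipped (",
                               conditionMessage(e), "); exact Hessian used")
                     NULL
                   })
    p0$hessian <- h0 %||% surface_eval(pes$state0, q, hessian = TRUE)$hessian
    p1$hessian <- h1 %||% surface_eval(pes$state1, q, hessian = TRUE)$hessian
  }
  list(q = q, g0 = p0$gradient, g1 = p1$gradient,
       h0 = p0$hessian, h1 = p1$hessian, e0 = p0$energy, e1 = p1$energy)
}

# one verified optimal point at scheduled force `target`, or NULL
.attempt_point <- function(pes, state, target, direction, branch_sign,
                           config) {
  exp_pt <- state$expansion         # list q,g0,g1,h0,h1
  dq <- tryCatch(
    predictor_step(surface_point(0, exp_pt$g0, exp_pt$h0), direction,
                   target - .norm2(exp_pt$g0)),
    error = function(e) NULL)
  if (is.null(dq)) {
    dq <- tryCatch(
      predictor_step(surface_point(0, exp_pt$g0, exp_pt$h0),
                     branch_sign * (exp_pt$g1 - exp_pt$g0),
                     target - .norm2(exp_pt$g0)),
      error = function(e) NULL)
    if (is.null(dq)) return(NULL)
  }
  total_iters <- 0L
  for (rex in seq_len(config$max_reexpand)) {
    e0 <- surface_point(exp_pt$e0 %||% 0, exp_pt$g0, exp_pt$h0)
    e1 <- surface_point(exp_pt$e1 %||% 0, exp_pt$g1, exp_pt$h1)
    cs <- .corrector_loop(e0, e1, dq, target, config, branch_sign)
    total_iters <- total_iters + cs$iters
    if (!cs$converged) return(NULL)
    q1 <- exp_pt$q + cs$dq
    ver <- verify_exact(pes, q1, config,
                        hessians = if (config$hessian_policy == "bfgs")
                          list(h0 = exp_pt$h0, h1 = exp_pt$h1))
    budget <- enforce_force_budget(ver$force_magnitude, target, config)
    if (ver$verified && budget == "ok") {
      newexp <- .expand_at(pes, q1, config, prev = exp_pt)
      pt <- list(q = geometry(q1, pes$q_ref$atoms),
                 force_vector = ver$point0$gradient,
                 force_magnitude = ver$force_magnitude,
                 scheduled_force = target,
                 gap_variation = gap_variation(pes, q1),
                 cos_alpha = ver$cos_alpha,
                 n_corrector_iters = total_iters,
                 n_reexpansions = rex - 1L,
                 verified_exact = TRUE)
      return(list(point = pt, expansion = newexp,
                  disp = q1 - state$q_point))
    }
    # refresh the expansion at the candidate and resume the corrector
    .lgmf_log("verification ", if (!ver$verified) "failed" else
              "outside force budget", " at |F| = ", format(target),
              "; re-expanding (", rex, ")")
    exp_pt <- .expand_at(pes, q1, config, prev = exp_pt)
    dq <- numeric(length(q1))
  }
  NULL
}

.run_branch <- function(pes, config, q_start, dir0, branch_sign, start_exp,
                        start_gap) {
  f0 <- .norm2(start_exp$g0)
  start_pt <- list(q = geometry(q_start, pes$q_ref$atoms),
                   force_vector = start_exp$g0, force_magnitude = f0,
                   scheduled_force = f0,
                   gap_variation = start_gap, cos_alpha = 1,
                   n_corrector_iters = 0L, n_reexpansions = 0L,
                   verified_exact = TRUE)
  pts <- list(start_pt)
  state <- list(expansion = start_exp, q_point = q_start)
  direction <- dir0
  f_cur <- f0
  step <- config$force_step
  halvings <- 0L
  termination <- "ceiling"
  while (f_cur + step <= config$force_max * (1 + 1e-12)) {
    target <- f_cur + step
    att <- .attempt_point(pes, state, target, direction, branch_sign,
                          config)
    if (is.null(att)) {
      halvings <- halvings + 1L
      if (halvings > 2L) { termination <- "non-convergence"; break }
      step <- step / 2
      .lgmf_log("point at |F| = ", format(target),
                " did not converge; halving force step to ", format(step))
      next
    }
    pts <- c(pts, list(att$point))
    state <- list(expansion = att$expansion, q_point = att$expansion$q)
    direction <- att$disp
    f_cur <- target
    if (halvings > 0L) { step <- config$force_step; halvings <- 0L }
  }
  new_force_ramp(branch = if (branch_sign > 0) "increase" else "decrease",
                 points = pts, termination_reason = termination,
                 source = "lgmf")
}

#' Run the two optimal-force ramps
#'
#' From an optimized point of the initial state (the minimum, unless a
#' previously verified point is supplied), grows the gap-increasing and
#' gap-decreasing continuation branches up to the force ceiling. The
#' first search direction is the gap gradient and its opposite; afterward
#' each point continues along the previous displacement. Every emitted
#' point is verified with exact gradients and obeys the force budget.
#'
#' @param pes a [two_state_pes()].
#' @param config an [lgmf_config()].
#' @param q_start optional start geometry; defaults to the pes reference.
#'   Must be an optimized point of state 0 (gradient norm < 1e-6).
#' @return list of two `"force_ramp"`s, `increase` and `decrease`.
#' @examples
#' pes <- make_quadratic_pair(4, seed = 1)
#' cfg <- lgmf_config(force_step = 0.2, force_max = 1, force_unit = "nN")
#' ramps <- run_ramp(pes, cfg)
#' as.data.frame(ramps$increase)
#' @export
run_ramp <- function(pes, config = lgmf_config(), q_start = NULL) {
  q0 <- .as_coords(q_start %||% pes$q_ref)
  .check_dim(pes$n_dof, q0, "pes")
  start_exp <- .expand_at(pes, q0, config)
  g0n <- .norm2(start_exp$g0)
  if (g0n >= 1e-6)
    stop("start point is not an optimized point of state 0 ",
         "(|g0| = ", format(g0n), " >= 1e-6)", call. = FALSE)
  start_gap <- gap_variation(pes, q0)
  dgap <- start_exp$g1 - start_exp$g0
  if (.norm2(dgap) < 1e-10) {
    # stationary gap: seed from the extreme pencil eigenvector of the
    # local expansion instead of the (vanishing) gap gradient
    h0inv <- chol2inv(chol(start_exp$h0))
    cm <- .sympart(h0inv %*% (start_exp$h1 - start_exp$h0) %*% h0inv)
    eg <- eigen(cm, symmetric = TRUE)
    k <- which.max(abs(eg$values))
    dgap <- drop(h0inv %*% eg$vectors[, k])
  }
  inc <- .run_branch(pes, config, q0, dgap, +1, start_exp, start_gap)
  dec <- .run_branch(pes, config, q0, -dgap, -1, start_exp, start_gap)
  list(increase = inc, decrease = dec)
}
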
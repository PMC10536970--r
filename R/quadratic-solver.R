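#' @title Closed-form optimal forces on quadratic surfaces
#' @description On a pair of exact second-order surfaces expanded at the
#'   state-0 minimum, the structure of largest gap variation under a
#'   constant force-magnitude constraint solves a shifted linear system in
#'   the Lagrange multiplier lambda. Scanning lambda traces the two
#'   solution families (gap-increasing and gap-decreasing); a secular
#'   equation inverts the lambda-to-force map so ramps can be compared at
#'   prescribed force magnitudes.
#' @name quadratic_solver
NULL

.quad_parts <- function(pes) {
  s0 <- pes$state0; s1 <- pes$state1
  if (!inherits(s0, "quadratic_surface") || !inherits(s1, "quadratic_surface"))
    stop("both states must be quadratic surfaces; expand a general pair ",
         "with quadratic_expansion() first", call. = FALSE)
  if (max(abs(s0$q_ref$coords - s1$q_ref$coords)) > 1e-12)
    stop("the two quadratic states must share one expansion point",
         call. = FALSE)
  g0n <- sqrt(sum(s0$g_ref^2))
  if (g0n >= 1e-8)
    stop("state 0 must be expanded at its minimum (|g0| = ",
         format(g0n), " >= 1e-8)", call. = FALSE)
  list(h0 = s0$h_ref, h1 = s1$h_ref, g1 = s1$g_ref,
       q0 = s0$q_ref$coords, n = s0$n_dof)
}

# the two sign conventions of the optimality linear system:
#   printed    : (2*lambda*H0^2 - H0 + H1) dq = g1
#   lagrangian : (2*lambda*H0^2 + H0 - H1) dq = g1
#     (direct stationarity of grad dE = lambda * grad ||F||^2)
.opt_matrix <- function(lambda, h0, h1, convention) {
  h0sq <- h0 %*% h0
  switch(convention,
         printed = 2 * lambda * h0sq - h0 + h1,
         lagrangian = 2 * lambda * h0sq + h0 - h1,
         stop("unknown convention", call. = FALSE))
}

.cos_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-14 || nb < 1e-14) return(1)  # degenerate: condition vacuous
  sum(a * b) / (na * nb)
}

.parallelism_cos <- function(dq, h0, h1, g1) {
  grad_gap <- g1 + drop((h1 - h0) %*% dq)
  grad_fsq <- 2 * drop(h0 %*% (h0 %*% dq))
  .cos_angle(grad_gap, grad_fsq)
}

#' Equilibrium displacement under a prescribed external force
#'
#' Solves `H0 dq = F_ext` by Cholesky factorization of the (required
#' positive definite) state-0 Hessian: the new equilibrium structure when
#' a force is applied on a second-order surface.
#'
#' @param h0 symmetric Hessian (Hartree/Bohr^2).
#' @param f_ext external force vector (Hartree/Bohr).
#' @return displacement vector `dq` (Bohr).
#' @export
equilibrium_structure <- function(h0, f_ext) {
  h0 <- .check_symmetric(as.matrix(h0), what = "h0")
  f_ext <- as.numeric(f_ext)
  if (length(f_ext) != nrow(h0))
    stop("force length must match Hessian dimension", call. = FALSE)
  ev <- eigen(h0, symmetric = TRUE, only.values = TRUE)$values
  bad <- ev[ev <= 1e-10 * max(abs(ev), 1e-300)]
  if (length(bad))
    stop("state-0 Hessian is singular or indefinite: offending eigenvalue ",
         format(bad[which.min(abs(bad))]), call. = FALSE)
  drop(chol2inv(chol(h0)) %*% f_ext)
}

#' Optimal structure for one Lagrange multiplier
#'
#' Solves the optimality linear system for the displacement producing the
#' extremal gap variation at the force magnitude that `lambda` selects.
#' The printed-form matrix `2*lambda*H0^2 - H0 + H1` is tried first and
#' the solution self-validated by the parallelism condition
#' `cos(grad dE, grad ||F||^2) = +/-1`; when that fails (the generic
#' multi-dimensional case) the sign-resolved Lagrangian variant
#' `2*lambda*H0^2 + H0 - H1` is solved instead, and the convention used is
#' recorded in the result.
#'
#' @param lambda Lagrange multiplier (Bohr^2/Hartree).
#' @param pes quadratic [two_state_pes()] expanded at the state-0 minimum.
#' @return object of class `"quadratic_solution"`: fields
#'   `lambda`, `q_opt`, `dq`, `force_vector`, `force_magnitude`,
#'   `gap_variation`, `cos_alpha`, `branch`, `singular_flag`,
#'   `convention`.
#' @export
optimal_structure <- function(lambda, pes) {
  p <- .quad_parts(pes)

  solve_conv <- function(convention) {
    m <- .opt_matrix(lambda, p$h0, p$h1, convention)
    sv <- svd(m, nu = 0, nv = 0)$d
    if (max(sv) <= 0 || min(sv) < 1e-8 * max(sv))
      return(list(singular = TRUE))
    dq <- solve(m, p$g1)
    list(singular = FALSE, dq = dq,
         cos = .parallelism_cos(dq, p$h0, p$h1, p$g1))
  }

  pr <- solve_conv("printed")
  used <- "printed"; sol <- pr
  if (pr$singular || abs(pr$cos) < 1 - 1e-9) {
    lg <- solve_conv("lagrangian")
    if (!lg$singular && (pr$singular || abs(lg$cos) > abs(pr$cos))) {
      used <- "lagrangian"; sol <- lg
    }
  }

  if (sol$singular) {
    return(structure(list(lambda = lambda, q_opt = NULL, dq = NULL,
                          force_vector = NULL, force_magnitude = NA_real_,
                          gap_variation = NA_real_, cos_alpha = NA_real_,
                          branch = NA_character_, singular_flag = TRUE,
                          convention = used),
                     class = "quadratic_solution"))
  }

  dq <- sol$dq
  fvec <- drop(p$h0 %*% dq)
  gv <- sum(p$g1 * dq) + 0.5 * sum(dq * drop((p$h1 - p$h0) %*% dq))
  structure(list(
    lambda = lambda,
    q_opt = geometry(p$q0 + dq, pes$q_ref$atoms),
    dq = dq,
    force_vector = fvec,
    force_magnitude = sqrt(sum(fvec^2)),
    gap_variation = gv,
    cos_alpha = sol$cos,
    branch = if (gv >= 0) "increase" else "decrease",
    singular_flag = FALSE,
    convention = used
  ), class = "quadratic_solution")
}

#' @export
print.quadratic_solution <- function(x, ...) {
  if (x$singular_flag) {
    cat("<quadratic_solution> singular at lambda =", format(x$lambda), "\n")
  } else {
    cat("<quadratic_solution> lambda =", format(x$lambda),
        " |F| =", format(x$force_magnitude),
        " d(gap) =", format(x$gap_variation),
        " (", x$branch, ", cos =", format(x$cos_alpha), ")\n")
  }
  invisible(x)
}

#' Scan the Lagrange multiplier over a grid
#'
#' One closed-form solution per grid value; values within the singularity
#' tolerance of the pencil spectrum are dropped with a message. Solutions
#' are partitioned by the sign of the gap variation into an increasing and
#' a decreasing branch, each sorted by achieved force magnitude (the
#' lambda-to-force map is not globally monotone).
#'
#' @param pes quadratic [two_state_pes()] at the state-0 minimum.
#' @param lambda_grid ordered numeric vector of multipliers.
#' @return list with ramps `increase` and `decrease` (class
#'   `"force_ramp"`) and `dropped`, the singular grid values.
#' @export
lambda_scan <- function(pes, lambda_grid) {
  if (length(lambda_grid) == 0) stop("empty lambda grid", call. = FALSE)
  sols <- lapply(lambda_grid, optimal_structure, pes = pes)
  sing <- vapply(sols, function(s) s$singular_flag, TRUE)
  if (any(sing))
    message("lambda_scan: dropped ", sum(sing),
            " singular grid value(s): ",
            paste(format(lambda_grid[sing]), collapse = ", "))
  sols <- sols[!sing]
  gv <- vapply(sols, function(s) s$gap_variation, 0)
  fm <- vapply(sols, function(s) s$force_magnitude, 0)
  mk <- function(keep, branch) {
    pts <- sols[keep][order(fm[keep])]
    new_force_ramp(branch = branch, points = pts, source = "lambda_scan")
  }
  list(increase = mk(gv >= 0, "increase"),
       decrease = mk(gv < 0, "decrease"),
       dropped = lambda_grid[sing])
}

#' Closed-form optimum at a prescribed force magnitude
#'
#' Inverts the lambda-to-force map on the outer multiplier interval (the
#' branch continuously connected to zero force, which trust-region theory
#' identifies with the global constrained optimum) by solving the secular
#' equation in the eigenbasis of `H0^-1 (H1 - H0) H0^-1`. Includes the
#' hard case where the gap gradient has no component along the extreme
#' eigenvector.
#'
#' @param pes quadratic [two_state_pes()] at the state-0 minimum.
#' @param force target force magnitude (Hartree/Bohr), > 0.
#' @param branch `"increase"` (gap maximization) or `"decrease"`.
#' @return a `"quadratic_solution"` (Lagrangian convention).
#' @export
quadratic_optimum_at_force <- function(pes, force,
                                       branch = c("increase", "decrease")) {
  branch <- match.arg(branch)
  p <- .quad_parts(pes)
  if (force <= 0) stop("force must be positive", call. = FALSE)
  h0inv <- chol2inv(chol(p$h0))
  cmat <- .sympart(h0inv %*% (p$h1 - p$h0) %*% h0inv)
  eg <- eigen(cmat, symmetric = TRUE)
  d <- eg$values                      # descending
  beta <- drop(t(eg$vectors) %*% (h0inv %*% p$g1))

  # w_i = beta_i / (2 lambda - d_i); ||w|| = force on the outer interval
  if (branch == "increase") { dext <- d[1]; sgn <- 1 }
  else { dext <- d[length(d)]; sgn <- -1 }
  # x = sgn*(2 lambda - dext) > 0 on the outer interval
  wnorm <- function(x) {
    denom <- sgn * (x + sgn * (dext - d))   # = |2 lambda - d_i| signed
    sqrt(sum((beta / denom)^2))
  }
  bext <- beta[which(abs(d - dext) < 1e-14)]
  lim <- {            # ||w|| as x -> 0+, excluding the extreme block
    keep <- abs(d - dext) >= 1e-14
    if (any(keep)) sqrt(sum((beta[keep] / (d[keep] - dext))^2)) else 0
  }
  hard <- max(abs(bext)) < 1e-12 && lim < force
  if (hard) {
    # interior solution at the pole plus a free component along the
    # extreme eigenvector filling the remaining force budget
    keep <- abs(d - dext) >= 1e-14
    w <- numeric(length(d))
    w[keep] <- beta[keep] / (dext - d[keep])
    tau <- sqrt(force^2 - sum(w^2))
    w[!keep][1] <- tau
    lambda <- dext / 2
  } else {
    # bracket: wnorm is strictly decreasing in x from +inf (or lim) to 0
    lo <- 1e-14; hi <- 1
    while (wnorm(hi) > force) hi <- hi * 4
    while (wnorm(lo) < force) lo <- lo / 4
    x <- stats::uniroot(function(x) wnorm(x) - force, c(lo, hi),
                        tol = .Machine$double.eps^0.8)$root
    lambda <- (sgn * x + dext) / 2
    w <- beta / (2 * lambda - d)
  }
  dq <- drop(h0inv %*% (eg$vectors %*% w))
  fvec <- drop(p$h0 %*% dq)
  gv <- sum(p$g1 * dq) + 0.5 * sum(dq * drop((p$h1 - p$h0) %*% dq))
  structure(list(
    lambda = lambda,
    q_opt = geometry(p$q0 + dq, pes$q_ref$atoms),
    dq = dq,
    force_vector = fvec,
    force_magnitude = sqrt(sum(fvec^2)),
    gap_variation = gv,
    cos_alpha = .parallelism_cos(dq, p$h0, p$h1, p$g1),
    branch = branch,
    singular_flag = FALSE,
    convention = "lagrangian"
  ), class = "quadratic_solution")
}

#' Small-force mechanical response
#'
#' The slope of the optimal gap variation with respect to force magnitude
#' at zero force, `||H0^-1 g1||`: the first-order gap change
#' `g1' H0^-1 F` maximized over unit-norm forces.
#'
#' @param pes quadratic [two_state_pes()] at the state-0 minimum.
#' @return numeric slope in atomic units (Hartree per Hartree/Bohr);
#'   convert to the reporting scale with
#'   `unit_convert(x, "Hartree/Hartree/Bohr", "kcal/mol/nN")`.
#' @export
initial_response_slope <- function(pes) {
  p <- .quad_parts(pes)
  ev <- eigen(p$h0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev))
    stop("state-0 Hessian is singular", call. = FALSE)
  sqrt(sum(drop(chol2inv(chol(p$h0)) %*% p$g1)^2))
}

# ---- symmetry-adapted split -------------------------------------------------

#' Symmetry-adapted orthonormal basis
#'
#' Partition of the coordinate space into a totally-symmetric block (the
#' subspace containing the gap gradient) and its non-totally-symmetric
#' orthogonal complement. Point groups are not detected; the basis is
#' user-supplied or trivially the identity.
#'
#' @param sym matrix whose columns span the totally-symmetric block.
#' @param nosym matrix whose columns span the complement (may have zero
#'   columns).
#' @return object of class `"symmetry_basis"`.
#' @export
symmetry_basis <- function(sym, nosym = NULL) {
  sym <- as.matrix(sym)
  n <- nrow(sym)
  if (is.null(nosym)) nosym <- matrix(0, n, 0) else nosym <- as.matrix(nosym)
  if (nrow(nosym) != n) stop("blocks must share the row dimension", call. = FALSE)
  b <- cbind(sym, nosym)
  if (ncol(b) != n) stop("blocks must jointly span the space", call. = FALSE)
  if (max(abs(crossprod(b) - diag(n))) > 1e-10)
    stop("basis must be orthonormal to 1e-10", call. = FALSE)
  structure(list(sym = sym, nosym = nosym, n_dof = n),
            class = "symmetry_basis")
}

#' Identity basis with an empty non-symmetric block
#' @param n dimension.
#' @return a [symmetry_basis()].
#' @export
identity_basis <- function(n) symmetry_basis(diag(n))

#' Eigenvalue problem of the non-totally-symmetric block
#'
#' The multipliers at which the non-symmetric block system becomes
#' singular, i.e. all `lambda` with `(2 lambda H0^2 - H0 + H1) v = 0`
#' restricted to the block: the eigenvalues of `(H0 - H1) / (2 H0^2)` in
#' the block, solved as a symmetric generalized problem. Each eigenvalue
#' is a mechanical response of a purely non-symmetric optimal distortion.
#'
#' @param pes quadratic [two_state_pes()].
#' @param basis a [symmetry_basis()] with a nonempty non-symmetric block.
#' @return data-frame-like list: `values` (ascending) and `vectors`
#'   (full-space columns, unit norm).
#' @export
nosym_eigenvalues <- function(pes, basis) {
  p <- .quad_parts(pes)
  N <- basis$nosym
  if (ncol(N) == 0) stop("non-symmetric block is empty", call. = FALSE)
  h0b <- .sympart(crossprod(N, p$h0 %*% N))
  h1b <- .sympart(crossprod(N, p$h1 %*% N))
  ev0 <- eigen(h0b, symmetric = TRUE, only.values = TRUE)$values
  if (min(abs(ev0)) < 1e-10 * max(abs(ev0)))
    stop("state-0 Hessian block is singular", call. = FALSE)
  h0binv <- solve(h0b)
  m <- .sympart(h0binv %*% (h0b - h1b) %*% h0binv)
  eg <- eigen(m, symmetric = TRUE)
  lam <- eg$values / 2
  # eigenvectors of the pencil: v = H0b^-1 u, normalized, mapped to full space
  vecs <- apply(eg$vectors, 2, function(u) {
    v <- drop(h0binv %*% u); v / sqrt(sum(v^2))
  })
  vecs <- matrix(vecs, nrow = ncol(N))
  ord <- order(lam)
  list(values = lam[ord],
       vectors = N %*% vecs[, ord, drop = FALSE])
}

#' Block solve in a symmetry-adapted basis
#'
#' Transforms the optimality system into the basis, solves the
#' totally-symmetric block (where the gap gradient lives), and resolves
#' the non-symmetric block: zero unless `lambda` sits on the block pencil
#' spectrum, in which case the affected eigenvector directions are
#' reported as carrying infinitely many solutions rather than fabricating
#' a particular one.
#'
#' @param lambda Lagrange multiplier.
#' @param pes quadratic [two_state_pes()].
#' @param basis a [symmetry_basis()].
#' @param tol singularity tolerance for matching `lambda` to the block
#'   spectrum.
#' @return list `q_sym`, `q_nosym` (full-space vectors), `solvability`
#'   (list: `unique`, `free_directions`, `matched_lambda`), `cos_alpha`,
#'   `convention`.
#' @export
symmetry_split_solve <- function(lambda, pes, basis, tol = 1e-8) {
  p <- .quad_parts(pes)
  S <- basis$sym; N <- basis$nosym
  gN <- if (ncol(N)) drop(crossprod(N, p$g1)) else numeric(0)
  if (length(gN) && sqrt(sum(gN^2)) >= 1e-8)
    stop("g1 has non-totally-symmetric components (|g1_nosym| = ",
         format(sqrt(sum(gN^2))),
         "): the symmetry premise fails, use the general solver",
         call. = FALSE)
  off <- if (ncol(N)) max(abs(crossprod(S, p$h0 %*% N)),
                          abs(crossprod(S, p$h1 %*% N))) else 0
  if (off > 1e-8)
    warning("Hessians couple the two blocks (max off-diagonal ",
            format(off), "); the split is only approximate")

  solve_block <- function(convention) {
    mS <- crossprod(S, .opt_matrix(lambda, p$h0, p$h1, convention) %*% S)
    sv <- svd(mS, nu = 0, nv = 0)$d
    if (max(sv) <= 0 || min(sv) < 1e-8 * max(sv)) return(NULL)
    y <- solve(mS, drop(crossprod(S, p$g1)))
    dq <- drop(S %*% y)
    list(dq = dq, cos = .parallelism_cos(dq, p$h0, p$h1, p$g1))
  }
  pr <- solve_block("printed")
  used <- "printed"; sol <- pr
  if (is.null(pr) || abs(pr$cos) < 1 - 1e-9) {
    lg <- solve_block("lagrangian")
    if (!is.null(lg) && (is.null(pr) || abs(lg$cos) > abs(pr$cos))) {
      used <- "lagrangian"; sol <- lg
    }
  }
  if (is.null(sol))
    stop("symmetric block singular at this lambda in both conventions",
         call. = FALSE)

  free <- matrix(0, p$n, 0); matched <- numeric(0)
  if (ncol(N)) {
    # singular directions of the nosym block at this lambda, in the
    # convention actually used for the solve
    pencil_sign <- if (used == "printed") 1 else -1
    h0b <- .sympart(crossprod(N, p$h0 %*% N))
    h1b <- .sympart(crossprod(N, p$h1 %*% N))
    h0binv <- solve(h0b)
    m <- .sympart(h0binv %*% (pencil_sign * (h0b - h1b)) %*% h0binv)
    eg <- eigen(m, symmetric = TRUE)
    lam <- eg$values / 2
    scale <- max(abs(lam), 1)
    hit <- abs(lam - lambda) <= tol * scale
    if (any(hit)) {
      matched <- lam[hit]
      vs <- apply(eg$vectors[, hit, drop = FALSE], 2, function(u) {
        v <- drop(h0binv %*% u); v / sqrt(sum(v^2))
      })
      free <- N %*% matrix(vs, nrow = ncol(N))
    }
  }
  list(q_sym = sol$dq,
       q_nosym = numeric(p$n),
       solvability = list(unique = ncol(free) == 0,
                          free_directions = free,
                          matched_lambda = matched),
       cos_alpha = sol$cos,
       convention = used)
}
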
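# shared fixtures built in code

# canonical 1D pair: H0 = 1 (min at 0), H1 = 2, g1 = 1, vertical gap 10
pair_1d <- function() {
  two_state_pes(quadratic_surface(0, 0, 0, matrix(1)),
                quadratic_surface(0, 10, 1, matrix(2)))
}

# diagonal 2D pair used for symmetry-split examples
pair_2d_diag <- function(h0 = c(1, 1), h1 = c(2, 3), g1 = c(1, 0)) {
  two_state_pes(quadratic_surface(c(0, 0), 0, c(0, 0), diag(h0)),
                quadratic_surface(c(0, 0), 10, g1, diag(h1)))
}

# high-precision engine configuration used when comparing against oracles
tight_config <- function(force_step, force_max, ...) {
  lgmf_config(force_step = force_step, force_max = force_max,
              force_unit = "Hartree/Bohr", cos_tolerance = 1 - 1e-10,
              corrector_max_iter = 500, ...)
}

expect_budget_and_certificate <- function(ramps, pes, cos_min = 0.999,
                                          budget = 0.05) {
  for (br in c("increase", "decrease")) {
    pts <- ramps[[br]]$points
    for (p in pts[-1]) {
      expect_true(p$verified_exact)
      # recompute the certificate from the surfaces, independently of the
      # engine's bookkeeping
      p0 <- surface_eval(pes$state0, p$q, hessian = TRUE)
      p1 <- surface_eval(pes$state1, p$q, hessian = TRUE)
      gg <- p1$gradient - p0$gradient
      gf <- 2 * drop(p0$hessian %*% p0$gradient)
      ca <- sum(gg * gf) / sqrt(sum(gg^2) * sum(gf^2))
      expect_gte(abs(ca), cos_min)
      expect_lte(abs(p$force_magnitude - p$scheduled_force),
                 budget * p$scheduled_force)
    }
    f <- vapply(pts, function(p) p$force_magnitude, 0)
    expect_true(all(diff(f) > 0))
  }
}
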
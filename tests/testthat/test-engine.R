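test_that("predictor scales the displacement to the requested force increment", {
  # from a minimum: s = delta / ||H0 d_hat||
  e0 <- surface_point(0, c(0, 0), diag(c(2, 1)))
  dq <- predictor_step(e0, c(1, 0), 0.3)
  expect_equal(dq, c(0.15, 0))
  expect_equal(predictor_step(e0, c(0, 1), 0), c(0, 0))
  # away from the minimum the increment is on the magnitude, not the vector
  e1 <- surface_point(0, c(0.4, 0), diag(c(1, 1)))
  dq <- predictor_step(e1, c(1, 0), 0.1)
  expect_equal(sqrt(sum((e1$gradient + drop(e1$hessian %*% dq))^2)),
               0.4 + 0.1)
  # annihilated direction prompts a flip
  e2 <- surface_point(0, c(0, 0), diag(c(1, 0)))
  expect_error(predictor_step(e2, c(0, 1), 0.1), "direction")
  expect_error(predictor_step(e0, c(0, 0), 0.1), "nonzero")
})

test_that("model gradients follow the local expansion", {
  e0 <- surface_point(0, 0, matrix(1))
  e1 <- surface_point(10, 1, matrix(2))
  g <- approx_gradients(e0, e1, 0.5)
  expect_equal(g$grad_gap, 1.5)
  expect_equal(g$grad_force_sq, 1.0)
  # at a state-0 minimum with no displacement the force gradient vanishes
  g0 <- approx_gradients(e0, e1, 0)
  expect_equal(g0$grad_force_sq, 0)
  # on quadratic surfaces the model gradients are exact
  pes <- make_quadratic_pair(3, seed = 9)
  p0 <- surface_eval(pes$state0, c(0, 0, 0), hessian = TRUE)
  p1 <- surface_eval(pes$state1, c(0, 0, 0), hessian = TRUE)
  dq <- c(0.1, -0.2, 0.05)
  ga <- approx_gradients(p0, p1, dq)
  expect_equal(ga$grad_gap,
               surface_eval(pes$state1, dq)$gradient -
                 surface_eval(pes$state0, dq)$gradient)
})

test_that("orthogonal split is exact", {
  s <- split_perp(c(1, 1), c(1, 0))
  expect_equal(s$parallel, c(1, 0))
  expect_equal(s$perp, c(0, 1))
  s2 <- split_perp(c(3, 4), c(0, 2))
  expect_equal(s2$parallel, c(0, 4))
  expect_equal(s2$perp, c(3, 0))
  s3 <- split_perp(c(2, 4), c(1, 2))
  expect_equal(s3$perp, c(0, 0))
  expect_error(split_perp(c(1, 1), c(0, 0)), "zero")
})

test_that("corrector converges immediately on an already-optimal point", {
  pes <- pair_1d()
  p0 <- surface_eval(pes$state0, 0.5, hessian = TRUE)
  p1 <- surface_eval(pes$state1, 0.5, hessian = TRUE)
  cfg <- tight_config(0.1, 1)
  # 1D: gradients are always parallel
  st <- corrector_iterate(surface_point(0, 0, matrix(1)),
                          surface_point(10, 1, matrix(2)),
                          0.5, 0.5, cfg, 1)
  expect_true(st$converged)
  expect_equal(st$dq, 0.5)
  # anti-parallel gradients count as converged (180 degrees)
  cfg2 <- lgmf_config(force_step = 0.1, force_max = 1,
                      force_unit = "Hartree/Bohr", cos_tolerance = 0.999)
  e0 <- surface_point(0, c(0.3, 0), diag(2))
  e1 <- surface_point(1, c(-0.6, 1e-4), diag(2))
  st2 <- corrector_iterate(e0, e1, c(0, 0), 0.3, cfg2, 1)
  expect_true(st2$converged)
  expect_lt(st2$cos_alpha, -0.999)
})

test_that("corrector reduces the perpendicular component along a continuation step", {
  # continuation regime: expand at an optimized point, predict a small
  # force increment along the previous displacement, then correct
  pes <- make_quadratic_pair(2, seed = 12)
  cfg <- tight_config(0.002, 0.1)
  opt <- quadratic_optimum_at_force(pes, 0.008, "increase")
  p0 <- surface_eval(pes$state0, opt$q_opt, hessian = TRUE)
  p1 <- surface_eval(pes$state1, opt$q_opt, hessian = TRUE)
  dq <- predictor_step(p0, opt$dq, 0.002)
  pns <- numeric(0)
  cc <- cfg$corrector_constant
  for (i in 1:50) {
    st <- corrector_iterate(p0, p1, dq, 0.010, cfg, 1, cc)
    pns <- c(pns, st$perp_norm)
    if (st$converged) break
    dq <- st$dq; cc <- st$step_constant
  }
  expect_true(st$converged)
  expect_true(all(diff(pns) <= 1e-12))
  # and the converged displacement reproduces the closed form
  cf <- quadratic_optimum_at_force(pes, 0.010, "increase")
  expect_equal(gap_variation(pes, opt$q_opt$coords + st$dq),
               cf$gap_variation, tolerance = 1e-8)
})

test_that("force budget applies the five-percent rule", {
  cfg <- lgmf_config()
  expect_equal(enforce_force_budget(1.04, 1.0, cfg), "ok")
  expect_equal(enforce_force_budget(1.06, 1.0, cfg), "recalibrate")
  expect_equal(enforce_force_budget(1.0, 1.0, cfg), "ok")
  expect_error(enforce_force_budget(1, 0, cfg), "scheduled_force")
})

test_that("BFGS update satisfies the secant condition and fixed point", {
  h <- bfgs_update(diag(2), c(1, 0), c(2, 0))
  expect_equal(h, diag(c(2, 1)))
  set.seed(3)
  for (k in 1:10) {
    n <- sample(2:6, 1)
    h0 <- crossprod(matrix(rnorm(n * n), n)) + diag(n)
    dq <- rnorm(n)
    y <- drop(crossprod(matrix(rnorm(n * n), n)) %*% dq) + dq
    h1 <- bfgs_update(h0, dq, y)
    expect_lt(max(abs(drop(h1 %*% dq) - y)), 1e-12)
    expect_equal(h1, t(h1))
  }
  # y = H dq leaves H unchanged
  h0 <- diag(c(2, 3))
  expect_equal(bfgs_update(h0, c(1, 1), drop(h0 %*% c(1, 1))), h0)
  expect_error(bfgs_update(diag(2), c(1, 0), c(-1, 0)),
               class = "lgmf_curvature_error")
})

test_that("exact verification certifies quadratic points and the start", {
  pes <- make_quadratic_pair(4, seed = 18)
  cfg <- tight_config(0.005, 0.02)
  ramps <- run_ramp(pes, cfg)
  p <- ramps$increase$points[[length(ramps$increase$points)]]
  v <- verify_exact(pes, p$q, cfg)
  expect_true(v$verified)
  # the unforced minimum verifies trivially (degenerate certificate)
  v0 <- verify_exact(pes, c(0, 0, 0, 0), cfg)
  expect_true(v0$verified)
  expect_equal(v0$force_magnitude, 0)
})

test_that("ramps reproduce the closed form on quadratic pairs", {
  pes <- make_quadratic_pair(6, seed = 41)
  cfg <- tight_config(0.004, 0.024)
  ramps <- run_ramp(pes, cfg)
  for (br in c("increase", "decrease")) {
    df <- as.data.frame(ramps[[br]])
    expect_equal(ramps[[br]]$termination_reason, "ceiling")
    for (i in 2:nrow(df)) {
      cf <- quadratic_optimum_at_force(pes, df$force[i], br)
      expect_equal(df$gap_variation[i], cf$gap_variation,
                   tolerance = 1e-8)
    }
  }
  expect_budget_and_certificate(ramps, pes)
})

test_that("branch duality holds from the minimum", {
  for (seed in c(5, 23, 61)) {
    pes <- make_quadratic_pair(2, seed = seed)
    cfg <- tight_config(0.01, 0.02)
    ramps <- run_ramp(pes, cfg)
    gi <- ramps$increase$points[[2]]$gap_variation
    gd <- ramps$decrease$points[[2]]$gap_variation
    expect_gt(gi, 0)
    expect_lt(gd, 0)
    # signs agree with the dense oracle
    bf <- brute_force_optimum(pes, ramps$increase$points[[2]]$force_magnitude,
                              resolution = 120)
    expect_gt(bf$increase$gap_variation, 0)
    expect_lt(bf$decrease$gap_variation, 0)
  }
})

test_that("a ceiling below one step yields only the start point", {
  pes <- make_quadratic_pair(3, seed = 4)
  cfg <- lgmf_config(force_step = 0.01, force_max = 0.005,
                     force_unit = "Hartree/Bohr")
  ramps <- run_ramp(pes, cfg)
  expect_length(ramps$increase$points, 1)
  expect_length(ramps$decrease$points, 1)
  expect_equal(ramps$increase$points[[1]]$gap_variation, 0)
})

test_that("run_ramp rejects an unoptimized start point", {
  pes <- make_quadratic_pair(3, seed = 4)
  expect_error(run_ramp(pes, lgmf_config(), q_start = c(0.5, 0, 0)),
               "not an optimized point")
})

test_that("oversized steps trigger re-expansion on anharmonic surfaces and still verify", {
  pes <- make_model2d_pair()
  cfg <- tight_config(unit_convert(0.25, "nN", "Hartree/Bohr"),
                      unit_convert(1.0, "nN", "Hartree/Bohr"))
  ramps <- run_ramp(pes, cfg)
  reex <- unlist(lapply(c(ramps$increase$points, ramps$decrease$points),
                        function(p) p$n_reexpansions))
  expect_gt(max(reex), 0)  # exact verification failed at least once
  expect_equal(ramps$increase$termination_reason, "ceiling")
  expect_equal(ramps$decrease$termination_reason, "ceiling")
  expect_budget_and_certificate(ramps, pes)
})

test_that("BFGS-policy ramps coincide with exact-Hessian ramps on quadratics", {
  pes <- make_quadratic_pair(5, seed = 13)
  base <- list(force_step = 0.005, force_max = 0.03)
  re <- run_ramp(pes, tight_config(base$force_step, base$force_max))
  rb <- run_ramp(pes, tight_config(base$force_step, base$force_max,
                                   hessian_policy = "bfgs"))
  for (br in c("increase", "decrease")) {
    de <- as.data.frame(re[[br]]); db <- as.data.frame(rb[[br]])
    n <- min(nrow(de), nrow(db))
    expect_gt(n, 3)
    expect_lt(max(abs(de$gap_variation[1:n] - db$gap_variation[1:n])), 1e-4)
  }
})

test_that("the first-point slope approaches the zero-force response", {
  pes <- make_quadratic_pair(4, seed = 29)
  slope <- initial_response_slope(pes)
  f1 <- 1e-3 * sqrt(sum(pes$state1$g_ref^2))
  cfg <- tight_config(f1, f1)
  ramps <- run_ramp(pes, cfg)
  for (br in c("increase", "decrease")) {
    p <- ramps[[br]]$points[[2]]
    expect_equal(abs(p$gap_variation) / p$force_magnitude, slope,
                 tolerance = 0.01)
  }
})
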
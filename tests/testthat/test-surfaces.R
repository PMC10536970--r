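test_that("quadratic evaluation reproduces the second-order polynomial", {
  s <- quadratic_surface(0, e_ref = 10, g_ref = 0, h_ref = 1)
  p <- surface_eval(s, 0, hessian = TRUE)
  expect_equal(p$energy, 10)
  expect_equal(p$gradient, 0)
  expect_equal(p$hessian, matrix(1))
  p <- surface_eval(s, 0.5)
  expect_equal(p$energy, 10.125)
  expect_equal(p$gradient, 0.5)
  expect_error(surface_eval(s, c(1, 2)), "dimension mismatch")
})

test_that("analytic gradients match finite differences on random quadratics", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    h <- crossprod(matrix(rnorm(n * n), n))
    s <- quadratic_surface(rnorm(n), rnorm(1), rnorm(n), h)
    for (k in 1:20) {
      q <- rnorm(n)
      g <- surface_eval(s, q)$gradient
      gfd <- vapply(seq_len(n), function(i) {
        e <- 1e-5; qp <- q; qm <- q
        qp[i] <- qp[i] + e; qm[i] <- qm[i] - e
        (surface_eval(s, qp)$energy - surface_eval(s, qm)$energy) / (2 * e)
      }, 0)
      expect_lt(max(abs(g - gfd)), 1e-7)
    }
  }
})

test_that("anharmonic model surfaces have consistent derivatives and minima", {
  surfs <- list(
    morse_surface(0.18, 1.0, c(0, 0, 0)),
    quartic_surface(diag(c(0.3, 1.2)), c(0.05, 0), c(0, 0)),
    make_model2d_pair()$state0,
    make_model2d_pair()$state1
  )
  set.seed(4)
  for (s in surfs) {
    n <- surface_dim(s)
    for (k in 1:5) {
      q <- rnorm(n, sd = 0.4)
      p <- surface_eval(s, q, hessian = TRUE)
      gfd <- vapply(seq_len(n), function(i) {
        e <- 1e-6; qp <- q; qm <- q
        qp[i] <- qp[i] + e; qm[i] <- qm[i] - e
        (surface_eval(s, qp)$energy - surface_eval(s, qm)$energy) / (2 * e)
      }, 0)
      expect_lt(max(abs(p$gradient - gfd)), 1e-6)
      hfd <- finite_difference_hessian(
        function(z) surface_eval(s, z)$gradient, q, step = 1e-5)
      expect_lt(max(abs(p$hessian - hfd)), 1e-6)
    }
  }
  # declared minima really are stationary
  m <- morse_surface(c(0.2, 0.1), c(1.2, 0.8), c(0.3, -0.2))
  expect_lt(sqrt(sum(surface_eval(m, m$center)$gradient^2)), 1e-8)
})

test_that("energy gap and gap variation follow the two-state definition", {
  pes <- pair_1d()
  expect_equal(energy_gap(pes, 0), 10)
  expect_equal(energy_gap(pes, 0.5), 10.625)
  expect_equal(gap_variation(pes, 0.5), 0.625)
  # identical surfaces: gap variation vanishes everywhere
  s <- quadratic_surface(c(0, 0), 1, c(0.2, -0.1), diag(2))
  same <- two_state_pes(s, s)
  for (q in list(c(0, 0), c(1, -2), c(0.3, 0.7)))
    expect_equal(gap_variation(same, q), 0)
})

test_that("external force is the state-0 gradient with its Euclidean norm", {
  pes <- pair_1d()
  expect_equal(external_force(pes, 0)$magnitude, 0)
  expect_equal(external_force(pes, 0.5)$vector, 0.5)
  pes2 <- two_state_pes(quadratic_surface(c(0, 0), 0, c(0, 0), diag(2)),
                        quadratic_surface(c(0, 0), 1, c(1, 0), diag(2)))
  f <- external_force(pes2, c(0.3, 0.4))
  expect_equal(f$magnitude, 0.5)
  # any stationary point of state 0 carries zero external force
  expect_lt(external_force(make_model2d_pair(), c(0, 0))$magnitude, 1e-10)
})

test_that("seeded quadratic pairs are deterministic with controlled spectra", {
  a <- make_quadratic_pair(4, seed = 7)
  b <- make_quadratic_pair(4, seed = 7)
  expect_identical(a$state0$h_ref, b$state0$h_ref)
  expect_identical(a$state1$g_ref, b$state1$g_ref)
  # byte-identical after serialization
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_pes_json(a, f1); write_pes_json(b, f2)
  expect_identical(readLines(f1), readLines(f2))

  ev <- eigen(a$state0$h_ref, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= 0.2 - 1e-12 & ev <= 1.5 + 1e-12))
  ev1 <- eigen(a$state1$h_ref, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev1 >= 0.15 - 1e-12 & ev1 <= 1.8 + 1e-12))
  expect_equal(sqrt(sum(a$state1$g_ref^2)), 0.1)
  expect_error(make_quadratic_pair(3, 1, spectrum0 = c(-1, 1)),
               "must be positive")

  # zero gap gradient: the optimum for any multiplier is the origin
  z <- make_quadratic_pair(3, seed = 5, g1_scale = 0)
  sol <- optimal_structure(0.3, z)
  expect_equal(sol$dq, c(0, 0, 0))
  expect_equal(sol$gap_variation, 0)
})

test_that("the generator RNG stream does not leak into the session", {
  set.seed(123); before <- .Random.seed
  invisible(make_quadratic_pair(5, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("brute-force search solves the 1D constrained problem exactly", {
  pes <- pair_1d()
  bf <- brute_force_optimum(pes, 0.5)
  expect_equal(bf$increase$q$coords, 0.5, tolerance = 1e-10)
  expect_equal(bf$increase$gap_variation, 0.625, tolerance = 1e-10)
  expect_equal(bf$decrease$q$coords, -0.5, tolerance = 1e-10)
  expect_equal(bf$decrease$gap_variation, -0.375, tolerance = 1e-10)
  z <- brute_force_optimum(pes, 0)
  expect_equal(z$increase$gap_variation, 0)
  expect_equal(z$increase$q$coords, 0)
  expect_error(brute_force_optimum(pes, 50, box = 2), "unreachable")
  expect_error(brute_force_optimum(make_quadratic_pair(3, 1), 0.1),
               "at most 2 dof")
})

test_that("brute force agrees with the closed form in 2D, tightening under refinement", {
  pes <- make_quadratic_pair(2, seed = 21)
  f <- 0.02
  errs <- vapply(c(60, 240), function(res) {
    bf <- brute_force_optimum(pes, f, resolution = res)
    cf_i <- quadratic_optimum_at_force(pes, f, "increase")
    cf_d <- quadratic_optimum_at_force(pes, f, "decrease")
    max(abs(bf$increase$gap_variation - cf_i$gap_variation),
        abs(bf$decrease$gap_variation - cf_d$gap_variation))
  }, 0)
  expect_lt(errs[2], 1e-8)
  expect_lte(errs[2], errs[1] + 1e-12)
})

test_that("backend adapter serves finite-difference Hessians when needed", {
  h <- matrix(c(2, 0.3, 0.3, 1), 2)
  fun <- function(q, want_h) {
    list(energy = 0.5 * sum(q * (h %*% q)), gradient = drop(h %*% q),
         hessian = NULL)
  }
  s <- backend_surface(fun, 2, analytic_hessian = FALSE)
  p <- surface_eval(s, c(0.1, -0.2), hessian = TRUE)
  expect_equal(p$hessian, h, tolerance = 1e-8)
  bad <- backend_surface(function(q, w) list(energy = 0, gradient = 1), 2)
  expect_error(surface_eval(bad, c(0, 0)), "length")
})
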
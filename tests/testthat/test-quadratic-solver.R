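test_that("equilibrium displacement solves H0 dq = F", {
  expect_equal(equilibrium_structure(diag(2), c(0, 0)), c(0, 0))
  expect_equal(equilibrium_structure(diag(c(1, 2)), c(1, 1)), c(1, 0.5))
  expect_error(equilibrium_structure(diag(c(1, 0)), c(1, 1)),
               "offending eigenvalue 0")
  expect_error(equilibrium_structure(diag(c(1, -2)), c(1, 1)), "indefinite")
})

test_that("optimal structure matches the scalar closed form in 1D", {
  pes <- pair_1d()
  s0 <- optimal_structure(0, pes)
  expect_equal(s0$dq, 1)
  expect_equal(s0$force_magnitude, 1)
  s5 <- optimal_structure(0.5, pes)
  expect_equal(s5$dq, 0.5)
  expect_equal(s5$force_magnitude, 0.5)
  expect_equal(s5$gap_variation, 0.625)
  # infinite-penalty limit: displacement, force and gap variation vanish
  for (lam in c(1e6, -1e6)) {
    s <- optimal_structure(lam, pes)
    expect_lt(abs(s$dq), 1e-5)
    expect_lt(abs(s$gap_variation), 1e-5)
  }
})

test_that("solutions satisfy the parallelism condition across random pairs", {
  lambdas <- c(-0.8, -0.2, 0.1, 0.6, 2.0)
  for (k in 1:50) {
    pes <- make_quadratic_pair(sample(2:8, 1), seed = 1000 + k)
    for (lam in lambdas) {
      s <- optimal_structure(lam, pes)
      if (s$singular_flag) next
      expect_gte(abs(s$cos_alpha), 0.999)
    }
  }
})

test_that("lambda scan partitions branches and drops singular values", {
  pes <- pair_1d()
  sc <- lambda_scan(pes, c(0, 0.5))
  inc <- as.data.frame(sc$increase)
  expect_equal(sort(inc$force), c(0.5, 1))
  expect_true(all(diff(inc$force) > 0))  # sorted by force magnitude

  # degenerate pair (H1 = H0): printed-form singularity at lambda = 0
  deg <- two_state_pes(quadratic_surface(0, 0, 0, matrix(1)),
                       quadratic_surface(0, 5, 1, matrix(1)))
  expect_message(sc2 <- lambda_scan(deg, c(-0.4, 0, 0.4)), "dropped")
  expect_equal(sc2$dropped, 0)

  expect_error(lambda_scan(pes, numeric(0)), "empty")

  # first entries of the two branches have opposite-sign gap variation
  pes2 <- make_quadratic_pair(2, seed = 31)
  sc3 <- lambda_scan(pes2, seq(-3, 3, by = 0.11))
  gi <- as.data.frame(sc3$increase)$gap_variation
  gd <- as.data.frame(sc3$decrease)$gap_variation
  expect_gt(gi[1], 0)
  expect_lt(gd[1], 0)
})

test_that("scan solutions coincide with the brute-force oracle on 2D pairs", {
  pes <- make_quadratic_pair(2, seed = 8)
  sc <- lambda_scan(pes, seq(-2, 2, by = 0.23))
  for (br in c("increase", "decrease")) {
    df <- as.data.frame(sc[[br]])
    rows <- df[df$force > 1e-4 & df$force < 0.05, ]
    for (i in seq_len(min(3, nrow(rows)))) {
      bf <- brute_force_optimum(pes, rows$force[i], resolution = 240)[[br]]
      expect_equal(rows$gap_variation[i], bf$gap_variation,
                   tolerance = 1e-6)
    }
  }
})

test_that("non-symmetric block eigenvalues reduce to per-coordinate scalars", {
  # 1D block: lambda = (H0 - H1) / (2 H0^2)
  pes <- pair_2d_diag(h0 = c(1, 1), h1 = c(2, 3), g1 = c(1, 0))
  b <- symmetry_basis(diag(2)[, 1, drop = FALSE], diag(2)[, 2, drop = FALSE])
  e <- nosym_eigenvalues(pes, b)
  expect_equal(e$values, -1)

  # degenerate pair: all eigenvalues zero
  pesd <- pair_2d_diag(h0 = c(1, 2), h1 = c(1, 2), g1 = c(1, 0))
  bd <- symmetry_basis(diag(2)[, 1, drop = FALSE], diag(2)[, 2, drop = FALSE])
  expect_equal(nosym_eigenvalues(pesd, bd)$values, 0)

  # 2D block, diagonal: {-1, -0.5} with coordinate eigenvectors
  pes3 <- two_state_pes(
    quadratic_surface(c(0, 0, 0), 0, c(0, 0, 0), diag(c(1, 1, 1))),
    quadratic_surface(c(0, 0, 0), 10, c(1, 0, 0), diag(c(2, 2, 3))))
  b3 <- symmetry_basis(diag(3)[, 1, drop = FALSE], diag(3)[, 2:3])
  e3 <- nosym_eigenvalues(pes3, b3)
  expect_equal(e3$values, c(-1, -0.5))
  expect_equal(abs(e3$vectors), cbind(c(0, 0, 1), c(0, 1, 0)),
               tolerance = 1e-12)

  expect_error(nosym_eigenvalues(pes, symmetry_basis(diag(2))), "empty")
})

test_that("symmetry-split solve matches the general solver and flags free directions", {
  pes <- pair_2d_diag()
  b <- symmetry_basis(diag(2)[, 1, drop = FALSE], diag(2)[, 2, drop = FALSE])
  sp <- symmetry_split_solve(0.2, pes, b)
  # scalar symmetric block: (2*0.2*1 - 1 + 2) q = 1
  expect_equal(sp$q_sym, c(1 / 1.4, 0))
  expect_equal(sp$q_nosym, c(0, 0))
  expect_true(sp$solvability$unique)

  # identity basis reduces to the general solver
  full <- optimal_structure(0.2, pes)
  spi <- symmetry_split_solve(0.2, pes, identity_basis(2))
  expect_equal(spi$q_sym, full$dq, tolerance = 1e-12)

  # lambda on the block spectrum: one free direction reported
  sp2 <- symmetry_split_solve(-1, pes, b)
  expect_false(sp2$solvability$unique)
  expect_equal(ncol(sp2$solvability$free_directions), 1)
  expect_equal(abs(sp2$solvability$free_directions[, 1]), c(0, 1))

  # non-symmetric gap gradient violates the premise
  bad <- pair_2d_diag(g1 = c(1, 0.5))
  expect_error(symmetry_split_solve(0.2, bad, b), "general solver")
})

test_that("block-structured pairs keep the general solution symmetric", {
  # H0, H1 block diagonal and g1 in the first block: the full solve must
  # put nothing in the second block (agreement of the two solver paths)
  set.seed(17)
  for (k in 1:5) {
    h0a <- crossprod(matrix(rnorm(4), 2)) + diag(2)
    h0b <- crossprod(matrix(rnorm(4), 2)) + diag(2)
    h1a <- crossprod(matrix(rnorm(4), 2)) + 0.5 * diag(2)
    h1b <- crossprod(matrix(rnorm(4), 2)) + 0.5 * diag(2)
    blockdiag <- function(a, b) rbind(cbind(a, matrix(0, 2, 2)),
                                      cbind(matrix(0, 2, 2), b))
    g1 <- c(rnorm(2), 0, 0)
    pes <- two_state_pes(
      quadratic_surface(numeric(4), 0, numeric(4), blockdiag(h0a, h0b)),
      quadratic_surface(numeric(4), 1, g1, blockdiag(h1a, h1b)))
    sol <- optimal_structure(0.37, pes)
    expect_false(sol$singular_flag)
    expect_lt(max(abs(sol$dq[3:4])), 1e-8)
  }
})

test_that("small-force response slope equals the closed-form limit", {
  pes <- two_state_pes(quadratic_surface(c(0, 0), 0, c(0, 0), diag(2)),
                       quadratic_surface(c(0, 0), 1, c(3, 4), diag(2)))
  expect_equal(initial_response_slope(pes), 5)
  expect_equal(initial_response_slope(pair_1d()), 1)
  z <- make_quadratic_pair(3, seed = 2, g1_scale = 0)
  expect_equal(initial_response_slope(z), 0)

  # ratio of gap variation to force tends to the slope at small force
  pes2 <- make_quadratic_pair(5, seed = 77)
  slope <- initial_response_slope(pes2)
  f <- 1e-3 * sqrt(sum(pes2$state1$g_ref^2))
  for (br in c("increase", "decrease")) {
    s <- quadratic_optimum_at_force(pes2, f, br)
    expect_equal(abs(s$gap_variation) / s$force_magnitude, slope,
                 tolerance = 0.01)
  }
})

test_that("secular inversion agrees with the multiplier scan", {
  pes <- make_quadratic_pair(6, seed = 55)
  for (br in c("increase", "decrease")) {
    s <- quadratic_optimum_at_force(pes, 0.01, br)
    expect_equal(s$force_magnitude, 0.01, tolerance = 1e-10)
    # the returned multiplier reproduces the same point through the
    # general solver
    s2 <- optimal_structure(s$lambda, pes)
    expect_equal(s2$dq, s$dq, tolerance = 1e-8)
    expect_gte(abs(s$cos_alpha), 0.999999)
  }
})
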
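# Directional selection: kernels vs closed forms, singular strategies,
# boundary pinning, convergence stability.

test_that("generic age kernels equal the model-specific closed forms", {
  m <- sym_model()
  v <- c(0.5, 0.45)
  sg <- selection_gradient(m, v)
  ck <- sn_gradient_kernels(sym_params(), v)
  # compare on the generic grid via interpolation of the analytic kernels
  for (j in 1:2) {
    gk <- sg$kernels[, j]
    ak <- stats::spline(ck$age, ck$kernels[, j], xout = sg$age)$y
    expect_lt(max(abs(gk - ak)) / max(abs(ak)), 1e-4)
  }
  expect_equal(unname(sg$total), ck$total, tolerance = 1e-5)
})

test_that("age kernels integrate to zero at the singular strategy", {
  st <- sym_state()
  sg <- selection_gradient(sym_model(), st$v, state = st)
  expect_lt(max(abs(sg$total)), 1e-6)
  # and the kernels themselves cross zero (early gain, late cost of growth)
  expect_gt(sg$kernels[2, 1], 0)
  expect_lt(sg$kernels[nrow(sg$kernels) %/% 2, 1], 0)
})

test_that("without size matching the male kernel is non-positive at positive traits", {
  p0 <- sexual_niche_params(kappa = 0)
  m0 <- sexual_niche_model(p0)
  for (vm in c(0.1, 0.3, 0.6)) {
    sg <- selection_gradient(m0, c(0.5, vm))
    expect_true(all(sg$kernels[, 2] <= 1e-12))
    expect_lt(sg$total[2], 0)
  }
})

test_that("a steeper female survival cost weakens selection for female growth", {
  v <- c(0.5, 0.45)
  g1 <- selection_gradient(sym_model(), v)$total[1]
  p2 <- sym_params(); p2$beta_f <- 2 * p2$beta_f
  g2 <- selection_gradient(sexual_niche_model(p2), v)$total[1]
  expect_lt(g2, g1)
})

test_that("shared-trait kernels sum the sex-specific ones", {
  m <- sym_model()
  vl <- 0.36
  sg <- selection_gradient(m, c(vl, vl), constraints = list(c(1L, 2L)))
  expect_equal(unname(sg$constrained_total[1]),
               unname(sg$total[1] + sg$total[2]), tolerance = 1e-12)
})

test_that("newton and fixed-point routes agree on the singular strategy", {
  fp <- sn_fixed_point(sym_params(), c(0.5, 0.45))
  expect_true(fp$converged)
  expect_lt(max(abs(fp$v - sym_vstar())), 1e-3)
  fps <- sn_fixed_point(sym_params(), 0.4, shared = TRUE)
  expect_lt(abs(fps$v[1] - sym_vl()), 1e-3)
})

test_that("grid search locates the same singular strategy as newton", {
  ss <- find_singular_strategy(sym_model(), c(0.45, 0.5), method = "grid",
                               grid_n = 5L)
  expect_true(ss$converged)
  expect_lt(max(abs(ss$v_flat - sym_vstar())), 1e-5)
})

test_that("pure survival cost pins the male trait at the boundary", {
  p0 <- sexual_niche_params(kappa = 0)
  m0 <- sexual_niche_model(p0)
  ss <- find_singular_strategy(m0, c(0.5, 0.3))
  expect_true(ss$converged)
  expect_equal(ss$v_flat[2], 0)
  # female singular value is unchanged by kappa (no feedback from males)
  expect_equal(ss$v_flat[1], sym_vstar()[1], tolerance = 1e-6)
})

test_that("the symmetric singular strategy is strongly convergence stable", {
  jr <- convergence_stability(sym_model(), sym_vstar())
  expect_equal(jr$label, "strongly_convergence_stable")
  expect_lt(jr$leading, 0)
  expect_true(jr$isotropic_stable)
})

test_that("selection kernels for single-channel mutations recover the classic age weights", {
  # state-dependent fecundity but z-independent development, so that the
  # remaining-reproduction profile differs in shape from survivorship
  base <- haploid_model()
  base$fecundity <- function(i, j, z, x, env) x[, 1L]
  base$growth <- function(j, z, x, env) 0.4 - x[, 1L]
  # mortality-only channel: kernel proportional to remaining reproduction
  m_mu <- base
  m_mu$mortality <- function(j, z, x, env) rep(0.3 + 0.1 * z[1L], nrow(x))
  st <- ontosel:::analysis_state(m_mu, 0.5, n_grid = 501L)
  kern <- ontosel:::age_specific_gradient(m_mu, 0.5, st)[, 1]
  rr <- st$costates$lambda_l_surv[, 1]  # lambda_l * survivorship
  keep <- rr > 1e-5 * max(rr)
  ratio <- kern[keep] / rr[keep]
  expect_lt(diff(range(ratio)) / abs(mean(ratio)), 1e-5)
  # check the shapes genuinely differ (the test would otherwise be vacuous)
  lj0 <- st$traj$surv[, 1]
  expect_gt(diff(range(rr[keep] / lj0[keep])) / mean(rr[keep] / lj0[keep]), 0.1)
  # fecundity-only channel: kernel proportional to survivorship
  m_f <- base
  m_f$fecundity <- function(i, j, z, x, env) x[, 1L] + 0.1 * z[1L]
  st2 <- ontosel:::analysis_state(m_f, 0.5, n_grid = 501L)
  kern2 <- ontosel:::age_specific_gradient(m_f, 0.5, st2)[, 1]
  lj <- st2$traj$surv[, 1]
  keep2 <- lj > 1e-5
  ratio2 <- kern2[keep2] / lj[keep2]
  expect_lt(diff(range(ratio2)) / abs(mean(ratio2)), 1e-5)
})
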
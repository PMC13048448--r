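# The worked model: demography, male competition, Fisher's condition,
# comparative statics.

test_that("resident demography closed forms are internally consistent", {
  p <- sym_params()
  v <- c(0.5, 0.45)
  dem <- resident_demography(p, v)
  # symmetric mortalities and c = 1/2 give an even secondary sex ratio
  demsym <- resident_demography(p, c(0.5, 0.5))
  expect_equal(demsym$secondary_sex_ratio, 0.5)
  # NT from the closed-form lifetime size integral v/(mu(mu+alpha))
  intlx <- integrate(function(a) exp(-dem$mu_f * a) * v[1] *
                       (1 - exp(-p$alpha * a)) / p$alpha, 0, Inf)$value
  expect_equal(intlx, v[1] / (dem$mu_f * (dem$mu_f + p$alpha)), tolerance = 1e-8)
  expect_equal(dem$NT, p$K * (1 - 1 / ((1 - p$c) * intlx)), tolerance = 1e-6)
  # size densities integrate to one and have mean v/(mu+alpha)
  for (sex in c("f", "m")) {
    mu <- if (sex == "f") dem$mu_f else dem$mu_m
    vj <- if (sex == "f") v[1] else v[2]
    tot <- integrate(dem$chi[[sex]], 0, vj / p$alpha, rel.tol = 1e-10)$value
    expect_equal(tot, 1, tolerance = 1e-6)
    avg <- integrate(function(x) x * dem$chi[[sex]](x), 0, vj / p$alpha,
                     rel.tol = 1e-10)$value
    expect_equal(avg, vj / (mu + p$alpha), tolerance = 1e-6)
    expect_equal(unname(dem$mean_size[sex]), vj / (mu + p$alpha))
  }
})

test_that("size densities increase with size iff size loss outpaces mortality", {
  p <- sexual_niche_params(alpha = 0.1, mu_e_f = 0.05, beta_f = 0.1)
  dem_small <- resident_demography(p, c(0.4, 0.4))   # mu_f = 0.066 < alpha
  xs <- seq(0.2, 3.5, length.out = 20)
  expect_true(all(diff(dem_small$chi$f(xs)) > 0))
  dem_big <- resident_demography(p, c(1.4, 0.4))     # mu_f = 0.246 > alpha
  xs2 <- seq(0.2, 13, length.out = 20)
  expect_true(all(diff(dem_big$chi$f(xs2)) < 0))
})

test_that("extinction is flagged when recruitment cannot compensate mortality", {
  p <- sexual_niche_params(mu_e_f = 0.6)
  dem <- resident_demography(p, c(0.5, 0.5))
  expect_true(dem$extinct)
  expect_lt(dem$NT, 0)
  # analyses still run on the formal demography
  expect_silent(sn_gradient_kernels(p, c(0.5, 0.5), n_age = 1001L))
})

test_that("male fertilisation shares are normalised over resident males", {
  p <- sym_params()
  v <- c(0.5, 0.45)
  env <- ontosel:::sn_env(p, v)
  dem <- resident_demography(p, v)
  # int over males of (share of one egg) = 1 for any female size
  for (xf in c(0.3, 1.2, 2.2)) {
    denom <- integrate(function(xm) {
      dem$secondary_sex_ratio * dem$NT * dem$chi$m(xm) *
        exp(-p$kappa * (xm - xf)^2)
    }, 0, dem$x_max["m"], rel.tol = 1e-9)$value
    num <- integrate(function(xm) {
      dem$secondary_sex_ratio * dem$NT * dem$chi$m(xm) *
        exp(-p$kappa * (xm - xf)^2) / denom
    }, 0, dem$x_max["m"], rel.tol = 1e-9)$value
    expect_equal(num, 1, tolerance = 1e-6)
  }
})

test_that("total male siring balances total female egg production (Fisher's condition)", {
  p <- asym_params()
  v <- c(0.7, 0.5)
  dem <- resident_demography(p, v)
  env <- ontosel:::sn_env(p, v, n_nodes = 400L)
  male_total <- integrate(function(a) {
    dem$mu_m * exp(-dem$mu_m * a) *
      env$fm_of(v[2] * (1 - exp(-p$alpha * a)) / p$alpha)
  }, 0, 400, rel.tol = 1e-10)$value * dem$secondary_sex_ratio * dem$NT
  female_total <- integrate(function(a) {
    dem$mu_f * exp(-dem$mu_f * a) * dem$phi * v[1] *
      (1 - exp(-p$alpha * a)) / p$alpha
  }, 0, 400, rel.tol = 1e-10)$value * (1 - dem$secondary_sex_ratio) * dem$NT
  expect_equal(male_total, female_total, tolerance = 1e-6)
})

test_that("without size matching every male sires equally", {
  p0 <- sexual_niche_params(kappa = 0)
  v <- c(0.5, 0.45)
  dem <- resident_demography(p0, v)
  fm <- male_fecundity(p0, v, c(0.1, 0.9, 1.9))
  expect_lt(diff(range(fm)) / mean(fm), 1e-10)
  # equal shares: total female egg rate divided by male density
  eggs <- integrate(function(x) dem$chi$f(x) * x * dem$phi, 0, dem$x_max["f"],
                    rel.tol = 1e-10)$value * (1 - dem$secondary_sex_ratio) * dem$NT
  expect_equal(fm[1], eggs / (dem$secondary_sex_ratio * dem$NT), tolerance = 1e-6)
})

test_that("model rates have the declared structure", {
  p <- sym_params()
  m <- sexual_niche_model(p)
  env <- ontosel:::prepare_env(m, matrix(c(0.5, 0.45), 2, 1))
  # growth is z at size zero, zero at the maximum size z/alpha
  expect_equal(m$growth(1, 0.5, matrix(0), env), 0.5)
  expect_equal(m$growth(1, 0.5, matrix(0.5 / p$alpha), env), 0)
  # mortality at zero allocation equals the extrinsic rate
  expect_equal(m$mortality(1, 0, matrix(1), env), p$mu_e_f)
  # female fecundity is linear in size with slope 1 - NT/K
  f1 <- m$fecundity(1, 1, 0.5, matrix(1), env) + m$fecundity(2, 1, 0.5, matrix(1), env)
  f2 <- m$fecundity(1, 1, 0.5, matrix(2), env) + m$fecundity(2, 1, 0.5, matrix(2), env)
  expect_equal(f2 - f1, env$phi, tolerance = 1e-12)
})

test_that("parameters round-trip through the YAML config format", {
  p <- asym_params()
  path <- tempfile(fileext = ".yaml")
  write_sn_params(p, path)
  p2 <- read_sn_params(path)
  expect_equal(unclass(p2), unclass(p))
})

test_that("singular growth rates shift with parameters as the life-history logic predicts", {
  # finite parameter perturbations around the symmetric point, via the
  # fixed-point route (fast and independent of the newton machinery)
  base <- sym_params()
  v0 <- sym_vstar()
  solve_at <- function(p) sn_fixed_point(p, v0, n_age = 2001L)$v
  bump <- function(field, fac = 1.15) {
    p <- base
    p[[field]] <- p[[field]] * fac
    solve_at(p)
  }
  vb <- solve_at(base)
  # steeper female survival cost: slower female growth
  expect_lt(bump("beta_f")[1], vb[1])
  # higher female extrinsic mortality: faster female growth
  expect_gt(bump("mu_e_f")[1], vb[1])
  # male analogues
  expect_lt(bump("beta_m")[2], vb[2])
  expect_gt(bump("mu_e_m")[2], vb[2])
  # faster size loss: females grow faster, males slower (they track females)
  va <- bump("alpha")
  expect_gt(va[1], vb[1])
  expect_lt(va[2], vb[2])
})

test_that("the shared-trait equilibrium sits below both sex-specific optima", {
  expect_lt(sym_vl(), min(sym_vstar()))
  expect_lt(asym_vl(), min(asym_vstar()))
})
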
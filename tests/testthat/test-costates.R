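# Costates: boundary conditions, closed-form agreement, the
# remaining-reproduction identity, and the Hamiltonian structure.

state_at <- function() sym_state()

test_that("survivorship costates start at total lifetime reproduction (two at c = 1/2)", {
  st <- state_at()
  expect_equal(unname(st$costates$lambda_l[1, ]), c(2, 2), tolerance = 1e-6)
})

test_that("state costates satisfy their terminal condition", {
  st <- state_at()
  expect_lt(max(abs(st$costates$lambda_x[length(st$traj$age), , ])), 1e-8)
})

test_that("female costates match their closed forms", {
  st <- state_at()
  v <- st$v
  cf <- sn_closed_costates_f(sym_params(), as.numeric(v), st$traj$age)
  lamxf <- st$costates$lambda_x[, 1, 1]
  expect_lt(max(abs(lamxf - cf$lambda_x_f)) / max(cf$lambda_x_f), 1e-6)
  expect_lt(max(abs(st$costates$lambda_l_surv[, 1] - cf$remaining_f)) /
              max(cf$remaining_f), 1e-6)
})

test_that("remaining reproduction: tail identity and endpoints", {
  st <- state_at()
  m <- sym_model()
  v <- as.numeric(st$v)
  a <- c(0, 2.5, 7, 20)
  rr <- remaining_reproduction(m, v, st$traj, i = 1, j = 1, a = a) +
    remaining_reproduction(m, v, st$traj, i = 2, j = 1, a = a)
  cf <- sn_closed_costates_f(sym_params(), v, a)
  expect_equal(rr, cf$remaining_f, tolerance = 1e-6)
  # at birth: equals lifetime fecundity; at a_max: empty tail
  Rij <- st$costates$Rij
  expect_equal(rr[1], sum(Rij[, 1]), tolerance = 1e-9)
  expect_lt(remaining_reproduction(m, v, st$traj, i = 1, j = 1,
                                   a = st$traj$a_max), 1e-8)
  # Box-1 identity: lambda_l * survivorship equals the tail integral
  lf <- st$traj$surv[, 1]
  idx <- c(1, 500, 1200)
  ages <- st$traj$age[idx]
  rr2 <- remaining_reproduction(m, v, st$traj, i = 1, j = 1, a = ages) +
    remaining_reproduction(m, v, st$traj, i = 2, j = 1, a = ages)
  expect_equal(st$costates$lambda_l[idx, 1] * lf[idx], rr2, tolerance = 1e-7)
})

test_that("costates satisfy their differential equations (residual check)", {
  st <- state_at()
  p <- sym_params()
  traj <- st$traj
  a <- traj$age
  # forward ODE for lambda_l (kept as a residual test; lambda_l itself is
  # computed from the tail identity): dlam/da = mu lam - f
  for (j in 1:2) {
    lam <- st$costates$lambda_l[, j]
    f <- if (j == 1) {
      traj$states[[1]][, 1] * st$env$phi
    } else {
      st$env$fm_of(traj$states[[2]][, 1])
    }
    mu <- if (j == 1) st$env$mu_f else st$env$mu_m
    dlam <- stats::splinefun(a, lam)(a, deriv = 1)
    resid <- dlam - (mu * lam - f)
    # exclude the last few points where survivorship underflows
    keep <- traj$surv[, j] > 1e-7
    expect_lt(max(abs(resid[keep])) / max(abs(lam)), 1e-5)
  }
  # backward ODE for lambda_x: dlam/da = alpha lam - l dfdx
  for (j in 1:2) {
    lam <- st$costates$lambda_x[, 1, j]
    dfdx <- if (j == 1) rep(st$env$phi, length(a)) else st$env$dfm_of(traj$states[[2]][, 1])
    dlam <- stats::splinefun(a, lam)(a, deriv = 1)
    resid <- dlam - (p$alpha * lam - traj$surv[, j] * dfdx)
    expect_lt(max(abs(resid)) / max(abs(lam)), 1e-5)
  }
})

test_that("reproductive values decompose over offspring classes (birth identity)", {
  m <- sym_model()
  v <- c(0.52, 0.43)
  st <- ontosel:::analysis_state(m, v, mode = "class_oriented")
  lam0 <- st$costates$lambda_l[1, , ]  # [i, j]
  rhs <- as.numeric(t(st$bs$nu) %*% (m$genetics$gamma * lam0))
  expect_equal(rhs, unname(st$bs$nu), tolerance = 1e-6)
})

test_that("class-specific and class-oriented pipelines agree under constant class proportions", {
  m <- sym_model()
  v <- c(0.52, 0.43)
  sg1 <- selection_gradient(m, v)
  st2 <- ontosel:::analysis_state(m, v, mode = "class_oriented")
  sg2 <- selection_gradient(m, v, state = st2)
  expect_equal(sg1$total, sg2$total, tolerance = 1e-9)
})

test_that("the Hamiltonian reduces to its developmental term without fecundity and mortality", {
  m0 <- haploid_model(fec = 0, mort = 0)
  m0$mortality <- function(j, z, x, env) rep(0, nrow(x))
  traj <- ontosel:::solve_trajectories(
    m0, z = matrix(0.5, 1, 1), v = matrix(0.5, 1, 1),
    env = list(v = matrix(0.5, 1, 1)), a_max = 5, n_grid = 101L)
  cst <- solve_costates(m0, 0.5, traj, mode = "class_specific")
  H <- evaluate_hamiltonian(m0, traj, cst, j = 1)
  lamx <- cst$lambda_x[, 1, 1]
  g <- 0.5 - traj$states[[1]][, 1]
  expect_equal(H, lamx * g, tolerance = 1e-12)
})

test_that("costates export as tidy per-channel data frames", {
  st <- state_at()
  df <- as.data.frame(st$costates)
  expect_named(df, c("class_parent", "class_offspring", "age", "lambda_l",
                     "lambda_x_1"))
  expect_setequal(unique(df$class_parent), c("f", "m"))
  expect_equal(df$lambda_l[df$class_parent == "f"][1], 2, tolerance = 1e-6)
})

test_that("the sex-specific Hamiltonian matches its explicit three-term form", {
  st <- state_at()
  m <- sym_model()
  p <- sym_params()
  traj <- st$traj
  v <- as.numeric(st$v)
  H <- evaluate_hamiltonian(m, traj, st$costates, j = 1, env = st$env)
  lf <- traj$surv[, 1]; xf <- traj$states[[1]][, 1]
  explicit <- lf * xf * st$env$phi -
    st$costates$lambda_l[, 1] * (p$mu_e_f + p$beta_f * v[1]^2) * lf +
    st$costates$lambda_x[, 1, 1] * (v[1] - p$alpha * xf)
  expect_equal(H, explicit, tolerance = 1e-10)
})
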
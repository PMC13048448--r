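# Quadratic selection: perturbation closed forms, the finite-difference
# oracle on R0, component structure and classification.

test_that("perturbations match the example model's closed forms", {
  st <- sym_state()
  m <- sym_model()
  p <- sym_params()
  pert <- compute_perturbations(m, st$v, st)
  a <- st$traj$age
  # propagator: exponential decay at the size-loss rate
  expect_equal(pert$psi(1, 5, 2)[1, 1], exp(-p$alpha * 3), tolerance = 1e-10)
  expect_equal(pert$psi(2, 4, 4)[1, 1], 1)  # Psi(tau, tau) = I
  # state sensitivity dx/dz = (1 - e^{-alpha a})/alpha, both routes
  dxdz <- (1 - exp(-p$alpha * a)) / p$alpha
  expect_lt(max(abs(pert$classes[[1]]$dx_dz[, 1, 1] - dxdz)) / max(dxdz), 1e-6)
  # survivorship sensitivity dl/dz = -l 2 beta v a (z-only mortality)
  for (j in 1:2) {
    beta <- if (j == 1) p$beta_f else p$beta_m
    cf <- -st$traj$surv[, j] * 2 * beta * st$v[j, 1] * a
    expect_lt(max(abs(pert$classes[[j]]$dl_dz[, 1] - cf)) / max(abs(cf)), 1e-6)
    expect_equal(pert$classes[[j]]$dl_dz[1, 1], 0)  # vanishes at birth
    expect_equal(pert$classes[[j]]$dx_dz[1, 1, 1], 0)
  }
  # constant class proportions: birth frequencies do not move
  expect_lt(max(abs(pert$dq_dz)), 1e-10)
  # rows of dq sum to zero (q stays on the simplex)
  expect_lt(max(abs(colSums(pert$dq_dz))), 1e-10)
})

test_that("assembled Hessians match Richardson-extrapolated second differences of R0", {
  for (case in c("sym", "asym")) {
    st <- if (case == "sym") sym_state() else asym_state()
    m <- if (case == "sym") sym_model() else asym_model()
    v <- as.numeric(st$v)
    R0fun <- function(u) {
      birth_structure(next_generation_matrix(m, v, u = u, traj = st$traj,
                                             env = st$env))$R0
    }
    d2 <- function(k, h) {
      up <- v; up[k] <- v[k] + h
      um <- v; um[k] <- v[k] - h
      (R0fun(up) - 2 * R0fun(v) + R0fun(um)) / h^2
    }
    rich <- function(k, h) (4 * d2(k, h / 2) - d2(k, h)) / 3
    hr <- selection_hessian(m, v, state = st)
    for (k in 1:2) {
      oracle <- rich(k, 0.04)
      expect_lt(abs(hr$H[k, k] - oracle) / abs(oracle), 1e-3)
    }
    # cross coefficient via the four-point stencil
    h <- 0.03
    cross <- (R0fun(v + c(h, h)) - R0fun(v + c(h, -h)) -
                R0fun(v + c(-h, h)) + R0fun(v + c(-h, -h))) / (4 * h^2)
    expect_lt(abs(hr$H[1, 2] - cross), 1e-6)
    # the between-sex coefficient vanishes in this model
    expect_lt(abs(hr$H[1, 2]), 1e-8)
  }
})

test_that("the generic state-mediated male component equals its closed form", {
  st <- asym_state()
  hr <- selection_hessian(asym_model(), as.numeric(st$v), state = st)
  cf <- sn_male_xx_kernel(asym_params(), as.numeric(st$v), hr$age)
  gen <- hr$kernels[, 2, 2, "xx"]
  expect_lt(max(abs(gen - cf$kernel)) / max(abs(cf$kernel)), 1e-4)
  # disruptiveness requires a positive fecundity-weighted competition
  # curvature wherever the kernel is positive
  pos <- gen > 1e-6 * max(gen)
  expect_true(all(cf$bracket[pos] > 0))
})

test_that("without size matching the male state-mediated component vanishes", {
  p0 <- sexual_niche_params(kappa = 0)
  m0 <- sexual_niche_model(p0)
  vst <- c(sym_vstar()[1], 0)
  hr <- selection_hessian(m0, vst, gradient_tol = 1e-4)
  expect_lt(max(abs(hr$kernels[, 2, 2, "xx"])), 1e-10)
  cf <- sn_male_xx_kernel(p0, vst, hr$age)
  expect_true(all(cf$kernel == 0))
})

test_that("classification: stabilising at the symmetric point, disruptive (male-driven) at the asymmetric one", {
  hs <- selection_hessian(sym_model(), sym_vstar(), state = sym_state())
  expect_equal(hs$net, "net_stabilising")
  expect_true(all(diag(hs$H) < 0))
  ha <- selection_hessian(asym_model(), asym_vstar(), state = asym_state())
  expect_equal(ha$net, "net_disruptive")
  expect_gt(ha$H[2, 2], 0)            # the male diagonal drives it
  expect_lt(ha$H[1, 1], 0)
  expect_equal(ha$labels[["m.growth"]], "disruptive")
  # branching direction points along the male trait
  expect_gt(abs(ha$branching_direction[2]), 0.99)
})

test_that("the genetic constraint collapses the Hessian by summation and suppresses disruption", {
  vl <- asym_vl()
  hr <- selection_hessian(asym_model(), c(vl, vl), constraints = list(c(1L, 2L)))
  expect_equal(hr$H_constrained[1, 1],
               hr$H[1, 1] + hr$H[2, 2] + 2 * hr$H[1, 2], tolerance = 1e-12)
  expect_equal(hr$constrained_net, "net_stabilising")
  # mixed sex kernel is zero (up to finite-difference noise in the
  # birth-frequency solve), so the constrained age kernel is the sum of the
  # sex-specific diagonal kernels
  ker_sum <- rowSums(hr$kernels[, 1, 1, ]) + rowSums(hr$kernels[, 2, 2, ])
  ker_fm <- rowSums(hr$kernels[, 1, 2, ])
  expect_lt(max(abs(ker_fm)), 1e-6)
  expect_true(is.numeric(ker_sum))
})

test_that("rejects residents that are not singular", {
  expect_error(selection_hessian(sym_model(), c(0.8, 0.8)), "singular")
})

test_that("classification of bare matrices follows the eigen structure", {
  cl <- classify_second_order(diag(c(-1, -1)))
  expect_equal(cl$net, "net_stabilising")
  cl2 <- classify_second_order(matrix(c(-1, 0, 0, 0.5), 2, 2))
  expect_equal(cl2$net, "net_disruptive")
  expect_equal(cl2$per_trait, c("stabilising", "disruptive"))
  expect_equal(abs(cl2$branching_direction), c(0, 1))
})
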
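# Resident dynamics vs the example model's closed forms, and the
# eigen-structure of the next-generation matrix.

test_that("resident ODE solutions match the closed forms of the example model", {
  m <- sym_model()
  v <- c(0.5, 0.45)
  traj <- solve_resident(m, v)
  cf <- sn_closed_resident(sym_params(), v, traj$age)
  expect_lt(max(abs(traj$surv - cf$surv)), 1e-6)
  rel <- max(abs(traj$states[[1]][, 1] - cf$size[, "f"])) / max(cf$size[, "f"])
  expect_lt(rel, 1e-6)
  # initial conditions
  expect_equal(unname(traj$surv[1, ]), c(1, 1))
  expect_equal(traj$states[[1]][1, 1], 0)
  # frozen closed-form point: v = 0.5, alpha = 0.1 gives
  # x(10) = 5 (1 - e^{-1}) = 3.160603
  m2 <- sexual_niche_model(sexual_niche_params(alpha = 0.1))
  tr2 <- solve_resident(m2, c(0.5, 0.5))
  x10 <- stats::spline(tr2$age, tr2$states[[1]][, 1], xout = 10)$y
  expect_equal(x10, 3.160603, tolerance = 1e-5)
})

test_that("truncation makes survivorship at a_max fall below tol", {
  traj <- solve_resident(sym_model(), c(0.5, 0.45), tol = 1e-9)
  expect_lt(max(traj$surv[nrow(traj$surv), ]), 1.01e-9)
})

test_that("resident columns of lifetime fecundity sum to two offspring at c = 1/2", {
  R <- next_generation_matrix(sym_model(), c(0.5, 0.45))
  Rij <- attr(R, "lifetime_fecundity")
  expect_equal(unname(colSums(Rij)), c(2, 2), tolerance = 1e-6)
})

test_that("the resident basic reproductive number is one (density dependence self-equilibrates)", {
  for (v in list(c(0.5, 0.45), c(0.8, 0.2), c(0.3, 0.6))) {
    bs <- birth_structure(next_generation_matrix(sym_model(), v))
    expect_equal(bs$R0, 1, tolerance = 1e-6)
  }
})

test_that("birth eigenvectors are consistent and match the two-sex closed forms", {
  # diploid at c = 0.3: newborn allele frequencies follow the primary sex ratio
  p <- sexual_niche_params(c = 0.3)
  m <- sexual_niche_model(p, genetics = genetic_system("diploid_two_sex", 0.3))
  R <- next_generation_matrix(m, c(0.5, 0.45))
  bs <- birth_structure(R)
  expect_equal(unname(bs$q), c(0.7, 0.3), tolerance = 1e-8)
  expect_lt(max(abs(R %*% bs$q - bs$R0 * bs$q)), 1e-8 * max(abs(R)))
  expect_lt(max(abs(t(bs$nu) %*% R - bs$R0 * t(bs$nu))), 1e-8 * max(abs(R)))
  expect_equal(sum(bs$nu * bs$q), 1)

  # haplodiploid: q = (2(1-c)/(2-c), c/(2-c))
  mh <- sexual_niche_model(p, genetics = genetic_system("haplodiploid_two_sex", 0.3))
  bsh <- birth_structure(next_generation_matrix(mh, c(0.5, 0.45)))
  expect_equal(unname(bsh$q), c(2 * 0.7, 0.3) / 1.7, tolerance = 1e-8)
  expect_equal(bsh$R0, 1, tolerance = 1e-6)
})

test_that("degenerate next-generation matrices are handled", {
  m0 <- haploid_model()
  m0$fecundity <- function(i, j, z, x, env) rep(0, nrow(x))
  R <- next_generation_matrix(m0, 0.5)
  expect_equal(as.numeric(R), 0)
  # demographically consistent haploid single class: R = [1]
  R1 <- next_generation_matrix(haploid_model(), 0.5)
  expect_equal(as.numeric(R1), 1, tolerance = 1e-6)
  expect_error(birth_structure(matrix(c(1, -2, 0, 1), 2, 2)), "non-negative")
})

test_that("trajectories export as tidy per-class data frames", {
  df <- as.data.frame(solve_resident(sym_model(), c(0.5, 0.45), n_grid = 201L))
  expect_named(df, c("class", "age", "survivorship", "state_1"))
  expect_setequal(unique(df$class), c("f", "m"))
  expect_true(all(diff(df$survivorship[df$class == "f"]) <= 0))
})
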
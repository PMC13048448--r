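# The worked example: two-sex growth/survival trade-off with size-matching
# sexual selection.
#
# Females and males carry one evolving trait each, the basal growth rate of a
# sexually relevant size module x(a). Growth is g = z - alpha * x (size is
# lost at rate alpha), mortality is mu = mu_e + beta * z^2 (survival cost of
# growth), female fecundity is ff = x * (1 - NT/K) (linear in size,
# density-dependent), and male fecundity is the outcome of competition for
# eggs, weighted by a Gaussian size-matching kernel C~ = exp(-kappa (xm-xf)^2)
# against the standing distribution of female sizes.
#
# Resident demography is available in closed form: l(a) = exp(-mu a),
# x(a) = v (1 - exp(-alpha a)) / alpha, and the equilibrium density NT and
# secondary sex ratio follow from demographic consistency (each female leaves
# one daughter). Size-distribution integrals are evaluated on the age axis
# (stationary ages are exponential and sizes monotone in age), which avoids
# the integrable endpoint singularity of the size density chi when
# alpha > mu.

#' Parameters of the sexual-niche model
#'
#' @param c primary sex ratio (proportion of males at birth), in (0, 1).
#' @param alpha rate at which size is lost (per time).
#' @param mu_e_f,mu_e_m extrinsic mortality rates (per time).
#' @param beta_f,beta_m survival cost of growth (per squared trait unit and
#'   time).
#' @param kappa strength of size-matching sexual selection (per squared size
#'   unit); `kappa = 0` makes all males equally competitive.
#' @param K density-dependence scale of female fecundity (individuals).
#' @return a named list of class `sexual_niche_params`.
#' @export
sexual_niche_params <- function(c = 0.5, alpha = 0.2,
                                mu_e_f = 0.1, mu_e_m = 0.1,
                                beta_f = 0.2, beta_m = 0.2,
                                kappa = 1, K = 1e4) {
  stopifnot(c > 0, c < 1, alpha > 0, K > 0,
            mu_e_f >= 0, mu_e_m >= 0, beta_f >= 0, beta_m >= 0, kappa >= 0)
  structure(list(c = c, alpha = alpha, mu_e_f = mu_e_f, mu_e_m = mu_e_m,
                 beta_f = beta_f, beta_m = beta_m, kappa = kappa, K = K),
            class = "sexual_niche_params")
}

#' Read / write sexual-niche parameters as a flat YAML file
#'
#' Keys match the model's symbols: `c, alpha, mu_e_f, mu_e_m, beta_f, beta_m,
#' kappa, K`.
#'
#' @param path file path.
#' @return [read_sn_params()] returns a [sexual_niche_params()] object.
#' @export
read_sn_params <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(sexual_niche_params, y[intersect(names(y),
    c("c", "alpha", "mu_e_f", "mu_e_m", "beta_f", "beta_m", "kappa", "K"))])
}

#' @rdname read_sn_params
#' @param params a [sexual_niche_params()] object.
#' @export
write_sn_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Resident demography of the sexual-niche model
#'
#' Closed-form equilibrium quantities at resident trait values `v = (vf, vm)`:
#' sex-specific mortality `mu_j = mu_e_j + beta_j vj^2`, total density `NT`,
#' the density-dependence factor `phi = 1 - NT/K`, the secondary sex ratio
#' (proportion of males among living residents), maximum sizes `vj/alpha`,
#' the equilibrium size densities `chi_j`, and average sizes
#' `vj/(mu_j + alpha)` (the mean of `chi_j`). When `NT <= 0` the resident
#' population is not viable; the `extinct` flag is set but all quantities are
#' still returned (the model remains formally evaluable).
#'
#' @param params a [sexual_niche_params()].
#' @param v resident traits `c(vf, vm)`; `vf` must be positive.
#' @return list of class `sn_demography` with elements `mu_f`, `mu_m`, `NT`,
#'   `phi`, `secondary_sex_ratio`, `x_max` (length 2), `mean_size` (length
#'   2), `chi` (list of two density functions), `extinct`.
#' @export
resident_demography <- function(params, v) {
  p <- params
  vf <- v[1L]; vm <- v[2L]
  if (vf <= 0) stop("female basal growth rate must be positive (resident females must grow)")
  mu_f <- p$mu_e_f + p$beta_f * vf^2
  mu_m <- p$mu_e_m + p$beta_m * vm^2
  # lifetime discounted size integral: int l x da = v / (mu (mu + alpha))
  phi <- mu_f * (mu_f + p$alpha) / ((1 - p$c) * vf)
  NT <- p$K * (1 - phi)
  ctil <- p$c * mu_f / ((1 - p$c) * mu_m + p$c * mu_f)
  x_max <- c(f = vf / p$alpha, m = vm / p$alpha)
  chi_fun <- function(vj, muj) {
    force(vj); force(muj)
    function(x) {
      out <- rep(0, length(x))
      ok <- x >= 0 & x < vj / p$alpha
      out[ok] <- (muj / vj) * (vj / (vj - p$alpha * x[ok]))^((p$alpha - muj) / p$alpha)
      out
    }
  }
  structure(list(mu_f = mu_f, mu_m = mu_m, NT = NT, phi = phi,
                 secondary_sex_ratio = ctil, x_max = x_max,
                 mean_size = c(f = vf / (mu_f + p$alpha),
                               m = vm / (mu_m + p$alpha)),
                 chi = list(f = chi_fun(vf, mu_f),
                            m = if (vm > 0) chi_fun(vm, mu_m) else NULL),
                 point_mass_males = vm <= 0,
                 extinct = NT <= 0),
            class = "sn_demography")
}

# Resident environment: demography plus the partner-size quadrature used by
# the male fecundity integrals. All integrals over the standing size
# distributions run over stationary ages (Gauss-Legendre nodes).
sn_env <- function(params, v, n_nodes = 240L, tol = 1e-9) {
  p <- params
  dem <- resident_demography(params, v)
  al <- p$alpha
  glf <- pracma::gaussLegendre(n_nodes, 0, -log(tol) / dem$mu_f)
  glm <- pracma::gaussLegendre(n_nodes, 0, -log(tol) / max(dem$mu_m, 1e-12))
  xfp <- v[1L] * (1 - exp(-al * glf$x)) / al
  xmp <- v[2L] * (1 - exp(-al * glm$x)) / al
  wfp <- glf$w * dem$mu_f * exp(-dem$mu_f * glf$x)   # integrates chi_f(x) dx
  wmp <- glm$w * dem$mu_m * exp(-dem$mu_m * glm$x)
  ffp <- xfp * dem$phi
  ctil <- dem$secondary_sex_ratio
  NT <- dem$NT
  # normalisation over resident males, at the female partner sizes
  D <- as.vector((ctil * NT * wmp) %*% exp(-p$kappa * outer(xmp, xfp, "-")^2))
  wF <- (1 - ctil) * NT * wfp * ffp / D
  fm_of <- function(xm) {
    dd <- outer(xm, xfp, "-")
    as.vector(exp(-p$kappa * dd^2) %*% wF)
  }
  dfm_of <- function(xm) {
    dd <- outer(xm, xfp, "-")
    as.vector((exp(-p$kappa * dd^2) * (-2 * p$kappa * dd)) %*% wF)
  }
  d2fm_of <- function(xm) {
    dd <- outer(xm, xfp, "-")
    as.vector((exp(-p$kappa * dd^2) *
                 (2 * p$kappa * (2 * p$kappa * dd^2 - 1))) %*% wF)
  }
  c(dem, list(params = p, v = matrix(v, 2L, 1L),
              fm_of = fm_of, dfm_of = dfm_of, d2fm_of = d2fm_of))
}

#' Male siring rate at a given size
#'
#' The rate at which a (rare mutant) male of size `xm` sires offspring:
#' the egg production of each female size class, times the male's
#' competitive share `C = C~(xm, xf) / (resident-male normalisation)`, summed
#' over the standing female size distribution. The construction couples male
#' and female totals (every egg has one sire).
#'
#' @param params a [sexual_niche_params()].
#' @param v resident traits `c(vf, vm)`.
#' @param xm male sizes (vector).
#' @param n_nodes quadrature nodes for the partner-size integrals.
#' @return siring rates, one per element of `xm`.
#' @export
male_fecundity <- function(params, v, xm, n_nodes = 240L) {
  sn_env(params, v, n_nodes = n_nodes)$fm_of(xm)
}

#' Build the sexual-niche life-history model
#'
#' Assembles the two-sex example as a [life_history_model()] consumable by
#' the generic machinery: one trait per sex (the basal growth rate), one
#' internal state (size), constant class proportions at birth (primary sex
#' ratio `c`), and an environment hook computing the closed-form resident
#' demography plus the male-competition quadrature.
#'
#' Under haplodiploid genetics the vital rates are unchanged (trait values,
#' not ploidy, set the phenotype) and only the transmission weights and
#' genetic exposures differ.
#'
#' @param params a [sexual_niche_params()].
#' @param genetics a [genetic_system()]; defaults to diploid two-sex with the
#'   model's primary sex ratio.
#' @param n_nodes partner-quadrature nodes used by the environment hook.
#' @return a [life_history_model()] with classes `f`, `m`.
#' @export
sexual_niche_model <- function(params, genetics = NULL, n_nodes = 240L) {
  p <- params
  if (is.null(genetics)) genetics <- genetic_system("diploid_two_sex", p$c)
  if (length(genetics$class_names) != 2L) {
    stop("the sexual-niche model needs a two-class (two-sex) genetic system")
  }
  cprop <- matrix(c(1 - p$c, p$c, 1 - p$c, p$c), 2L, 2L,
                  dimnames = list(c("f", "m"), c("f", "m")))
  model <- life_history_model(
    n_classes = 2L, n_traits = 1L, n_states = 1L,
    fecundity = function(i, j, z, x, env) {
      fj <- if (j == 1L) x[, 1L] * env$phi else env$fm_of(x[, 1L])
      cprop[i, j] * fj
    },
    mortality = function(j, z, x, env) {
      mu_e <- if (j == 1L) p$mu_e_f else p$mu_e_m
      beta <- if (j == 1L) p$beta_f else p$beta_m
      rep(mu_e + beta * z[1L]^2, nrow(x))
    },
    growth = function(j, z, x, env) {
      z[1L] - p$alpha * x[, 1L]
    },
    initial_states = list(f = 0, m = 0),
    genetics = genetics,
    class_proportions = cprop,
    prepare = function(v, model) sn_env(p, as.numeric(v), n_nodes = n_nodes),
    class_names = c("f", "m"),
    trait_names = "growth",
    trait_bounds = c(0, Inf)
  )
  model$params <- p
  model
}

# ---- closed-form shortcuts (independent oracles for the generic machinery) -

#' Closed-form resident trajectories of the sexual-niche model
#'
#' `l_j(a) = exp(-mu_j a)` and `x_j(a) = vj (1 - exp(-alpha a)) / alpha`.
#'
#' @param params a [sexual_niche_params()].
#' @param v resident traits `c(vf, vm)`.
#' @param a ages.
#' @return list with matrices `surv` and `size` (ages x sexes).
#' @export
sn_closed_resident <- function(params, v, a) {
  dem <- resident_demography(params, v)
  mu <- c(dem$mu_f, dem$mu_m)
  surv <- cbind(f = exp(-mu[1L] * a), m = exp(-mu[2L] * a))
  size <- cbind(f = v[1L] * (1 - exp(-params$alpha * a)) / params$alpha,
                m = v[2L] * (1 - exp(-params$alpha * a)) / params$alpha)
  list(surv = surv, size = size)
}

#' Closed-form female costates of the sexual-niche model
#'
#' The female state costate solves its linear ODE analytically:
#' `lambda_x,f(a) = phi exp(-mu_f a) / (mu_f + alpha)`; the female remaining
#' reproduction (survivorship costate times survivorship) is
#' `phi vf / alpha * (exp(-mu_f a)/mu_f - exp(-(mu_f+alpha) a)/(mu_f+alpha))`.
#'
#' @inheritParams sn_closed_resident
#' @return list with `lambda_x_f` and `remaining_f` vectors over `a`.
#' @export
sn_closed_costates_f <- function(params, v, a) {
  dem <- resident_demography(params, v)
  mu <- dem$mu_f; al <- params$alpha; phi <- dem$phi
  list(lambda_x_f = phi * exp(-mu * a) / (mu + al),
       remaining_f = phi * v[1L] / al *
         (exp(-mu * a) / mu - exp(-(mu + al) * a) / (mu + al)))
}

# Lightweight analytic pipeline: closed-form resident demography and
# trajectories, partner-grid male fecundity, costates by reversed cumulative
# quadrature. Independent of the generic ODE/finite-difference machinery;
# used as the oracle route and by the fixed-point shortcut.
sn_analytic_pipeline <- function(params, v, n_age = 4001L, tol = 1e-9,
                                 n_nodes = 240L) {
  p <- params
  env <- sn_env(p, v, n_nodes = n_nodes, tol = tol)
  mu <- c(env$mu_f, env$mu_m)
  a_max <- max(-log(tol) / mu)
  if (n_age %% 2L == 0L) n_age <- n_age + 1L
  a <- seq(0, a_max, length.out = n_age)
  h <- a[2L] - a[1L]
  w <- simpson_weights(n_age, h)
  lf <- exp(-mu[1L] * a); lm_ <- exp(-mu[2L] * a)
  xfa <- v[1L] * (1 - exp(-p$alpha * a)) / p$alpha
  xma <- v[2L] * (1 - exp(-p$alpha * a)) / p$alpha
  ffa <- xfa * env$phi
  fma <- env$fm_of(xma)
  lamLf_lf <- tailquad(lf * ffa, h)
  lamLm_lm <- tailquad(lm_ * fma, h)
  lamx <- function(r) tailquad(exp(-p$alpha * a) * r, h) * exp(p$alpha * a)
  lamXf <- lamx(lf * env$phi)
  lamXm <- lamx(lm_ * env$dfm_of(xma))
  list(env = env, age = a, h = h, weights = w,
       surv = cbind(f = lf, m = lm_), size = cbind(f = xfa, m = xma),
       fec = cbind(f = ffa, m = fma),
       lambda_l_surv = cbind(f = lamLf_lf, m = lamLm_lm),
       lambda_x = cbind(f = lamXf, m = lamXm))
}

#' Model-specific selection shortcuts for the sexual-niche model
#'
#' The age-specific directional kernels in closed form,
#' `s^_f = (1-c)/2 (lambda_x,f - lambda_l,f l_f 2 beta_f vf)` (and the male
#' analogue), built from the analytic pipeline rather than the generic
#' Hamiltonian differentiation.
#'
#' @inheritParams sn_closed_resident
#' @param n_age,n_nodes discretisation of the analytic pipeline.
#' @return list with `age`, `kernels` (ages x 2), `total` (length 2,
#'   including the diploid exposure 1/2), and the pipeline in `pipeline`.
#' @export
sn_gradient_kernels <- function(params, v, n_age = 4001L, n_nodes = 240L) {
  p <- params
  pl <- sn_analytic_pipeline(params, v, n_age = n_age, n_nodes = n_nodes)
  kf <- (1 - p$c) / 2 * (pl$lambda_x[, "f"] - pl$lambda_l_surv[, "f"] * 2 * p$beta_f * v[1L])
  km <- p$c / 2 * (pl$lambda_x[, "m"] - pl$lambda_l_surv[, "m"] * 2 * p$beta_m * v[2L])
  kern <- cbind(f = kf, m = km)
  list(age = pl$age, kernels = kern,
       total = 0.5 * as.numeric(t(kern) %*% pl$weights),
       pipeline = pl)
}

#' Fixed-point characterisation of the singular growth rates
#'
#' The singular strategy satisfies, per sex,
#' `vj* = (1/(2 beta_j)) int lambda_x,j da / int lambda_l,j l_j da`
#' (and the sex-averaged analogue under a shared trait). The map is implicit
#' (costates depend on `v`) and is not a contraction in the male component,
#' so the root of `map(v) - v` is found by a damped Newton iteration. This
#' path is independent of the generic Hamiltonian machinery and serves as its
#' oracle.
#'
#' @param params a [sexual_niche_params()].
#' @param v0 starting traits `c(vf, vm)` (scalar for `shared = TRUE`).
#' @param shared logical: force a single shared growth rate in both sexes.
#' @param tol convergence tolerance on the root residual.
#' @param maxit iteration cap.
#' @param n_age,n_nodes discretisation of the analytic pipeline.
#' @return list with `v` (length 2, equal entries when shared), `residual`,
#'   `converged`.
#' @export
sn_fixed_point <- function(params, v0, shared = FALSE, tol = 1e-9,
                           maxit = 60L, n_age = 4001L, n_nodes = 240L) {
  p <- params
  map <- function(v) {
    pl <- sn_analytic_pipeline(params, v, n_age = n_age, n_nodes = n_nodes)
    iXf <- sum(pl$weights * pl$lambda_x[, "f"])
    iXm <- sum(pl$weights * pl$lambda_x[, "m"])
    iLf <- sum(pl$weights * pl$lambda_l_surv[, "f"])
    iLm <- sum(pl$weights * pl$lambda_l_surv[, "m"])
    if (shared) {
      num <- (1 - p$c) * iXf + p$c * iXm
      den <- (1 - p$c) * p$beta_f * iLf + p$c * p$beta_m * iLm
      rep(0.5 * num / den, 2L)
    } else {
      c(0.5 / p$beta_f * iXf / iLf, 0.5 / p$beta_m * iXm / iLm)
    }
  }
  v <- if (shared) rep(v0[1L], 2L) else v0
  resid <- function(v) map(v) - v
  r <- resid(v)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    if (max(abs(r)) < tol) { converged <- TRUE; break }
    idx <- if (shared) 1L else 1:2
    J <- matrix(0, length(idx), length(idx))
    hstep <- 1e-5
    for (kk in seq_along(idx)) {
      vp <- v; vm_ <- v
      if (shared) {
        vp <- vp + hstep; vm_ <- vm_ - hstep
      } else {
        vp[idx[kk]] <- vp[idx[kk]] + hstep
        vm_[idx[kk]] <- vm_[idx[kk]] - hstep
      }
      J[, kk] <- (resid(vp)[idx] - resid(vm_)[idx]) / (2 * hstep)
    }
    step <- tryCatch(solve(J, -r[idx]), error = function(e) -r[idx])
    step <- pmin(pmax(step, -0.2), 0.2)
    if (shared) v <- pmax(v + step, 1e-6) else v[idx] <- pmax(v[idx] + step, 0)
    r <- resid(v)
  }
  list(v = v, residual = r, converged = converged)
}

#' Closed-form male size-mediated quadratic kernel
#'
#' The dominant pathway for disruptive selection on male growth: the
#' state-mediated (xx) component of the male quadratic kernel,
#' `(c/2) l_m(a) (d2 f_m/d x^2)(x_m(a)) ((1 - e^{-alpha a})/alpha)^2`,
#' with `d2 fm/dx2` the fecundity-weighted average of
#' `2 kappa (2 kappa (xm - xf)^2 - 1) C(xm, xf)` over the standing female
#' sizes. Obtained by direct differentiation of the male Hamiltonian; serves
#' as the closed-form check of the generic state-mediated component. It is
#' positive - and disruptive selection possible - only where the
#' fecundity-weighted average of `2 kappa (xm - xf)^2 - 1` is positive, i.e.
#' where male and female size distributions diverge.
#'
#' @inheritParams sn_closed_resident
#' @param n_nodes partner-quadrature nodes.
#' @return list with `age`, `kernel` (values over `a`), and the bracket
#'   average `bracket` (fecundity-weighted competition curvature).
#' @export
sn_male_xx_kernel <- function(params, v, a, n_nodes = 240L) {
  p <- params
  env <- sn_env(params, v, n_nodes = n_nodes)
  xma <- v[2L] * (1 - exp(-p$alpha * a)) / p$alpha
  lm_ <- exp(-env$mu_m * a)
  dxdz <- (1 - exp(-p$alpha * a)) / p$alpha
  d2 <- env$d2fm_of(xma)
  list(age = a,
       kernel = (p$c / 2) * lm_ * d2 * dxdz^2,
       bracket = d2 / (2 * p$kappa))
}
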
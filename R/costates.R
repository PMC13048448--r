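# Hamiltonians and costates: the shadow prices of survivorship and of the
# internal states, in units of expected remaining (class-oriented)
# reproduction.
#
# The survivorship costate lambda_l is computed from its integral identity
# lambda_l(a) = (1 / l(a)) * int_a^inf l f dtau  (remaining reproduction per
# unit survivorship), which is numerically stabler than its forward ODE (the
# ODE is kept as a residual check in the test suite). The state costates
# lambda_x are obtained by backward integration from their terminal condition
# lambda_x(a_max) = 0.

# finite-difference steps (relative) used for rate-function derivatives
.fd_rel_grad <- 1e-6
.fd_rel_hess <- 1e-3

# Derivatives of the rate functions along the resident path, by central
# differences over one state component.
rate_state_derivs <- function(model, j, zj, xj, env, fij_list, mu = TRUE) {
  nx <- ncol(xj)
  n <- nrow(xj)
  dmu <- matrix(0, n, nx)
  dfs <- lapply(fij_list, function(i) matrix(0, n, nx))
  dg <- array(0, dim = c(n, nx, nx))  # [age, d/dx_m, component]
  for (m in seq_len(nx)) {
    hm <- fd_step(xj[, m], .fd_rel_grad)
    xp <- xj; xp[, m] <- xj[, m] + hm
    xm_ <- xj; xm_[, m] <- xj[, m] - hm
    if (mu) {
      dmu[, m] <- (model$mortality(j, zj, xp, env) -
                   model$mortality(j, zj, xm_, env)) / (2 * hm)
    }
    for (k in seq_along(fij_list)) {
      i <- fij_list[[k]]
      dfs[[k]][, m] <- (fec_eval(model, i, j, zj, xp, env) -
                        fec_eval(model, i, j, zj, xm_, env)) / (2 * hm)
    }
    dg[, m, ] <- (as_state_matrix(model$growth(j, zj, xp, env), nx) -
                  as_state_matrix(model$growth(j, zj, xm_, env), nx)) / (2 * hm)
  }
  list(dmu = dmu, df = dfs, dg = dg)
}

# fecundity evaluation; i = 0 means total fecundity over offspring classes
fec_eval <- function(model, i, j, zj, xj, env) {
  if (i == 0L) {
    tot <- 0
    for (ii in seq_len(model$n_classes)) {
      tot <- tot + model$fecundity(ii, j, zj, xj, env)
    }
    tot
  } else {
    model$fecundity(i, j, zj, xj, env)
  }
}

as_state_matrix <- function(g, nx) {
  if (is.matrix(g)) g else matrix(g, ncol = nx)
}

#' Expected remaining class-oriented reproduction
#'
#' The tail integral `int_a^inf l_j(tau) f_ij(v_j, x_j(tau), v) dtau`: the
#' number of class-`i` offspring a class-`j` newborn is expected to produce
#' beyond age `a`. At `a = 0` it equals the lifetime fecundity `R_ij`, and at
#' any age it equals `lambda_l,ij(a) * l_j(a)` (survivorship costate weighted
#' by survivorship).
#'
#' @param model a [life_history_model()].
#' @param v resident allelic values.
#' @param traj resident trajectory (resolved if `NULL`).
#' @param i offspring class index.
#' @param j parental class index.
#' @param a ages at which to evaluate (vector).
#' @param env resident environment.
#' @return numeric vector, one value per requested age.
#' @export
remaining_reproduction <- function(model, v, traj = NULL, i, j, a, env = NULL) {
  v <- as_trait_matrix(v, model$n_classes)
  if (is.null(env)) env <- prepare_env(model, v)
  if (is.null(traj)) traj <- solve_resident(model, v, env = env)
  stopifnot(all(a >= 0), all(a <= traj$a_max + 1e-9))
  y <- traj$surv[, j] * fec_eval(model, i, j, traj$z[j, ], traj$states[[j]], env)
  tail <- tailquad(y, traj$h)
  stats::spline(traj$age, tail, xout = a, method = "natural")$y
}

#' Solve the costate equations
#'
#' Computes, along the resident path, the survivorship costates
#' `lambda_l(a)` (from the remaining-reproduction identity) and the state
#' costates `lambda_x(a)` (by backward integration of their linear ODE from
#' the terminal condition `lambda_x(a_max) = 0`).
#'
#' In `class_oriented` mode one costate set is produced per (offspring class
#' i, parental class j) pair. When class proportions at birth are constant
#' (`model$class_proportions` present), `class_specific` mode solves one set
#' per parental class using total fecundities, with
#' `lambda_l,j(0) = sum_i R_ij`.
#'
#' @param model a [life_history_model()].
#' @param v resident allelic values.
#' @param traj resident trajectory (resolved if `NULL`).
#' @param mode `"auto"` (class-specific when constant class proportions are
#'   declared), `"class_specific"`, or `"class_oriented"`.
#' @param env resident environment.
#' @return object of class `costate_set`: list with `mode`, `age`,
#'   `lambda_l`, `lambda_l_surv` (= lambda_l * survivorship, the remaining
#'   reproduction, numerically stable at old ages), `lambda_x`, and the
#'   lifetime fecundity matrix `Rij`. In class-specific mode `lambda_l` is
#'   ages x classes and `lambda_x` ages x states x classes; in class-oriented
#'   mode the layouts are `lambda_l[age, i, j]` and
#'   `lambda_x[age, state, i, j]` with `i` the offspring class.
#' @export
solve_costates <- function(model, v, traj = NULL,
                           mode = c("auto", "class_specific", "class_oriented"),
                           env = NULL) {
  mode <- match.arg(mode)
  v <- as_trait_matrix(v, model$n_classes)
  if (is.null(env)) env <- prepare_env(model, v)
  if (is.null(traj)) traj <- solve_resident(model, v, env = env)
  if (mode == "auto") {
    mode <- if (!is.null(model$class_proportions)) "class_specific" else "class_oriented"
  }
  if (mode == "class_specific" && is.null(model$class_proportions)) {
    stop("class_specific costates require constant class proportions ",
         "(model$class_proportions)")
  }
  nc <- model$n_classes
  nx <- model$n_states
  n <- length(traj$age)
  Rij <- matrix(NA_real_, nc, nc,
                dimnames = list(model$class_names, model$class_names))
  for (j in seq_len(nc)) {
    for (i in seq_len(nc)) {
      Rij[i, j] <- sum(traj$weights * traj$surv[, j] *
                         fec_eval(model, i, j, traj$z[j, ], traj$states[[j]], env))
    }
  }

  solve_channel <- function(i, j) {
    # i = 0: class-specific (total fecundity) channel for parent class j
    zj <- traj$z[j, ]
    lj <- traj$surv[, j]
    xj <- traj$states[[j]]
    f <- fec_eval(model, i, j, zj, xj, env)
    ll_surv <- tailquad(lj * f, traj$h)           # lambda_l * l
    lambda_l <- ifelse(lj > 0, ll_surv / pmax(lj, .Machine$double.xmin), 0)
    d <- rate_state_derivs(model, j, zj, xj, env, fij_list = list(i))
    # forcing P(a) = l f_x - (lambda_l l) mu_x ; coefficient A(a) = g_x
    P <- lj * d$df[[1L]] - ll_surv * d$dmu        # n x nx
    lamx <- backward_costate(traj, P, d$dg)
    list(lambda_l = lambda_l, lambda_l_surv = ll_surv, lambda_x = lamx)
  }

  if (mode == "class_specific") {
    lambda_l <- matrix(NA_real_, n, nc, dimnames = list(NULL, model$class_names))
    lambda_l_surv <- lambda_l
    lambda_x <- array(NA_real_, dim = c(n, nx, nc))
    for (j in seq_len(nc)) {
      ch <- solve_channel(0L, j)
      lambda_l[, j] <- ch$lambda_l
      lambda_l_surv[, j] <- ch$lambda_l_surv
      lambda_x[, , j] <- ch$lambda_x
    }
  } else {
    lambda_l <- array(NA_real_, dim = c(n, nc, nc))
    lambda_l_surv <- lambda_l
    lambda_x <- array(NA_real_, dim = c(n, nx, nc, nc))
    for (j in seq_len(nc)) {
      for (i in seq_len(nc)) {
        ch <- solve_channel(i, j)
        lambda_l[, i, j] <- ch$lambda_l
        lambda_l_surv[, i, j] <- ch$lambda_l_surv
        lambda_x[, , i, j] <- ch$lambda_x
      }
    }
  }
  structure(list(mode = mode, age = traj$age, lambda_l = lambda_l,
                 lambda_l_surv = lambda_l_surv, lambda_x = lambda_x,
                 Rij = Rij),
            class = "costate_set")
}

# Backward integration of dlambda_x/da = -(P(a) + A(a)^T lambda_x) from
# lambda_x(a_max) = 0, where P = l f_x - (lambda_l l) mu_x and A = g_x.
backward_costate <- function(traj, P, A) {
  nx <- ncol(P)
  age <- traj$age
  Pfun <- lapply(seq_len(nx), function(m) stats::splinefun(age, P[, m], method = "natural"))
  Afun <- vector("list", nx * nx)
  dim(Afun) <- c(nx, nx)
  for (m in seq_len(nx)) {
    for (k in seq_len(nx)) {
      Afun[[m, k]] <- stats::splinefun(age, A[, m, k], method = "natural")
    }
  }
  amax <- traj$a_max
  dfun <- function(s, y, parms) {
    a <- amax - s
    Pa <- vapply(Pfun, function(f) f(a), numeric(1L))
    Aa <- matrix(vapply(Afun, function(f) f(a), numeric(1L)), nx, nx)
    # d lambda/ds = + dH/dx at a = amax - s
    list(Pa + as.numeric(t(Aa) %*% y))
  }
  s_grid <- rev(amax - age)
  sol <- deSolve::lsoda(rep(0, nx), times = s_grid, func = dfun,
                        rtol = 1e-10, atol = 1e-12)
  lamx <- sol[, -1L, drop = FALSE]
  matrix(lamx[nrow(lamx):1L, ], ncol = nx)
}

#' Tidy export of a costate set
#'
#' @param x a `costate_set`.
#' @param ... unused.
#' @return data frame with columns `class_parent`, `class_offspring` (`NA`
#'   in class-specific mode), `age`, `lambda_l`, `lambda_x_1..nx`.
#' @export
as.data.frame.costate_set <- function(x, ...) {
  nx <- dim(x$lambda_x)[2L]
  xcols <- paste0("lambda_x_", seq_len(nx))
  out <- list()
  cls <- colnames(x$Rij)
  nc <- ncol(x$Rij)
  if (x$mode == "class_specific") {
    for (j in seq_len(nc)) {
      df <- data.frame(class_parent = cls[j], class_offspring = NA_character_,
                       age = x$age, lambda_l = x$lambda_l[, j])
      df[xcols] <- as.data.frame(matrix(x$lambda_x[, , j], ncol = nx))
      out[[length(out) + 1L]] <- df
    }
  } else {
    for (j in seq_len(nc)) {
      for (i in seq_len(nc)) {
        df <- data.frame(class_parent = cls[j], class_offspring = cls[i],
                         age = x$age, lambda_l = x$lambda_l[, i, j])
        df[xcols] <- as.data.frame(matrix(x$lambda_x[, , i, j], ncol = nx))
        out[[length(out) + 1L]] <- df
      }
    }
  }
  do.call(rbind, out)
}

#' Evaluate a Hamiltonian along the resident age grid
#'
#' The class-oriented Hamiltonian
#' `H_ij = l f_ij - lambda_l,ij mu l + lambda_x,ij . g` prices a class-j
#' individual's age-specific contribution to its lifetime production of
#' class-i offspring: current fecundity, plus future reproduction bought
#' through survival (weighted by `lambda_l`) and through development
#' (weighted by `lambda_x`). With `i = NULL` and class-specific costates the
#' class-specific Hamiltonian (total fecundity) is returned.
#'
#' Traits `z`, states `x` and survivorship `l` can be overridden to evaluate
#' off the resident path (used for the finite-difference derivatives of the
#' selection coefficients).
#'
#' @param model a [life_history_model()].
#' @param traj resident trajectory.
#' @param costates a [solve_costates()] result.
#' @param j parental class.
#' @param i offspring class, or `NULL` for the class-specific Hamiltonian.
#' @param z traits (length `n_traits`); default resident.
#' @param x states (ages x n_states); default resident path.
#' @param l survivorship (vector); default resident.
#' @param env resident environment.
#' @return numeric vector of Hamiltonian values over the age grid.
#' @export
evaluate_hamiltonian <- function(model, traj, costates, j, i = NULL,
                                 z = NULL, x = NULL, l = NULL, env = NULL) {
  if (is.null(env)) env <- traj$env
  if (is.null(z)) z <- traj$z[j, ]
  if (is.null(x)) x <- traj$states[[j]]
  if (is.null(l)) l <- traj$surv[, j]
  if (costates$mode == "class_specific") {
    if (!is.null(i)) stop("costates are class-specific; call with i = NULL")
    lam_l <- costates$lambda_l[, j]
    lam_x <- costates$lambda_x[, , j, drop = FALSE]
    dim(lam_x) <- dim(lam_x)[1:2]
    f <- fec_eval(model, 0L, j, z, x, env)
  } else {
    if (is.null(i)) stop("costates are class-oriented; an offspring class i is required")
    lam_l <- costates$lambda_l[, i, j]
    lam_x <- costates$lambda_x[, , i, j, drop = FALSE]
    dim(lam_x) <- dim(lam_x)[1:2]
    f <- fec_eval(model, i, j, z, x, env)
  }
  mu <- model$mortality(j, z, x, env)
  g <- as_state_matrix(model$growth(j, z, x, env), model$n_states)
  l * f - lam_l * mu * l + rowSums(lam_x * g)
}
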
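# Resident (and mutant) survivorship and state dynamics, lifetime
# fecundities, the next-generation matrix and its eigen-structure.

#' Solve resident survivorship and internal-state dynamics
#'
#' Integrates, for each class j, the autonomous system
#' dl_j/da = -mu_j(v_j, x_j(a), v) l_j and dx_j/da = g_j(v_j, x_j(a), v) with
#' l_j(0) = 1 and x_j(0) = x_{j,0}. The age axis is truncated at `a_max`,
#' chosen adaptively so that every class's survivorship has fallen below
#' `tol`; all lifetime integrals downstream are truncated there.
#'
#' @param model a [life_history_model()].
#' @param v resident allelic values (`n_classes x n_traits` matrix or vector).
#' @param tol survivorship truncation tolerance defining `a_max`.
#' @param n_grid number of (uniform) age-grid points; forced odd for the
#'   Simpson rules.
#' @param a_max optional fixed truncation age (computed from `tol` if `NULL`).
#' @param env resident environment; recomputed from `v` if `NULL`.
#' @return an object of class `resident_trajectory`: list with `age`, `h`
#'   (spacing), `weights` (Simpson), `surv` (ages x classes), `states` (list
#'   of ages x n_states matrices), `a_max`, `v`, `env`.
#' @export
solve_resident <- function(model, v, tol = 1e-9, n_grid = 2001L,
                           a_max = NULL, env = NULL) {
  v <- as_trait_matrix(v, model$n_classes)
  if (is.null(env)) env <- prepare_env(model, v)
  solve_trajectories(model, z = v, v = v, env = env, tol = tol,
                     n_grid = n_grid, a_max = a_max)
}

# Shared machinery for resident (z = v) and mutant (z = z(u, v)) trajectories.
solve_trajectories <- function(model, z, v, env, tol = 1e-9, n_grid = 2001L,
                               a_max = NULL) {
  nc <- model$n_classes
  nx <- model$n_states
  derivs <- function(j, zj) {
    force(j); force(zj)
    function(t, y, parms) {
      x <- matrix(y[-1L], nrow = 1L)
      mu <- model$mortality(j, zj, x, env)
      g <- model$growth(j, zj, x, env)
      list(c(-mu * y[1L], as.numeric(g)))
    }
  }
  if (is.null(a_max)) {
    a_max <- 0
    for (j in seq_len(nc)) {
      f <- derivs(j, z[j, ])
      y0 <- c(1, model$initial_states[[j]])
      horizon <- 100
      aj <- NA_real_
      for (k in 1:14) {
        out <- deSolve::lsodar(y0, times = c(0, horizon), func = f,
                               rootfunc = function(t, y, p) y[1L] - tol,
                               rtol = 1e-10, atol = 1e-12)
        troot <- attr(out, "troot")
        if (length(troot) > 0 && is.finite(troot[1L])) {
          aj <- troot[1L]
          break
        }
        horizon <- horizon * 2
      }
      if (!is.finite(aj)) {
        stop("survivorship of class ", model$class_names[j],
             " did not fall below tol = ", tol, " within age ", horizon,
             "; mortality may vanish along the resident path")
      }
      a_max <- max(a_max, aj)
    }
  }
  n_grid <- as.integer(n_grid)
  if (n_grid %% 2L == 0L) n_grid <- n_grid + 1L
  age <- seq(0, a_max, length.out = n_grid)
  h <- age[2L] - age[1L]
  surv <- matrix(NA_real_, n_grid, nc, dimnames = list(NULL, model$class_names))
  states <- vector("list", nc)
  for (j in seq_len(nc)) {
    y0 <- c(1, model$initial_states[[j]])
    sol <- deSolve::lsoda(y0, times = age, func = derivs(j, z[j, ]),
                          rtol = 1e-10, atol = 1e-12)
    if (nrow(sol) < n_grid) {
      stop("ODE solver failed for class ", model$class_names[j],
           " (integration stopped at age ", max(sol[, 1L]), ")")
    }
    surv[, j] <- pmax(sol[, 2L], 0)
    states[[j]] <- matrix(sol[, -(1:2), drop = FALSE], n_grid, nx)
  }
  structure(list(age = age, h = h, weights = simpson_weights(n_grid, h),
                 surv = surv, states = states, a_max = a_max,
                 v = v, z = z, env = env, tol = tol),
            class = "resident_trajectory")
}

#' Mutant (or resident) next-generation matrix
#'
#' Element (i, j) is `gamma_ij * R_ij(u_j, v)`, the expected number of mutant
#' allele copies a mutant allele in a class-j carrier places into class-i
#' offspring over the carrier's lifetime, with lifetime class-oriented
#' fecundity `R_ij = int_0^inf l_j(a) f_ij(z_j(u_j, v_j), x_j(a), v) da`.
#' For `u != v` the mutant survivorship/state system is re-solved on the
#' resident truncation grid.
#'
#' @param model a [life_history_model()].
#' @param v resident allelic values.
#' @param u mutant allelic values; defaults to `v` (resident matrix).
#' @param traj resident trajectory from [solve_resident()] (resolved if `NULL`).
#' @param env resident environment (recomputed if `NULL`).
#' @return `n_classes x n_classes` matrix of expected transmitted copies, with
#'   the individual-level lifetime fecundities `R_ij` in attribute
#'   `"lifetime_fecundity"`.
#' @export
next_generation_matrix <- function(model, v, u = NULL, traj = NULL, env = NULL) {
  v <- as_trait_matrix(v, model$n_classes)
  if (is.null(env)) env <- prepare_env(model, v)
  if (is.null(traj)) traj <- solve_resident(model, v, env = env)
  if (!is.null(u)) {
    u <- as_trait_matrix(u, model$n_classes)
    if (max(abs(u - v)) > 0) {
      z <- express_traits(u, v, model$genetics)
      traj <- solve_trajectories(model, z = z, v = v, env = env,
                                 n_grid = length(traj$age), a_max = traj$a_max)
    }
  }
  nc <- model$n_classes
  Rij <- matrix(NA_real_, nc, nc,
                dimnames = list(model$class_names, model$class_names))
  w <- traj$weights
  for (j in seq_len(nc)) {
    zj <- traj$z[j, ]
    lj <- traj$surv[, j]
    xj <- traj$states[[j]]
    for (i in seq_len(nc)) {
      y <- lj * model$fecundity(i, j, zj, xj, env)
      tail_frac <- abs(y[length(y)]) * traj$h
      Rij[i, j] <- sum(w * y)
      if (is.finite(Rij[i, j]) && tail_frac > 1e-6 * max(abs(Rij[i, j]), 1)) {
        warning("fecundity integral f[", i, ",", j,
                "] has a non-negligible tail beyond a_max; ",
                "consider a smaller truncation tol")
      }
    }
  }
  structure(model$genetics$gamma * Rij, lifetime_fecundity = Rij)
}

#' Eigen-structure of a next-generation matrix
#'
#' The basic reproductive number R0 is the leading (Perron) eigenvalue; the
#' associated right eigenvector `q` gives the frequencies of mutant alleles
#' among newborn carriers of each class, and the left eigenvector `nu` their
#' reproductive values at birth. `q` is normalised to sum to one and `nu` so
#' that `sum(nu * q) = 1` (selection-gradient zeros and all stability
#' classifications are invariant to the scale of `nu`).
#'
#' @param R a non-negative square matrix, e.g. from
#'   [next_generation_matrix()].
#' @return object of class `birth_structure`: list with `R0`, `q`, `nu`, `R`
#'   and `lifetime_fecundity` (when present on `R`).
#' @export
birth_structure <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (any(R < -1e-12)) stop("next-generation matrix must be non-negative")
  er <- eigen(R)
  k <- which.max(Re(er$values))
  lead <- er$values[k]
  gap <- sort(abs(er$values), decreasing = TRUE)
  if (length(gap) > 1L && gap[1L] > 0 && (gap[1L] - gap[2L]) < 1e-10 * gap[1L]) {
    warning("leading eigenvalue is (near-)degenerate; ",
            "the birth eigenvectors are not uniquely defined")
  }
  if (abs(Im(lead)) > 1e-10 * max(1, abs(lead))) {
    stop("leading eigenvalue is complex; matrix is not primitive")
  }
  q <- Re(er$vectors[, k])
  if (sum(q) < 0) q <- -q
  q <- q / sum(q)
  el <- eigen(t(R))
  kl <- which.min(abs(el$values - lead))
  nu <- Re(el$vectors[, kl])
  if (sum(nu) < 0) nu <- -nu
  nu <- nu / sum(nu * q)
  nms <- rownames(R)
  if (!is.null(nms)) names(q) <- names(nu) <- nms
  structure(list(R0 = Re(lead), q = q, nu = nu, R = R,
                 lifetime_fecundity = attr(R, "lifetime_fecundity")),
            class = "birth_structure")
}

#' @export
print.birth_structure <- function(x, ...) {
  cat("<birth_structure> R0 =", format(x$R0, digits = 8), "\n")
  cat("birth class frequencies q: ", paste(format(x$q, digits = 6), collapse = ", "), "\n")
  cat("reproductive values nu:    ", paste(format(x$nu, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy export of a trajectory
#'
#' @param x a `resident_trajectory`.
#' @param ... unused.
#' @return data frame with columns `class`, `age`, `survivorship`,
#'   `state_1..state_nx`.
#' @export
as.data.frame.resident_trajectory <- function(x, ...) {
  nc <- ncol(x$surv)
  out <- vector("list", nc)
  for (j in seq_len(nc)) {
    df <- data.frame(class = colnames(x$surv)[j], age = x$age,
                     survivorship = x$surv[, j])
    st <- as.data.frame(x$states[[j]])
    names(st) <- paste0("state_", seq_len(ncol(st)))
    out[[j]] <- cbind(df, st)
  }
  do.call(rbind, out)
}
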
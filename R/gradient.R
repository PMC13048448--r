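# Directional selection: age-specific kernels, total coefficients, singular
# strategies and convergence stability.

# One full resident analysis at v: environment, trajectory, costates, birth
# structure. All directional/quadratic machinery is built on this state.
analysis_state <- function(model, v, mode = "auto", tol = 1e-9,
                           n_grid = 2001L) {
  v <- as_trait_matrix(v, model$n_classes)
  env <- prepare_env(model, v)
  traj <- solve_resident(model, v, tol = tol, n_grid = n_grid, env = env)
  costates <- solve_costates(model, v, traj, mode = mode, env = env)
  R <- next_generation_matrix(model, v, traj = traj, env = env)
  bs <- birth_structure(R)
  list(v = v, env = env, traj = traj, costates = costates, bs = bs)
}

# nu_check_j = sum_i nu_i gamma_ij c_ij: reproductive value at birth of one
# average offspring of a class-j parent (class-specific shortcut weight).
nu_check <- function(model, bs) {
  as.numeric(t(bs$nu) %*% (model$genetics$gamma * model$class_proportions))
}

#' Age-specific directional selection kernels
#'
#' For every (class j, trait l), the age-resolved coefficient
#' `s^_jl(a, v) = sum_i nu_i gamma_ij (dH_ij/dz_jl) q_j`, the
#' reproductive-value-weighted marginal effect of trait (j, l) on the
#' class-oriented Hamiltonians at age `a`. The total coefficient is the age
#' integral times the genetic exposure.
#'
#' @param model a [life_history_model()].
#' @param v resident allelic values.
#' @param state optional precomputed internal analysis state; recomputed from
#'   `v` when `NULL`.
#' @return matrix of kernels, ages x (class.trait), with the age grid in
#'   attribute `"age"`.
#' @keywords internal
age_specific_gradient <- function(model, v, state = NULL) {
  if (is.null(state)) state <- analysis_state(model, v)
  traj <- state$traj
  cst <- state$costates
  bs <- state$bs
  nc <- model$n_classes
  nz <- model$n_traits
  n <- length(traj$age)
  kern <- matrix(0, n, nc * nz)
  colnames(kern) <- trait_labels(model)
  for (j in seq_len(nc)) {
    zj <- traj$z[j, ]
    for (l in seq_len(nz)) {
      hl <- fd_step(zj[l], .fd_rel_grad)
      zp <- zj; zp[l] <- zj[l] + hl
      zm <- zj; zm[l] <- zj[l] - hl
      if (cst$mode == "class_specific") {
        dH <- (evaluate_hamiltonian(model, traj, cst, j, z = zp) -
               evaluate_hamiltonian(model, traj, cst, j, z = zm)) / (2 * hl)
        wgt <- nu_check(model, bs)[j] * bs$q[j]
        kern[, (j - 1L) * nz + l] <- wgt * dH
      } else {
        acc <- 0
        for (i in seq_len(nc)) {
          dH <- (evaluate_hamiltonian(model, traj, cst, j, i = i, z = zp) -
                 evaluate_hamiltonian(model, traj, cst, j, i = i, z = zm)) / (2 * hl)
          acc <- acc + bs$nu[i] * model$genetics$gamma[i, j] * dH
        }
        kern[, (j - 1L) * nz + l] <- acc * bs$q[j]
      }
    }
  }
  attr(kern, "age") <- traj$age
  kern
}

#' Selection gradient on all traits
#'
#' Orchestrates the resident solve, the costate solve and the age-specific
#' kernels, and integrates them into the total directional selection
#' coefficients `s_jl(v)` (one per class/trait, including the genetic
#' exposure factor dz/du). Under genetic constraints (pleiotropic traits
#' forced to mutate together), the coefficient of a constraint group is the
#' sum of its members' coefficients.
#'
#' @param model a [life_history_model()].
#' @param v resident allelic values.
#' @param constraints optional list of integer vectors of flattened
#'   (class-major) trait indices; each vector is a group expressed from the
#'   same pleiotropic genes. E.g. `list(c(1, 2))` shares trait 1 of class 1
#'   with trait 1 of class 2 in a one-trait two-class model.
#' @param state optional precomputed analysis state.
#' @return object of class `selection_gradient`: list with `total` (named
#'   vector), `kernels`, `age`, `v`, `constraints` and `constrained_total`.
#' @export
selection_gradient <- function(model, v, constraints = NULL, state = NULL) {
  if (is.null(state)) state <- analysis_state(model, v)
  kern <- age_specific_gradient(model, v, state)
  w <- state$traj$weights
  exposure <- rep(model$genetics$exposure, each = model$n_traits)
  total <- as.numeric(t(kern) %*% w) * exposure
  names(total) <- colnames(kern)
  ct <- NULL
  if (!is.null(constraints)) {
    ct <- constrained_totals(total, constraints)
  }
  structure(list(total = total, kernels = kern, age = state$traj$age,
                 v = state$v, constraints = constraints,
                 constrained_total = ct),
            class = "selection_gradient")
}

# Collapse per-trait totals onto constraint groups; free traits keep their own
# entry. Returns a named vector in reduced coordinates.
constrained_totals <- function(total, constraints) {
  np <- length(total)
  in_group <- unlist(constraints)
  stopifnot(!anyDuplicated(in_group), all(in_group %in% seq_len(np)))
  free <- setdiff(seq_len(np), in_group)
  red <- c(vapply(constraints, function(g) sum(total[g]), numeric(1L)),
           total[free])
  names(red) <- c(vapply(constraints, function(g)
    paste(names(total)[g], collapse = "+"), character(1L)),
    names(total)[free])
  attr(red, "groups") <- constraints
  attr(red, "free") <- free
  red
}

# reduced <-> full coordinate maps under constraints
reduce_v <- function(v_full, constraints) {
  if (is.null(constraints)) return(v_full)
  free <- setdiff(seq_along(v_full), unlist(constraints))
  c(vapply(constraints, function(g) mean(v_full[g]), numeric(1L)), v_full[free])
}
expand_v <- function(theta, v_template, constraints) {
  if (is.null(constraints)) return(theta)
  v <- v_template
  ng <- length(constraints)
  for (k in seq_len(ng)) v[constraints[[k]]] <- theta[k]
  free <- setdiff(seq_along(v), unlist(constraints))
  v[free] <- theta[-seq_len(ng)]
  v
}

#' Locate a singular strategy
#'
#' Finds trait values `v*` at which every (unconstrained) directional
#' selection coefficient vanishes, by a damped Newton iteration on the
#' selection gradient with a finite-difference Jacobian (`method = "newton"`,
#' the default), or by a coarse grid scan followed by Newton polishing
#' (`method = "grid"`). Components that run into the admissible-range
#' boundary with selection still pointing outward are reported as
#' boundary-pinned (the singular value sits on the boundary).
#'
#' @param model a [life_history_model()].
#' @param v0 initial guess (full coordinates).
#' @param constraints optional constraint groups (see
#'   [selection_gradient()]).
#' @param method `"newton"` or `"grid"`.
#' @param lower,upper admissible box for allelic values (defaults from the
#'   model's `trait_bounds`; the grid method needs a finite box).
#' @param gtol convergence tolerance on the max-norm of the gradient.
#' @param maxit Newton iteration cap.
#' @param step_max largest Newton step per component and iteration.
#' @param grid_n grid points per dimension for `method = "grid"`.
#' @return object of class `singular_strategy`: list with `v` (full
#'   coordinates), `gradient` (at `v`), `converged`, `pinned` (logical, by
#'   flattened trait), `iterations`.
#' @export
find_singular_strategy <- function(model, v0, constraints = NULL,
                                   method = c("newton", "grid"),
                                   lower = NULL, upper = NULL,
                                   gtol = 1e-8, maxit = 50L, step_max = 0.2,
                                   grid_n = 21L) {
  method <- match.arg(method)
  np_full <- model$n_classes * model$n_traits
  v0 <- as.numeric(as_trait_matrix(v0, model$n_classes))
  # flattened class-major order: as_trait_matrix is classes x traits,
  # flattening must match trait_labels(): (j - 1) * nz + l
  v0 <- as.numeric(t(matrix(v0, model$n_classes, model$n_traits)))
  if (is.null(lower)) lower <- rep(model$trait_bounds[1L], np_full)
  if (is.null(upper)) upper <- rep(model$trait_bounds[2L], np_full)
  lower <- rep_len(lower, np_full)
  upper <- rep_len(upper, np_full)

  gfun <- function(v_flat) {
    vm <- matrix(v_flat, model$n_classes, model$n_traits, byrow = TRUE)
    sg <- selection_gradient(model, vm, constraints = constraints)
    if (is.null(constraints)) sg$total else sg$constrained_total
  }
  th_lower <- reduce_v(lower, constraints)
  th_upper <- reduce_v(upper, constraints)

  if (method == "grid") {
    # coarse scan of the gradient norm over the box, then polish from the
    # best grid point (mirrors a grid + interpolation workflow, with the
    # interpolation replaced by Newton refinement from the best cell)
    th0 <- reduce_v(v0, constraints)
    npar <- length(th0)
    lo <- pmax(th_lower, th0 - 0.5)
    hi <- pmin(th_upper, th0 + 0.5)
    axes <- lapply(seq_len(npar), function(k) seq(lo[k], hi[k], length.out = grid_n))
    pts <- as.matrix(do.call(expand.grid, axes))
    best <- NULL
    best_norm <- Inf
    for (r in seq_len(nrow(pts))) {
      g <- tryCatch(gfun(expand_v(pts[r, ], v0, constraints)), error = function(e) NULL)
      if (!is.null(g) && max(abs(g)) < best_norm) {
        best_norm <- max(abs(g))
        best <- pts[r, ]
      }
    }
    if (is.null(best)) stop("gradient could not be evaluated anywhere on the grid")
    v0 <- expand_v(best, v0, constraints)
  }

  theta <- pmin(pmax(reduce_v(v0, constraints), th_lower), th_upper)
  npar <- length(theta)
  pinned <- rep(FALSE, npar)
  g <- gfun(expand_v(theta, v0, constraints))
  it <- 0L
  converged <- FALSE
  for (it in seq_len(maxit)) {
    at_lo <- theta <= th_lower + 1e-12
    at_hi <- theta >= th_upper - 1e-12
    pinned <- (at_lo & g < 0) | (at_hi & g > 0)
    free <- which(!pinned)
    if (length(free) == 0L || max(abs(g[free])) < gtol) {
      converged <- TRUE
      break
    }
    J <- matrix(0, npar, length(free))
    for (kk in seq_along(free)) {
      k <- free[kk]
      hk <- fd_step(theta[k], 1e-4)
      tp <- theta; tm <- theta
      if (theta[k] - hk < th_lower[k]) {        # one-sided at the boundary
        tp[k] <- theta[k] + hk
        J[, kk] <- (gfun(expand_v(tp, v0, constraints)) - g) / hk
      } else if (theta[k] + hk > th_upper[k]) {
        tm[k] <- theta[k] - hk
        J[, kk] <- (g - gfun(expand_v(tm, v0, constraints))) / hk
      } else {
        tp[k] <- theta[k] + hk
        tm[k] <- theta[k] - hk
        J[, kk] <- (gfun(expand_v(tp, v0, constraints)) -
                    gfun(expand_v(tm, v0, constraints))) / (2 * hk)
      }
    }
    Jf <- J[free, , drop = FALSE]
    step <- tryCatch(solve(Jf, -g[free]), error = function(e) -g[free])
    step <- pmin(pmax(step, -step_max), step_max)
    # backtracking on the gradient norm
    ok <- FALSE
    for (bt in 0:4) {
      cand <- theta
      cand[free] <- theta[free] + step / 2^bt
      cand <- pmin(pmax(cand, th_lower), th_upper)
      gc_ <- gfun(expand_v(cand, v0, constraints))
      if (max(abs(gc_[free])) < max(abs(g[free])) || bt == 4L) {
        theta <- cand
        g <- gc_
        ok <- TRUE
        break
      }
    }
    if (!ok) break
  }
  v_flat <- expand_v(theta, v0, constraints)
  # expand reduced pinned flags to the full coordinates
  pinned_full <- rep(FALSE, np_full)
  if (is.null(constraints)) {
    pinned_full <- pinned
  } else {
    ng <- length(constraints)
    for (k in seq_len(ng)) pinned_full[constraints[[k]]] <- pinned[k]
    free_idx <- setdiff(seq_len(np_full), unlist(constraints))
    pinned_full[free_idx] <- pinned[-seq_len(ng)]
  }
  vm <- matrix(v_flat, model$n_classes, model$n_traits, byrow = TRUE)
  structure(list(v = vm, v_flat = v_flat, gradient = g,
                 converged = converged || all(pinned),
                 pinned = pinned_full, iterations = it,
                 constraints = constraints),
            class = "singular_strategy")
}

#' @export
print.singular_strategy <- function(x, ...) {
  cat("<singular_strategy>", if (x$converged) "(converged)" else "(NOT converged)", "\n")
  v <- x$v_flat
  lab <- if (any(x$pinned)) ifelse(x$pinned, " [boundary-pinned]", "") else rep("", length(v))
  for (k in seq_along(v)) cat(sprintf("  v*[%d] = %.6f%s\n", k, v[k], lab[k]))
  cat("  max |gradient| =", format(max(abs(x$gradient)), digits = 3), "\n")
  invisible(x)
}

#' Convergence stability of a singular strategy
#'
#' Central finite-difference Jacobian of the selection gradient with respect
#' to the resident trait values, `J_kl = d s_k / d v_l` at `v*`. The strategy
#' is strongly convergence stable when the symmetric part of `J` is negative
#' definite: gradual evolution then approaches `v*` from all nearby residents
#' regardless of the mutational covariance structure. Every evaluation
#' re-solves the full resident system, since the resident traits enter the
#' environment as well as the focal rates.
#'
#' @param model a [life_history_model()].
#' @param vstar singular strategy (full coordinates; matrix or vector).
#' @param constraints optional constraint groups, as in
#'   [selection_gradient()].
#' @param step relative finite-difference step.
#' @return object of class `jacobian_report`: list with `J`, `sym_eigen`,
#'   `leading` (leading symmetric-part eigenvalue) and `label` in
#'   `strongly_convergence_stable` / `not_negative_semidefinite` / `marginal`.
#' @export
convergence_stability <- function(model, vstar, constraints = NULL,
                                  step = 1e-3) {
  v0 <- as.numeric(t(as_trait_matrix(vstar, model$n_classes)))
  gfun <- function(v_flat) {
    vm <- matrix(v_flat, model$n_classes, model$n_traits, byrow = TRUE)
    sg <- selection_gradient(model, vm, constraints = constraints)
    if (is.null(constraints)) sg$total else sg$constrained_total
  }
  theta <- reduce_v(v0, constraints)
  npar <- length(theta)
  J <- matrix(0, npar, npar)
  for (k in seq_len(npar)) {
    hk <- fd_step(theta[k], step)
    tp <- theta; tp[k] <- theta[k] + hk
    tm <- theta; tm[k] <- theta[k] - hk
    J[, k] <- (gfun(expand_v(tp, v0, constraints)) -
               gfun(expand_v(tm, v0, constraints))) / (2 * hk)
  }
  S <- (J + t(J)) / 2
  ev <- eigen(S, symmetric = TRUE)$values
  nrm <- max(abs(J))
  leading <- max(ev)
  label <- if (abs(leading) < 1e-6 * max(nrm, 1e-300)) {
    "marginal"
  } else if (leading < 0) {
    "strongly_convergence_stable"
  } else {
    "not_negative_semidefinite"
  }
  # J's own spectrum: all eigenvalues in the left half-plane means v* still
  # attracts under isotropic mutational covariance, even when the symmetric
  # part is indefinite (not *strongly* convergence stable)
  J_eigen <- eigen(J)$values
  structure(list(J = J, sym_eigen = ev, leading = leading, label = label,
                 J_eigen = J_eigen,
                 isotropic_stable = all(Re(J_eigen) < 0)),
            class = "jacobian_report")
}

#' @export
print.jacobian_report <- function(x, ...) {
  cat("<jacobian_report>", x$label, "\n")
  cat("leading symmetric-part eigenvalue:", format(x$leading, digits = 6), "\n")
  invisible(x)
}
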
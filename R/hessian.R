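# Quadratic selection at a singular strategy: trait-induced perturbations of
# states, survivorship and birth-class frequencies; the six age-resolved
# Hessian components; assembly and stabilising/disruptive classification.

#' Trait-induced perturbations of states, survivorship and birth frequencies
#'
#' Computes, at a singular strategy, the building blocks of the indirect
#' quadratic selection pathways: the fundamental (propagator) matrices
#' `Psi_j(a, tau)` of the linearised state dynamics, the state sensitivities
#' `dx_j(a)/dz_jl`, the survivorship sensitivities `dl_j(a)/dz_jl`, and the
#' sensitivities `dq/dz_jl` of mutant birth-class frequencies obtained from a
#' linear solve around the next-generation matrix.
#'
#' @param model a [life_history_model()].
#' @param vstar singular trait values.
#' @param state optional precomputed analysis state.
#' @return object of class `perturbation_set`: per-class lists `Phi`
#'   (propagator from age 0, ages x nx x nx), `dx_dz` (ages x nx x n_traits),
#'   `dl_dz` (ages x n_traits), a function `psi(j, a, tau)`, and `dq_dz`
#'   (n_classes x flattened traits).
#' @export
compute_perturbations <- function(model, vstar, state = NULL) {
  if (is.null(state)) state <- analysis_state(model, vstar)
  traj <- state$traj
  env <- state$env
  nc <- model$n_classes
  nx <- model$n_states
  nz <- model$n_traits
  n <- length(traj$age)
  h <- traj$h

  per_class <- vector("list", nc)
  for (j in seq_len(nc)) {
    zj <- traj$z[j, ]
    xj <- traj$states[[j]]
    lj <- traj$surv[, j]
    d <- rate_state_derivs(model, j, zj, xj, env, fij_list = list())
    A <- d$dg  # [age, d/dx_m, component]
    # propagator Phi(a) with dPhi/da = A(a) Phi, Phi(0) = I
    A0 <- matrix(A[1L, , ], nx, nx)
    const_A <- max(abs(sweep(A, c(2, 3), A[1L, , ]))) < 1e-10
    Phi <- array(0, dim = c(n, nx, nx))
    if (const_A && nx == 1L) {
      Phi[, 1L, 1L] <- exp(A0[1L, 1L] * traj$age)
    } else if (const_A) {
      for (k in seq_len(n)) Phi[k, , ] <- pracma::expm(A0 * traj$age[k])
    } else {
      afun <- vector("list", nx * nx)
      dim(afun) <- c(nx, nx)
      for (m in seq_len(nx)) for (k2 in seq_len(nx)) {
        afun[[m, k2]] <- stats::splinefun(traj$age, A[, m, k2], method = "natural")
      }
      dfun <- function(t, y, p) {
        Aa <- matrix(vapply(afun, function(f) f(t), numeric(1L)), nx, nx)
        list(as.numeric(Aa %*% matrix(y, nx, nx)))
      }
      sol <- deSolve::lsoda(as.numeric(diag(nx)), times = traj$age, func = dfun,
                            rtol = 1e-10, atol = 1e-12)
      for (k in seq_len(n)) Phi[k, , ] <- matrix(sol[k, -1L], nx, nx)
    }
    # trait derivatives of the developmental and mortality rates
    gz <- array(0, dim = c(n, nx, nz))
    muz <- matrix(0, n, nz)
    for (l in seq_len(nz)) {
      hl <- fd_step(zj[l], .fd_rel_grad)
      zp <- zj; zp[l] <- zj[l] + hl
      zm <- zj; zm[l] <- zj[l] - hl
      gz[, , l] <- (as_state_matrix(model$growth(j, zp, xj, env), nx) -
                    as_state_matrix(model$growth(j, zm, xj, env), nx)) / (2 * hl)
      muz[, l] <- (model$mortality(j, zp, xj, env) -
                   model$mortality(j, zm, xj, env)) / (2 * hl)
    }
    # dx/dz_l(a) = Phi(a) int_0^a Phi(tau)^{-1} g_z(tau) dtau
    dx_dz <- array(0, dim = c(n, nx, nz))
    if (nx == 1L) {
      phi1 <- Phi[, 1L, 1L]
      for (l in seq_len(nz)) {
        dx_dz[, 1L, l] <- phi1 * cumquad(gz[, 1L, l] / phi1, h)
      }
    } else {
      Phinv <- array(0, dim = c(n, nx, nx))
      for (k in seq_len(n)) Phinv[k, , ] <- solve(matrix(Phi[k, , ], nx, nx))
      for (l in seq_len(nz)) {
        B <- matrix(0, n, nx)
        for (k in seq_len(n)) {
          B[k, ] <- matrix(Phinv[k, , ], nx, nx) %*% gz[k, , l]
        }
        Bc <- apply(B, 2L, cumquad, h = h)
        for (k in seq_len(n)) {
          dx_dz[k, , l] <- matrix(Phi[k, , ], nx, nx) %*% Bc[k, ]
        }
      }
    }
    # dl/dz_l(a) = -l(a) int_0^a (mu_x . dx/dz_l + mu_z) dtau
    dl_dz <- matrix(0, n, nz)
    for (l in seq_len(nz)) {
      integrand <- rowSums(d$dmu * matrix(dx_dz[, , l], n, nx)) + muz[, l]
      dl_dz[, l] <- -lj * cumquad(integrand, h)
    }
    per_class[[j]] <- list(Phi = Phi, dx_dz = dx_dz, dl_dz = dl_dz,
                           A_const = const_A, A = A)
  }

  # dq/dz_jl at the singular strategy:
  # dq = -((R^T - I)(R - I) + 1)^{-1} (R^T - I) (dR/dz_jl) q
  R <- state$bs$R
  q <- state$bs$q
  RtI <- t(R) - diag(nc)
  M <- RtI %*% (R - diag(nc)) + matrix(1, nc, nc)
  dq_dz <- matrix(0, nc, nc * nz)
  colnames(dq_dz) <- trait_labels(model)
  for (j in seq_len(nc)) {
    for (l in seq_len(nz)) {
      hz <- fd_step(state$v[j, l], 1e-4)
      du <- hz / model$genetics$exposure[j]   # u-step producing a z-step hz
      up <- state$v; up[j, l] <- up[j, l] + du
      um <- state$v; um[j, l] <- um[j, l] - du
      Rp <- next_generation_matrix(model, state$v, u = up, traj = traj, env = env)
      Rm <- next_generation_matrix(model, state$v, u = um, traj = traj, env = env)
      dR <- (Rp - Rm) / (2 * hz)
      dq <- tryCatch(-solve(M, RtI %*% dR %*% q), error = function(e) {
        stop("singular linear system for the birth-frequency perturbation")
      })
      dq_dz[, (j - 1L) * nz + l] <- as.numeric(dq)
    }
  }

  psi <- function(j, a, tau) {
    pc <- per_class[[j]]
    if (pc$A_const && nx == 1L) {
      matrix(exp(pc$A[1L, 1L, 1L] * (a - tau)), 1L, 1L)
    } else if (pc$A_const) {
      pracma::expm(matrix(pc$A[1L, , ], nx, nx) * (a - tau))
    } else {
      Pa <- apply(pc$Phi, c(2, 3), function(col) stats::spline(traj$age, col, xout = a)$y)
      Pt <- apply(pc$Phi, c(2, 3), function(col) stats::spline(traj$age, col, xout = tau)$y)
      matrix(Pa, nx, nx) %*% solve(matrix(Pt, nx, nx))
    }
  }

  structure(list(classes = per_class, dq_dz = dq_dz, psi = psi,
                 age = traj$age),
            class = "perturbation_set")
}

# Weighted Hamiltonian-derivative operator: given a function that evaluates a
# (possibly perturbed) Hamiltonian for parental class j (and offspring class
# i in class-oriented mode), return sum_i nu_i gamma_ij D_ij (no q factor).
weighted_ham <- function(model, state, j, eval_fn) {
  cst <- state$costates
  if (cst$mode == "class_specific") {
    nu_check(model, state$bs)[j] * eval_fn(NULL)
  } else {
    acc <- 0
    for (i in seq_len(model$n_classes)) {
      acc <- acc + state$bs$nu[i] * model$genetics$gamma[i, j] * eval_fn(i)
    }
    acc
  }
}

#' Hessian of quadratic selection at a singular strategy
#'
#' Assembles the matrix of quadratic selection coefficients `h_ij,kl(v*)`
#' from six age-resolved components per within-class block: direct trait
#' effects (`zz`), state-mediated (`xx`), trait-state (`zx`),
#' trait-survivorship (`zl`), survivorship-state (`lx`), and birth-frequency
#' (`zq`) pathways; between-class blocks carry only the `zq` pathway. All
#' second derivatives of the Hamiltonians are central finite differences; the
#' state/survivorship/birth-frequency sensitivities come from
#' [compute_perturbations()].
#'
#' @param model a [life_history_model()].
#' @param vstar singular strategy (the decomposition is only valid where the
#'   selection gradient vanishes; a resident with a visibly nonzero gradient
#'   is rejected).
#' @param constraints optional constraint groups; the constrained coefficient
#'   of a group is the sum of its members' blocks (chain rule for fully
#'   correlated mutation effects).
#' @param state optional precomputed analysis state.
#' @param fd_rel relative step for the second-order finite differences.
#' @param gradient_tol largest acceptable max-norm of the gradient at
#'   `vstar`.
#' @return object of class `hessian_report`: `H` (full symmetric matrix over
#'   flattened traits), `components` (list of per-block age kernels),
#'   `eigen`, `labels` (per-trait stabilising/disruptive), `net`
#'   (`"net_stabilising"` / `"net_disruptive"`), `branching_direction`,
#'   and, under constraints, the reduced matrix `H_constrained`.
#' @export
selection_hessian <- function(model, vstar, constraints = NULL, state = NULL,
                              fd_rel = .fd_rel_hess, gradient_tol = 1e-3) {
  if (is.null(state)) state <- analysis_state(model, vstar)
  sg <- selection_gradient(model, state$v, constraints = constraints, state = state)
  gr <- if (is.null(constraints)) sg$total else sg$constrained_total
  if (max(abs(gr)) > gradient_tol) {
    stop("the quadratic decomposition assumes a singular strategy; ",
         "|gradient| = ", format(max(abs(gr))), " at the supplied vstar")
  }
  pert <- compute_perturbations(model, vstar, state)
  traj <- state$traj
  env <- state$env
  nc <- model$n_classes
  nx <- model$n_states
  nz <- model$n_traits
  n <- length(traj$age)
  w <- traj$weights
  np <- nc * nz
  labels_ <- trait_labels(model)

  # Hamiltonian evaluator with overrides, per parental class
  Hj <- function(j, i, z = NULL, xshift = NULL, lshift = 0) {
    x <- traj$states[[j]]
    if (!is.null(xshift)) x <- x + rep(xshift, each = n)
    l <- traj$surv[, j] + lshift
    evaluate_hamiltonian(model, traj, state$costates, j, i = i,
                         z = z, x = x, l = l, env = env)
  }

  # second-order central differences of the weighted Hamiltonian, class j
  d2_zz <- function(j, k, l) {
    zj <- traj$z[j, ]
    hk <- fd_step(zj[k], fd_rel); hl <- fd_step(zj[l], fd_rel)
    weighted_ham(model, state, j, function(i) {
      if (k == l) {
        zp <- zj; zp[k] <- zj[k] + hk
        zm <- zj; zm[k] <- zj[k] - hk
        (Hj(j, i, z = zp) - 2 * Hj(j, i) + Hj(j, i, z = zm)) / hk^2
      } else {
        zpp <- zj; zpp[k] <- zj[k] + hk; zpp[l] <- zpp[l] + hl
        zpm <- zj; zpm[k] <- zj[k] + hk; zpm[l] <- zpm[l] - hl
        zmp <- zj; zmp[k] <- zj[k] - hk; zmp[l] <- zmp[l] + hl
        zmm <- zj; zmm[k] <- zj[k] - hk; zmm[l] <- zmm[l] - hl
        (Hj(j, i, z = zpp) - Hj(j, i, z = zpm) - Hj(j, i, z = zmp) +
           Hj(j, i, z = zmm)) / (4 * hk * hl)
      }
    })
  }
  x_step <- function(j, m) fd_rel * max(1, max(abs(traj$states[[j]][, m])))
  d2_xx <- function(j, m1, m2) {
    h1 <- x_step(j, m1); h2 <- x_step(j, m2)
    weighted_ham(model, state, j, function(i) {
      if (m1 == m2) {
        e <- numeric(nx); e[m1] <- h1
        (Hj(j, i, xshift = e) - 2 * Hj(j, i) + Hj(j, i, xshift = -e)) / h1^2
      } else {
        epp <- numeric(nx); epp[m1] <- h1; epp[m2] <- h2
        epm <- numeric(nx); epm[m1] <- h1; epm[m2] <- -h2
        (Hj(j, i, xshift = epp) - Hj(j, i, xshift = epm) -
           Hj(j, i, xshift = -epm) + Hj(j, i, xshift = -epp)) / (4 * h1 * h2)
      }
    })
  }
  d2_zx <- function(j, k, m) {
    zj <- traj$z[j, ]
    hk <- fd_step(zj[k], fd_rel); hm <- x_step(j, m)
    e <- numeric(nx); e[m] <- hm
    zp <- zj; zp[k] <- zj[k] + hk
    zm_ <- zj; zm_[k] <- zj[k] - hk
    weighted_ham(model, state, j, function(i) {
      (Hj(j, i, z = zp, xshift = e) - Hj(j, i, z = zp, xshift = -e) -
         Hj(j, i, z = zm_, xshift = e) + Hj(j, i, z = zm_, xshift = -e)) /
        (4 * hk * hm)
    })
  }
  d2_zl <- function(j, k) {
    zj <- traj$z[j, ]
    hk <- fd_step(zj[k], fd_rel); hl_ <- fd_rel
    zp <- zj; zp[k] <- zj[k] + hk
    zm_ <- zj; zm_[k] <- zj[k] - hk
    weighted_ham(model, state, j, function(i) {
      (Hj(j, i, z = zp, lshift = hl_) - Hj(j, i, z = zp, lshift = -hl_) -
         Hj(j, i, z = zm_, lshift = hl_) + Hj(j, i, z = zm_, lshift = -hl_)) /
        (4 * hk * hl_)
    })
  }
  d2_lx <- function(j, m) {
    hm <- x_step(j, m); hl_ <- fd_rel
    e <- numeric(nx); e[m] <- hm
    weighted_ham(model, state, j, function(i) {
      (Hj(j, i, xshift = e, lshift = hl_) - Hj(j, i, xshift = e, lshift = -hl_) -
         Hj(j, i, xshift = -e, lshift = hl_) + Hj(j, i, xshift = -e, lshift = -hl_)) /
        (4 * hm * hl_)
    })
  }
  d1_z <- function(j, k) {  # weighted dH/dz (no q), for the zq pathway
    zj <- traj$z[j, ]
    hk <- fd_step(zj[k], .fd_rel_grad)
    zp <- zj; zp[k] <- zj[k] + hk
    zm_ <- zj; zm_[k] <- zj[k] - hk
    weighted_ham(model, state, j, function(i) {
      (Hj(j, i, z = zp) - Hj(j, i, z = zm_)) / (2 * hk)
    })
  }

  q <- state$bs$q
  comp_names <- c("zz", "xx", "zx", "zl", "lx", "zq")
  kernels <- array(0, dim = c(n, np, np, 6L),
                   dimnames = list(NULL, labels_, labels_, comp_names))
  for (j in seq_len(nc)) {
    pc <- pert$classes[[j]]
    for (k in seq_len(nz)) {
      pk <- (j - 1L) * nz + k
      for (l in k:nz) {
        pl <- (j - 1L) * nz + l
        zz <- q[j] * d2_zz(j, k, l)
        xx <- 0
        for (m1 in seq_len(nx)) for (m2 in seq_len(nx)) {
          xx <- xx + q[j] * d2_xx(j, m1, m2) * pc$dx_dz[, m1, k] * pc$dx_dz[, m2, l]
        }
        zx <- 0
        for (m in seq_len(nx)) {
          zx <- zx + q[j] * (d2_zx(j, k, m) * pc$dx_dz[, m, l] +
                               d2_zx(j, l, m) * pc$dx_dz[, m, k])
        }
        zl <- q[j] * (d2_zl(j, k) * pc$dl_dz[, l] + d2_zl(j, l) * pc$dl_dz[, k])
        lx <- 0
        for (m in seq_len(nx)) {
          lx <- lx + q[j] * (pc$dl_dz[, k] * pc$dx_dz[, m, l] +
                               pc$dl_dz[, l] * pc$dx_dz[, m, k]) * d2_lx(j, m)
        }
        kernels[, pk, pl, "zz"] <- zz
        kernels[, pk, pl, "xx"] <- xx
        kernels[, pk, pl, "zx"] <- zx
        kernels[, pk, pl, "zl"] <- zl
        kernels[, pk, pl, "lx"] <- lx
        if (pl != pk) {
          kernels[, pl, pk, c("zz", "xx", "zx", "zl", "lx")] <-
            kernels[, pk, pl, c("zz", "xx", "zx", "zl", "lx")]
        }
      }
    }
  }
  # birth-frequency pathway, all (i, k) x (j, l) pairs
  d1_cache <- lapply(seq_len(nc), function(j)
    lapply(seq_len(nz), function(k) d1_z(j, k)))
  for (i in seq_len(nc)) for (k in seq_len(nz)) {
    pik <- (i - 1L) * nz + k
    for (j in seq_len(nc)) for (l in seq_len(nz)) {
      pjl <- (j - 1L) * nz + l
      if (pjl < pik) next
      zq <- d1_cache[[i]][[k]] * pert$dq_dz[i, pjl] +
        d1_cache[[j]][[l]] * pert$dq_dz[j, pik]
      kernels[, pik, pjl, "zq"] <- zq
      if (pjl != pik) kernels[, pjl, pik, "zq"] <- zq
    }
  }

  exposure <- rep(model$genetics$exposure, each = nz)
  H <- matrix(0, np, np, dimnames = list(labels_, labels_))
  for (p1 in seq_len(np)) for (p2 in seq_len(np)) {
    ker <- rowSums(matrix(kernels[, p1, p2, ], n, 6L))
    H[p1, p2] <- sum(w * ker) * exposure[p1] * exposure[p2]
  }
  H <- (H + t(H)) / 2

  ev <- eigen(H, symmetric = TRUE)
  leading <- ev$values[1L]
  per_trait <- ifelse(diag(H) > 0, "disruptive", "stabilising")
  net <- if (leading > 0) "net_disruptive" else "net_stabilising"
  bdir <- if (leading > 0) ev$vectors[, 1L] else NULL

  out <- list(H = H, kernels = kernels, age = traj$age,
              eigen = ev, leading = leading,
              labels = per_trait, net = net, branching_direction = bdir,
              vstar = state$v, perturbations = pert)
  if (!is.null(constraints)) {
    groups <- constraints
    free <- setdiff(seq_len(np), unlist(groups))
    nr <- length(groups) + length(free)
    Hc <- matrix(0, nr, nr)
    blocks <- c(groups, as.list(free))
    for (a_ in seq_len(nr)) for (b_ in seq_len(nr)) {
      Hc[a_, b_] <- sum(H[blocks[[a_]], blocks[[b_]]])
    }
    out$H_constrained <- Hc
    out$constrained_eigen <- eigen(Hc, symmetric = TRUE)
    out$constrained_net <- if (max(out$constrained_eigen$values) > 0)
      "net_disruptive" else "net_stabilising"
  }
  class(out) <- "hessian_report"
  out
}

#' Classify quadratic selection from an assembled Hessian
#'
#' @param report a [selection_hessian()] result (or a bare symmetric matrix).
#' @return list with `per_trait` labels (diagonal signs: positive means
#'   selection favours an increase in that trait's genetic variance, i.e. is
#'   disruptive for that trait evolving alone), `net` label from the leading
#'   eigenvalue, and the `branching_direction` (leading eigenvector) when net
#'   disruptive. A net-disruptive, convergence-stable singular strategy is a
#'   candidate evolutionary branching point.
#' @export
classify_second_order <- function(report) {
  H <- if (inherits(report, "hessian_report")) report$H else report
  ev <- eigen(H, symmetric = TRUE)
  leading <- ev$values[1L]
  list(per_trait = ifelse(diag(H) > 0, "disruptive", "stabilising"),
       net = if (leading > 0) "net_disruptive" else "net_stabilising",
       leading = leading,
       branching_direction = if (leading > 0) ev$vectors[, 1L] else NULL)
}

#' @export
print.hessian_report <- function(x, ...) {
  cat("<hessian_report> at v* =", paste(format(x$vstar, digits = 5), collapse = ", "), "\n")
  print(x$H)
  cat("eigenvalues:", paste(format(x$eigen$values, digits = 6), collapse = ", "), "\n")
  cat("net:", x$net, "\n")
  if (!is.null(x$H_constrained)) {
    cat("constrained (shared-trait) leading eigenvalue:",
        format(max(x$constrained_eigen$values), digits = 6),
        "->", x$constrained_net, "\n")
  }
  invisible(x)
}
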
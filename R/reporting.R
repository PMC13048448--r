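# Orchestration: run configured analysis stages and persist their outputs.

#' Run a configured analysis
#'
#' Executes the requested stages in dependency order on the sexual-niche
#' model and writes CSV/JSON outputs to `out_dir`. Recognised stages:
#' `"gradient"` (age-specific kernels at `v`), `"singular"` (singular
#' strategy from guess `v`), `"jacobian"` (convergence stability at the
#' singular strategy), `"hessian"` (quadratic selection at the singular
#' strategy), `"simulate"` (individual-based run). Later stages reuse the
#' singular strategy found by `"singular"`; `"jacobian"`/`"hessian"` without
#' it require `vstar` in the config.
#'
#' @param config a list (or path to a YAML file) with fields:
#'   `params` (list of sexual-niche parameters or path to a params YAML),
#'   `stages` (character vector), `v` (resident traits / initial guess),
#'   `vstar` (optional known singular strategy), `shared` (logical),
#'   `seed` (simulation seed), `sim` (optional list of [sim_config()]
#'   overrides: `K`, `duration`, `dt`, `mut_prob`, `mut_sd`, ...).
#' @param out_dir output directory (created if missing).
#' @return object of class `analysis_run`: list with `outputs` (manifest of
#'   files written), `results` (in-memory stage results) and `log`.
#' @export
run_analysis <- function(config, out_dir = ".") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% character()
  bad <- setdiff(stages, c("gradient", "singular", "jacobian", "hessian", "simulate"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  params <- config$params %||% list()
  if (is.character(params)) {
    params <- read_sn_params(params)
  } else {
    params <- do.call(sexual_niche_params, params)
  }
  shared <- isTRUE(config$shared)
  constraints <- if (shared) list(c(1L, 2L)) else NULL
  v <- as.numeric(config$v %||% c(0.5, 0.5))
  if (length(v) == 1L) v <- rep(v, 2L)
  model <- sexual_niche_model(params)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- character()
  results <- list()
  log <- list(params = unclass(params), shared = shared, stages = stages,
              tolerances = list(truncation_tol = 1e-9, gradient_tol = 1e-8,
                                jacobian_fd_step = 1e-3, hessian_fd_step = .fd_rel_hess))
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
  }

  vstar <- config$vstar
  if ("gradient" %in% stages) {
    sg <- selection_gradient(model, v, constraints = constraints)
    results$gradient <- sg
    emit("gradient_kernels.csv", function(path) {
      utils::write.csv(data.frame(age = sg$age, sg$kernels, check.names = FALSE),
                       path, row.names = FALSE)
    })
    emit("gradient_total.json", function(path) {
      jsonlite::write_json(list(v = v, total = as.list(sg$total),
                                constrained = as.list(sg$constrained_total)),
                           path, auto_unbox = TRUE, digits = NA)
    })
  }
  if ("singular" %in% stages) {
    ss <- find_singular_strategy(model, v, constraints = constraints)
    results$singular <- ss
    vstar <- ss$v_flat
    emit("singular.json", function(path) {
      jsonlite::write_json(list(vstar = ss$v_flat, converged = ss$converged,
                                pinned = ss$pinned,
                                gradient = as.numeric(ss$gradient)),
                           path, auto_unbox = TRUE, digits = NA)
    })
  }
  if ("jacobian" %in% stages) {
    if (is.null(vstar)) stop("jacobian requires a singular strategy: run the 'singular' stage or supply vstar")
    jr <- convergence_stability(model, vstar, constraints = constraints)
    results$jacobian <- jr
    emit("jacobian.json", function(path) {
      jsonlite::write_json(list(J = jr$J, sym_eigen = jr$sym_eigen, label = jr$label),
                           path, auto_unbox = TRUE, digits = NA)
    })
  }
  if ("hessian" %in% stages) {
    if (is.null(vstar)) stop("hessian requires a singular strategy: run the 'singular' stage or supply vstar")
    hr <- selection_hessian(model, vstar, constraints = constraints)
    results$hessian <- hr
    emit("hessian.json", function(path) {
      jsonlite::write_json(list(H = hr$H, eigenvalues = hr$eigen$values,
                                net = hr$net, labels = as.list(hr$labels)),
                           path, auto_unbox = TRUE, digits = NA)
    })
    emit("hessian_components.csv", function(path) {
      kn <- dimnames(hr$kernels)
      long <- expand.grid(p1 = kn[[2L]], p2 = kn[[3L]], stringsAsFactors = FALSE)
      dfs <- lapply(seq_len(nrow(long)), function(r) {
        comp <- hr$kernels[, long$p1[r], long$p2[r], ]
        data.frame(pair = paste(long$p1[r], long$p2[r], sep = ":"),
                   age = hr$age, comp, check.names = FALSE)
      })
      utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
    })
  }
  if ("simulate" %in% stages) {
    sim_over <- config$sim %||% list()
    sp <- params
    if (!is.null(sim_over$K)) sp$K <- sim_over$K
    init_v <- sim_over$init_v %||% vstar %||% v
    cfg <- sim_config(sp, genetics = sim_over$genetics %||% "diploid",
                      shared = shared, init_v = as.numeric(init_v),
                      dt = sim_over$dt %||% 0.2,
                      duration = sim_over$duration %||% 1e4,
                      mut_prob = sim_over$mut_prob %||% 0.01,
                      mut_sd = sim_over$mut_sd %||% 0.01)
    tr <- simulate_ibm(cfg, seed = config$seed %||% 1L)
    sm <- summarize_trace(tr)
    results$simulate <- list(trace = tr, summary = sm)
    emit("sim_traits.csv", function(path) {
      utils::write.csv(data.frame(time = tr$time, pop = tr$pop,
                                  n_f = tr$n_f, n_m = tr$n_m,
                                  mean_trait_f = tr$mean_f,
                                  mean_trait_m = tr$mean_m),
                       path, row.names = FALSE)
    })
    emit("sim_histograms.csv", function(path) {
      utils::write.csv(data.frame(size = sm$bins,
                                  density_f = sm$size_density_f,
                                  density_m = sm$size_density_m),
                       path, row.names = FALSE)
    })
    emit("sim_summary.json", function(path) {
      jsonlite::write_json(list(kl_male_female = sm$kl_male_female,
                                branching = sm$branching,
                                branching_fraction = sm$branching_fraction,
                                extinct = tr$extinct, seed = tr$seed),
                           path, auto_unbox = TRUE, digits = NA)
    })
  }
  structure(list(outputs = outputs, results = results, log = log),
            class = "analysis_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.analysis_run <- function(x, ...) {
  cat("<analysis_run> stages:", paste(x$log$stages, collapse = ", "), "\n")
  cat("outputs:\n")
  for (f in x$outputs) cat("  -", f, "\n")
  invisible(x)
}
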
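#!/usr/bin/env Rscript

# Thin command-line wrapper over ontosel::run_analysis().
#
# Usage:
#   Rscript scripts/ontosel.R run --config cfg.yaml --out results/
#   Rscript scripts/ontosel.R gradient --params params.yaml --v 0.5,0.45 --out results/
#   Rscript scripts/ontosel.R singular --params params.yaml --guess 0.5,0.5 [--shared] --out results/
#   Rscript scripts/ontosel.R hessian  --params params.yaml --guess 0.5,0.5 [--shared] --out results/
#   Rscript scripts/ontosel.R simulate --params params.yaml --v 0.52,0.43 --duration 10000 \
#       --K 1000 --seed 1 [--shared] --out results/
#
# `--params` is a flat YAML file with keys c, alpha, mu_e_f, mu_e_m, beta_f,
# beta_m, kappa, K; omitted keys take the package defaults.

suppressPackageStartupMessages(library(ontosel))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  stop("usage: ontosel.R <run|gradient|singular|jacobian|hessian|simulate> [options]")
}
cmd <- args[1L]
args <- args[-1L]
opt <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
has_flag <- function(flag) flag %in% args
num_vec <- function(s) if (is.null(s)) NULL else as.numeric(strsplit(s, ",")[[1L]])

out_dir <- opt("--out", ".")

if (cmd == "run") {
  cfg_path <- opt("--config")
  if (is.null(cfg_path)) stop("run needs --config <yaml>")
  run <- run_analysis(cfg_path, out_dir)
} else {
  params_path <- opt("--params")
  params <- if (is.null(params_path)) list() else unclass(read_sn_params(params_path))
  stages <- switch(cmd,
    gradient = "gradient",
    singular = "singular",
    jacobian = c("singular", "jacobian"),
    hessian = c("singular", "hessian"),
    simulate = "simulate",
    stop("unknown subcommand: ", cmd))
  cfg <- list(
    params = params,
    stages = stages,
    v = num_vec(opt("--v", opt("--guess", "0.5,0.5"))),
    shared = has_flag("--shared"),
    seed = as.integer(opt("--seed", "1"))
  )
  if (cmd == "simulate") {
    cfg$sim <- list(duration = as.numeric(opt("--duration", "10000")),
                    K = if (!is.null(opt("--K"))) as.numeric(opt("--K")) else NULL,
                    dt = as.numeric(opt("--dt", "0.2")))
    cfg$sim <- cfg$sim[!vapply(cfg$sim, is.null, logical(1L))]
  }
  run <- run_analysis(cfg, out_dir)
}
print(run)
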
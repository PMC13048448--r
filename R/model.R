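# Declarative life-history models.
#
# A model declares, for each birth-assigned class j, the class-oriented
# fecundity rates f_ij (offspring of class i per unit time), the mortality
# rate mu_j, and the developmental rates g_j of the internal states, all as
# functions of the expressed traits z_j, the current states x_j and the
# resident-determined environment. The environment (densities, competition
# kernels, ...) is rebuilt from the resident allelic values by the model's
# `prepare` hook, reflecting that at a resident equilibrium every
# environmental variable is fully determined by the resident population.

#' Construct a life-history model
#'
#' Rate functions are vectorised over ages: they receive a state matrix `x`
#' with one row per age and `n_states` columns and must return a vector (or,
#' for `growth`, a matrix) with one value per row.
#'
#' @param n_classes number of birth-assigned classes.
#' @param n_traits number of evolving traits per class.
#' @param n_states number of internal state variables (age-independent).
#' @param fecundity `function(i, j, z, x, env)`: rate at which a class-`j`
#'   individual with expressed traits `z` (length `n_traits`) and states `x`
#'   produces class-`i` offspring.
#' @param mortality `function(j, z, x, env)`: mortality rate.
#' @param growth `function(j, z, x, env)`: rates of change of the internal
#'   states; returns a matrix `nrow(x) x n_states` (a vector is accepted when
#'   `n_states == 1`).
#' @param initial_states list (one numeric vector of length `n_states` per
#'   class) of states at birth; traits must not affect these.
#' @param genetics a [genetic_system()] supplying the transmission matrix and
#'   genetic exposures.
#' @param class_proportions optional `n_classes x n_classes` matrix `c_ij`
#'   with unit column sums: the proportion of class-`i` offspring among the
#'   offspring of class-`j` parents, when this proportion is constant
#'   (independent of age, state and traits). Enables the class-specific
#'   costate shortcut.
#' @param prepare optional `function(v, model)` returning the environment
#'   list consumed by the rate functions; defaults to `list(v = v)`.
#' @param class_names,trait_names labels used in reports.
#' @param trait_bounds length-2 numeric, admissible range of allelic values
#'   (analyses work at interior points; the lower bound is where
#'   boundary-pinned singular strategies are reported).
#' @return an object of class `life_history_model`.
#' @seealso [sexual_niche_model()] for the built-in worked example.
#' @export
life_history_model <- function(n_classes, n_traits, n_states,
                               fecundity, mortality, growth,
                               initial_states, genetics,
                               class_proportions = NULL,
                               prepare = NULL,
                               class_names = NULL, trait_names = NULL,
                               trait_bounds = c(0, Inf)) {
  stopifnot(n_classes >= 1L, n_traits >= 1L, n_states >= 1L,
            is.function(fecundity), is.function(mortality), is.function(growth),
            inherits(genetics, "genetic_system"))
  if (length(initial_states) != n_classes) {
    stop("`initial_states` must have one entry per class")
  }
  if (length(genetics$exposure) != n_classes) {
    stop("genetic system has ", length(genetics$exposure),
         " classes but the model declares ", n_classes)
  }
  if (!is.null(class_proportions)) {
    stopifnot(is.matrix(class_proportions),
              all(dim(class_proportions) == n_classes))
  }
  if (is.null(class_names)) class_names <- genetics$class_names
  if (is.null(trait_names)) trait_names <- paste0("z", seq_len(n_traits))
  model <- list(
    n_classes = as.integer(n_classes),
    n_traits = as.integer(n_traits),
    n_states = as.integer(n_states),
    fecundity = fecundity, mortality = mortality, growth = growth,
    initial_states = lapply(initial_states, as.numeric),
    genetics = genetics,
    class_proportions = class_proportions,
    prepare = if (is.null(prepare)) function(v, model) list(v = v) else prepare,
    class_names = class_names, trait_names = trait_names,
    trait_bounds = trait_bounds
  )
  class(model) <- "life_history_model"
  model
}

# Build the resident environment consumed by the rate functions.
prepare_env <- function(model, v) {
  env <- model$prepare(as_trait_matrix(v, model$n_classes), model)
  if (is.null(env$v)) env$v <- as_trait_matrix(v, model$n_classes)
  env
}

# flattened (class-major) indexing of the (class, trait) pairs
trait_labels <- function(model) {
  as.vector(t(outer(model$class_names, model$trait_names, paste, sep = ".")))
}

#' Validate a life-history model
#'
#' Structural checks on shapes and invariants: unit column sums of the class
#' proportions, non-negative fecundity and mortality at sampled trait/state
#' values, resident identity of the trait-expression map. Returns a report
#' rather than raising, so that all violations are seen at once.
#'
#' @param model a [life_history_model()].
#' @param v resident allelic values at which rates are sampled (matrix
#'   `n_classes x n_traits` or vector); defaults to midpoint-ish values of 0.5.
#' @return data frame with columns `check` and `message`; zero rows when the
#'   model passes.
#' @export
validate_model <- function(model, v = NULL) {
  bad <- list()
  note <- function(check, message) bad[[length(bad) + 1L]] <<- data.frame(check = check, message = message)
  if (is.null(v)) v <- matrix(0.5, model$n_classes, model$n_traits)
  v <- as_trait_matrix(v, model$n_classes)

  g <- model$genetics
  if (!all(dim(g$gamma) == model$n_classes)) {
    note("transmission", "gamma is not n_classes x n_classes")
  }
  if (!is.null(model$class_proportions)) {
    cs <- colSums(model$class_proportions)
    if (any(abs(cs - 1) > 1e-8)) {
      note("class_proportions", "class proportions not normalized (columns must sum to 1)")
    }
    if (any(model$class_proportions < 0 | model$class_proportions > 1)) {
      note("class_proportions", "class proportions outside [0, 1]")
    }
  }
  for (j in seq_len(model$n_classes)) {
    if (length(model$initial_states[[j]]) != model$n_states) {
      note("initial_states", paste0("class ", model$class_names[j],
                                    ": wrong number of initial states"))
    }
  }
  # resident identity z(v, v) = v at sampled allelic values
  for (vv in list(v, v * 0.37 + 0.01, v * 1.91 + 0.05)) {
    z <- express_traits(vv, vv, g)
    if (max(abs(z - vv)) > 1e-12) {
      note("trait_expression", "resident identity z(v, v) = v violated")
      break
    }
  }
  # rate signs at sampled points along the resident path
  rates_ok <- tryCatch({
    env <- prepare_env(model, v)
    # short fixed-horizon solve: rate-sign sampling must not depend on the
    # adaptive truncation (which assumes decaying survivorship)
    traj <- solve_resident(model, v, env = env, n_grid = 201L, a_max = 10)
    idx <- unique(round(seq(1L, length(traj$age), length.out = 9L)))
    for (j in seq_len(model$n_classes)) {
      x <- traj$states[[j]][idx, , drop = FALSE]
      zj <- v[j, ]
      mu <- model$mortality(j, zj, x, env)
      if (any(!is.finite(mu)) || any(mu < 0)) {
        note("mortality", paste0("negative or non-finite rate in class ", model$class_names[j]))
      }
      for (i in seq_len(model$n_classes)) {
        f <- model$fecundity(i, j, zj, x, env)
        if (any(!is.finite(f)) || any(f < 0)) {
          note("fecundity", paste0("negative or non-finite rate f[",
                                   model$class_names[i], ",", model$class_names[j], "]"))
        }
      }
      gr <- model$growth(j, zj, x, env)
      if (any(!is.finite(gr))) {
        note("growth", paste0("non-finite developmental rate in class ", model$class_names[j]))
      }
    }
    TRUE
  }, error = function(e) {
    note("structure", paste("model is not callable:", conditionMessage(e)))
    FALSE
  })
  invisible(rates_ok)
  if (length(bad) == 0L) {
    data.frame(check = character(), message = character())
  } else {
    do.call(rbind, bad)
  }
}

#' @export
print.life_history_model <- function(x, ...) {
  cat("<life_history_model>\n")
  cat(sprintf("  classes: %s | traits/class: %d | states: %d\n",
              paste(x$class_names, collapse = ", "), x$n_traits, x$n_states))
  cat("  genetics:", x$genetics$kind, "\n")
  if (!is.null(x$class_proportions)) {
    cat("  constant class proportions at birth (class-specific costates available)\n")
  }
  invisible(x)
}
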
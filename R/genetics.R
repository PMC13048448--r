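# Genetic systems: how allelic values map to expressed traits and how mutant
# allele copies are transmitted between classes.

#' Construct a genetic system
#'
#' A genetic system bundles (i) the transmission matrix `gamma`, whose (i, j)
#' element is the expected number of mutant allele copies a class-j parent
#' transmits per class-i offspring, and (ii) per-class genetic exposures
#' dz/du, the share of an individual's trait value contributed by one mutant
#' allele (1/2 in a diploid heterozygote under additive gene action and dosage
#' compensation, 1 in a haploid carrier).
#'
#' Built-in kinds:
#' \describe{
#'   \item{`diploid_two_sex`}{two classes (female, male), both diploid with
#'     full genetic mixing: all `gamma` entries 1/2, all exposures 1/2.}
#'   \item{`haplodiploid_two_sex`}{diploid females, haploid males
#'     (arrhenotoky): females transmit 1/2 to offspring of either sex, males
#'     transmit their single allele to every daughter and nothing to sons
#'     (`gamma[f,m] = 1`, `gamma[m,m] = 0`); male exposure is 1 under complete
#'     dosage compensation.}
#'   \item{`haploid_single_class`}{one clonal class, `gamma = 1`, exposure 1.}
#' }
#'
#' @param kind one of `"diploid_two_sex"`, `"haplodiploid_two_sex"`,
#'   `"haploid_single_class"`.
#' @param primary_sex_ratio proportion of males at birth, in (0, 1); used by
#'   two-sex kinds (it parameterises the class proportions the sexual-niche
#'   model attaches to the system).
#' @return an object of class `genetic_system`: a list with `kind`,
#'   `class_names`, `gamma`, `exposure`, `primary_sex_ratio`.
#' @examples
#' gs <- genetic_system("haplodiploid_two_sex", primary_sex_ratio = 0.5)
#' gs$gamma
#' @export
genetic_system <- function(kind = c("diploid_two_sex", "haplodiploid_two_sex",
                                    "haploid_single_class"),
                           primary_sex_ratio = 0.5) {
  kind <- match.arg(kind)
  if (kind != "haploid_single_class") {
    if (!is.numeric(primary_sex_ratio) || length(primary_sex_ratio) != 1L ||
        primary_sex_ratio <= 0 || primary_sex_ratio >= 1) {
      stop("`primary_sex_ratio` must be a single number in (0, 1)")
    }
  }
  sys <- switch(kind,
    diploid_two_sex = list(
      class_names = c("f", "m"),
      gamma = matrix(0.5, 2L, 2L),
      exposure = c(f = 0.5, m = 0.5)
    ),
    haplodiploid_two_sex = list(
      class_names = c("f", "m"),
      # rows: offspring class, cols: parent class
      gamma = matrix(c(0.5, 0.5, 1, 0), 2L, 2L),
      exposure = c(f = 0.5, m = 1)
    ),
    haploid_single_class = list(
      class_names = "h",
      gamma = matrix(1, 1L, 1L),
      exposure = c(h = 1)
    )
  )
  dimnames(sys$gamma) <- list(sys$class_names, sys$class_names)
  sys$kind <- kind
  sys$primary_sex_ratio <- if (kind == "haploid_single_class") NA_real_ else primary_sex_ratio
  class(sys) <- "genetic_system"
  sys
}

#' Express traits from mutant and resident allelic values
#'
#' Additive gene action: the expressed trait of a mutant carrier in class j is
#' `v + exposure_j * (u - v)`, i.e. the heterozygote midpoint under diploidy
#' and the mutant allelic value itself under haploidy. Residents satisfy
#' `express_traits(v, v, sys) == v` identically.
#'
#' @param u mutant allelic values, a matrix with one row per class (or a
#'   vector, one entry per class when there is a single trait).
#' @param v resident allelic values, same shape as `u`.
#' @param system a [genetic_system()]. A custom expression map (e.g. for
#'   polyploid classes or selfing) can be supplied as `system$express`, a
#'   `function(u, v)` operating on class-by-trait matrices; it must satisfy
#'   the resident identity `express(v, v) = v` and have `system$exposure` as
#'   its derivative in `u` at `u = v`.
#' @return expressed mutant trait values, same shape as `u`.
#' @export
express_traits <- function(u, v, system) {
  if (!identical(dim(u), dim(v)) || length(u) != length(v)) {
    stop("`u` and `v` must have the same shape")
  }
  nc <- length(system$exposure)
  um <- as_trait_matrix(u, nc)
  vm <- as_trait_matrix(v, nc)
  z <- if (is.function(system$express)) {
    system$express(um, vm)
  } else {
    vm + system$exposure * (um - vm)  # exposure recycles down rows (classes)
  }
  if (is.null(dim(u))) as.vector(z) else z
}

# coerce a per-class trait specification to an nc x nz matrix (rows = classes)
as_trait_matrix <- function(v, n_classes) {
  if (is.matrix(v)) {
    stopifnot(nrow(v) == n_classes)
    v
  } else {
    matrix(v, nrow = n_classes)
  }
}

#' @export
print.genetic_system <- function(x, ...) {
  cat("<genetic_system>", x$kind, "\n")
  cat("classes:", paste(x$class_names, collapse = ", "), "\n")
  cat("transmission gamma (offspring x parent):\n")
  print(x$gamma)
  cat("genetic exposure dz/du:", paste(sprintf("%s=%g", names(x$exposure), x$exposure),
                                       collapse = ", "), "\n")
  invisible(x)
}
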
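#' Disease model for the maximum credible allele frequency
#'
#' Bundles the epidemiological quantities from which a frequency ceiling for
#' a plausibly causative allele is derived: disease prevalence, the share of
#' disease attributable to the gene under study (genetic heterogeneity), the
#' share of that gene's cases attributable to a single allele (allelic
#' heterogeneity), the inheritance factor (0.5 for a heterozygous monoallelic
#' model, since a carrier contributes one of two alleles), and penetrance.
#'
#' The defaults describe craniosynostosis: a prevalence of ~1 in 2000 births,
#' a conservative penetrance of 0.2, a heterozygous dominant model, and
#' heterogeneity contributions whose product is 0.036, giving a maximum
#' credible allele frequency of 4.5e-5 (see [max_credible_af()]). The split
#' of the heterogeneity product into its two factors is provisional; only
#' their product enters the threshold.
#'
#' @param prevalence Disease prevalence, in (0, 1].
#' @param genetic_contribution Fraction of disease attributable to the gene,
#'   in (0, 1].
#' @param allelic_contribution Fraction of the gene's cases attributable to
#'   the most common single causative allele, in (0, 1].
#' @param inheritance_factor Fraction of carrier chromosomes bearing the
#'   allele; 0.5 for a monoallelic (heterozygous) model, in (0, 1].
#' @param penetrance Probability that a carrier manifests disease, in (0, 1].
#'
#' @return An object of class `disease_model` (a named list).
#' @seealso [max_credible_af()]
#' @export
#' @examples
#' disease_model()  # craniosynostosis defaults, threshold 4.5e-5
disease_model <- function(prevalence = 1 / 2000,
                          genetic_contribution = 0.12,
                          allelic_contribution = 0.30,
                          inheritance_factor = 0.5,
                          penetrance = 0.2) {
  model <- list(
    prevalence = prevalence,
    genetic_contribution = genetic_contribution,
    allelic_contribution = allelic_contribution,
    inheritance_factor = inheritance_factor,
    penetrance = penetrance
  )
  for (field in names(model)) {
    x <- model[[field]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x > 1) {
      stop("disease_model field '", field, "' must be a single number in (0, 1], got ",
           deparse(x), call. = FALSE)
    }
  }
  structure(model, class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat("Disease model (heterozygous dominant)\n")
  cat(sprintf("  prevalence:            %g\n", x$prevalence))
  cat(sprintf("  genetic contribution:  %g\n", x$genetic_contribution))
  cat(sprintf("  allelic contribution:  %g\n", x$allelic_contribution))
  cat(sprintf("  inheritance factor:    %g\n", x$inheritance_factor))
  cat(sprintf("  penetrance:            %g\n", x$penetrance))
  cat(sprintf("  max credible AF:       %g\n", max_credible_af(x)))
  invisible(x)
}

#' Maximum credible population allele frequency
#'
#' Frequency ceiling above which an allele is implausible as a cause of the
#' modelled disease: a truly causative allele cannot be more common in the
#' population than the disease it causes, after discounting for genetic and
#' allelic heterogeneity, inheritance model, and penetrance:
#'
#' \deqn{AF_{max credible} = prevalence \times genetic \times allelic
#'   \times inheritance / penetrance}
#'
#' The threshold is strictly increasing in prevalence and each heterogeneity
#' factor and strictly decreasing in penetrance: the lower the penetrance,
#' the more standing carriers a causative allele may have, so the higher the
#' frequency it can credibly reach.
#'
#' @param model A [disease_model()].
#' @return A single probability: the maximum credible allele frequency.
#' @export
#' @examples
#' max_credible_af(disease_model())  # 4.5e-05
max_credible_af <- function(model) {
  if (!inherits(model, "disease_model")) {
    model <- do.call(disease_model, as.list(model))
  }
  model$prevalence * model$genetic_contribution * model$allelic_contribution *
    model$inheritance_factor / model$penetrance
}
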
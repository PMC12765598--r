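#' Reference conditional-logistic estimates
#'
#' Published case-crossover conditional-logistic effect estimates for seven
#' large herbivore species (gemsbok, giraffe, kudu, mountain zebra,
#' springbok, black rhino, elephant) responding to short-term (0-6 h) and
#' delayed (6-24 h) lion and spotted hyena exposure in an arid-zone
#' camera-trap survey. One row per (species, predator, exposure window),
#' with the reported coefficient, standard error, odds ratio, 95% CI
#' bounds, p-value, number of event strata, concordance, and likelihood
#' ratio statistic. Rows affected by quasi-complete separation carry
#' non-finite entries as `NA`.
#'
#' Used to validate the odds-ratio arithmetic of [fit_clogit()]: the
#' exponentiated reported coefficients must reproduce the reported odds
#' ratios.
#'
#' @return Data frame with columns `species`, `predator`, `window`,
#'   `coef`, `se`, `or`, `ci_low`, `ci_high`, `p`, `n_events`,
#'   `concordance`, `lr_chisq`.
#' @export
reference_clogit_estimates <- function() {
  path <- system.file("extdata", "reference_clogit_estimates.csv",
                      package = "fearscape", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
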
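# Packaged example datasets (plain-text fixtures under inst/extdata).

#' Gastric-cancer survival times
#'
#' Survival times in years of 46 gastric-cancer patients given combined
#' chemotherapy and radiation treatment (Stablein et al.), a standard
#' benchmark for heavy-tailed lifetime models.
#'
#' @return Sorted numeric vector of 46 positive survival times.
#' @examples
#' range(gastric_cancer())
#' @export
gastric_cancer <- function() {
  path <- system.file("extdata", "gastric_cancer.csv", package = "wfrcens",
                      mustWork = TRUE)
  sort(utils::read.csv(path)$time)
}

#' Simulated progressively censored example sample
#'
#' A progressively type-II censored sample of m = 15 failures from n = 30
#' units, generated from the Weibull-Frechet distribution with parameters
#' (a, b, alpha, beta) = (0.5, 2.5, 0.96, 0.6) under the removal scheme
#' R = (7, 1, 2, 4, 1, 0, ..., 0), used throughout the worked examples.
#'
#' @return A [censored_sample].
#' @examples
#' simulated_example()
#' @export
simulated_example <- function() {
  path <- system.file("extdata", "simulated_censored.csv", package = "wfrcens",
                      mustWork = TRUE)
  read_sample(path)
}
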
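#' Study-cohort demographics
#'
#' The ten-patient demographics table of the source cohort (sex, age,
#' procedure), shipped with the package. All patients underwent thoracic or
#' lumbar spine surgery under sevoflurane.
#'
#' @return data.frame with columns patient, sex, age, procedure
#' @export
patientDemographics <- function() {
  read.csv(system.file("extdata", "demographics.csv", package = "ssepml"),
           stringsAsFactors = FALSE)
}

#' Demographic summary of the study cohort
#'
#' Mean age and population standard deviation (divisor n) of the cohort
#' ages, plus the sex split.
#'
#' @param demo demographics table, default [patientDemographics()]
#' @return list with `n`, `mean_age`, `sd_age` (population SD), `n_male`,
#'   `n_female`
#' @export
demographicsSummary <- function(demo = patientDemographics()) {
  ages <- demo$age
  n <- length(ages)
  list(n = n, mean_age = mean(ages),
       sd_age = sqrt(mean((ages - mean(ages))^2)),
       n_male = sum(demo$sex == "M"), n_female = sum(demo$sex == "F"))
}
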
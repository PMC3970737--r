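#' Published reference cohort summary
#'
#' Group means, standard errors and assay sample sizes of the murine
#' pulmonary-arterial-hypertension progression cohort that the shipped
#' presets are calibrated against (see [default_group_specs]): a normoxic
#' control group and 14-, 21- and 28-day hypoxia+SU5416 exposure groups.
#' These values serve as calibration targets and as the fixed inputs of
#' group-level correlation analyses (e.g. collagen content vs chamber
#' compliance across group means).
#'
#' @return data.frame with columns `field`, `group_label`, `mean`, `se`,
#'   `n_assay`; groups ordered normoxia, hysu14, hysu21, hysu28.
#' @export
reference_cohort <- function() {
  path <- system.file("extdata", "reference_cohort.csv", package = "pvloops")
  df <- utils::read.csv(path, comment.char = "#")
  df$group_label <- factor(df$group_label,
                           levels = c("normoxia", "hysu14", "hysu21", "hysu28"))
  df[order(df$field, df$group_label), ]
}

#' @rdname reference_cohort
#' @param field a field name present in the reference table.
#' @return `reference_field`: named vector of the four group means for one
#'   field, in group order.
#' @export
reference_field <- function(field) {
  df <- reference_cohort()
  df <- df[df$field == field, ]
  if (!nrow(df)) stopf("unknown reference field: %s", field)
  stats::setNames(df$mean, as.character(df$group_label))
}
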
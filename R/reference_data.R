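#' Published benchmark: prediction performance for 17 Miscanthus traits
#'
#' Reference values from a published genome-wide prediction study of 138
#' outbred *Miscanthus sinensis* genotypes (100 random 10-fold
#' cross-validations on RAD-Seq SNVs): broad-sense heritability, average
#' predictive ability and average accuracy for each of 17 field-trial
#' traits, for markers aligned to the *Sorghum bicolor* genome (`_sorg`)
#' and to a *Miscanthus* pseudo-reference (`_misc`). Used as the target
#' regime for the synthetic demonstration data (heritabilities span
#' 0.48-0.89) and for accuracy-identity checks.
#'
#' @return A tibble with columns `trait`, `category`, `h2`, `r_sorg`,
#'   `accu_sorg`, `r_misc`, `accu_misc`.
#' @export
reference_trait_performance <- function() {
  tibble::tribble(
    ~trait, ~category, ~h2, ~r_sorg, ~accu_sorg, ~r_misc, ~accu_misc,
    "DOYFS1.9",           "phenology",  0.89, 0.76, 0.81, 0.78, 0.82,
    "AvgeSen.9",          "phenology",  0.83, 0.64, 0.71, 0.64, 0.71,
    "BaseDiameter.9",     "morphology", 0.52, 0.27, 0.38, 0.29, 0.40,
    "DryMatter.9",        "morphology", 0.54, 0.06, 0.09, 0.04, 0.05,
    "LeafLength.7",       "morphology", 0.65, 0.67, 0.83, 0.66, 0.82,
    "LeafWidth.7",        "morphology", 0.64, 0.52, 0.65, 0.56, 0.70,
    "MaxCanopyHeight.9",  "morphology", 0.77, 0.35, 0.40, 0.34, 0.39,
    "Moisture.9",         "morphology", 0.59, 0.70, 0.92, 0.73, 0.95,
    "StatureCategory.7",  "morphology", 0.48, 0.39, 0.57, 0.43, 0.62,
    "StatureLeafAngle.7", "morphology", 0.50, 0.46, 0.65, 0.47, 0.66,
    "StatureStemAngle.7", "morphology", 0.48, 0.37, 0.53, 0.40, 0.58,
    "StemDiameter.9",     "morphology", 0.60, 0.51, 0.66, 0.50, 0.65,
    "TallestStem.9",      "morphology", 0.88, 0.65, 0.69, 0.63, 0.68,
    "TransectCount.9",    "morphology", 0.51, 0.17, 0.23, 0.27, 0.39,
    "Cellulose.8",        "cell_wall",  0.79, 0.62, 0.70, 0.61, 0.69,
    "Hemicellulose.8",    "cell_wall",  0.60, 0.25, 0.32, 0.18, 0.24,
    "Lignin.8",           "cell_wall",  0.66, 0.43, 0.53, 0.35, 0.43
  )
}
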
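#' Transcribed strand E aggregation outcomes
#'
#' The built-in variant-by-pH outcome matrix for the strand E
#' phospho-scanning series, transcribed from the plate-reader study the
#' package models:
#'
#' * pH 1.1 (phosphate fully protonated): all eight peptides form fibrils
#'   rapidly; mean t50 values are attached where determined (control
#'   0.367 s, p9Y 2.90 s; the double variant p3S10T shows too wide a
#'   spread of rates for a single t50).
#' * pH 3.6 (phosphate mono-anionic): position-dependent -- control
#'   (0.484 s), p13T, p10T, p9Y (74.77 s) and p3S aggregate; p5Y, p8Y and
#'   p3S10T form no fibrils within 4 days.
#' * pH 7.5 (phosphate di-anionic): only the control aggregates
#'   (10.59 s); every phosphovariant is fully inhibited.
#'
#' Non-aggregating entries are censored at the 4-day incubation endpoint
#' (`censored_at` = 345600 s) and carry no t50.
#'
#' @return An `outcome_matrix` data frame with columns `variant`, `pH`,
#'   `outcome`, `t50` (seconds, `NA` when undetermined) and `censored_at`.
#' @examples
#' oc <- strand_e_outcomes()
#' subset(oc, pH == 3.6 & outcome == "no_fibrils")$variant
#' @export
strand_e_outcomes <- function() {
  v <- c("control", "p13T", "p10T", "p9Y", "p8Y", "p5Y", "p3S", "p3S10T")
  four_days <- 4 * 24 * 3600
  df <- rbind(
    data.frame(variant = v, pH = 1.1, outcome = "fibrils",
               t50 = c(0.367, NA, NA, 2.90, NA, NA, NA, NA)),
    data.frame(variant = v, pH = 3.6,
               outcome = c("fibrils", "fibrils", "fibrils", "fibrils",
                           "no_fibrils", "no_fibrils", "fibrils", "no_fibrils"),
               t50 = c(0.484, NA, NA, 74.77, NA, NA, NA, NA)),
    data.frame(variant = v, pH = 7.5,
               outcome = c("fibrils", rep("no_fibrils", 7)),
               t50 = c(10.59, rep(NA, 7)))
  )
  df$censored_at <- ifelse(df$outcome == "no_fibrils", four_days, NA_real_)
  as_outcome_matrix(df)
}
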
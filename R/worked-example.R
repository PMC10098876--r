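#' Worked-example stage-wise summaries (reconstructed bipolar-relapse trial)
#'
#' Stage-wise summary statistics of a two-stage trial constructed from a
#' published randomized maintenance trial in bipolar I disorder (control
#' versus 24 and 52 weeks of adjunct atypical antipsychotic; endpoint time
#' to mood-episode relapse, survival times reconstructed from the published
#' Kaplan-Meier curves). Both experimental arms pass the interim rule "all
#' arms with one-sided pairwise p-value <= 0.2" and continue to stage 2.
#' The fixture is immutable: the quantities are fixed constants of the
#' package.
#'
#' @return a [stage_summaries] object for K = 2 arms, with the pooled
#'   stage-1 estimate attached; attributes `a` (p-value threshold 0.2) and
#'   `w` (shrinkage weight 0.5).
#' @export
worked_example_summaries <- function() {
  sm <- stage_summaries(theta1 = c(-0.5284, -0.5327),
                        V1 = c(8.0705, 8.7239),
                        theta_full = c(-0.6528, -0.5796),
                        V_full = c(16.6260, 16.7495),
                        q = 0.0522,
                        theta1_all = -0.5809)
  attr(sm, "a") <- 0.2
  attr(sm, "w") <- 0.5
  sm
}

#' Run the packaged worked example
#'
#' Computes all five estimators for both selected arms of the packaged
#' worked-example summaries ([worked_example_summaries]) under the rule
#' "all arms with one-sided pairwise p-value <= 0.2", with shrinkage weight
#' 0.5 and the prior variance estimated from the data (which truncates to
#' zero here, i.e. complete shrinkage to the pooled stage-1 estimate).
#'
#' @return a [selest] fit.
#' @examples
#' run_worked_example()
#' @export
run_worked_example <- function() {
  sm <- worked_example_summaries()
  selest(sm, selection_rule("all_pval_le_a", a = attr(sm, "a")),
         w = attr(sm, "w"), nu2 = "estimate")
}
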
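#' Bundled reference tables from a published post-mortem HD cohort
#'
#' Small worked-example tables shipped with the package, taken from a
#' published mRNA-seq study of human HD prefrontal cortex (Brodmann area
#' 9; 20 HD cases vs 49 neuropathologically normal controls, all male):
#' the twenty top differentially expressed genes ranked by significance,
#' the twenty top genes ranked by the Differential Expression Score, and
#' the per-sample clinical/technical covariates for both groups. They are
#' used throughout the test suite as fixed worked examples for the DES
#' formula and the clinical-covariate schema; they are reference values,
#' not simulated data.
#'
#' @param which one of `"de_by_significance"`, `"de_by_des"`,
#'   `"case_samples"`, `"control_samples"`.
#' @return data frame. DE tables carry columns `gene_id`, `symbol`,
#'   `overall_mean`, `case_mean`, `control_mean`, `lfc` (log2 fold change
#'   HD vs control), `p`, `padj` and the published `des` column; sample
#'   tables carry post-mortem interval (`pmi`, hours; may be missing),
#'   `age_of_death`, `rin`, library `reads` and, for cases, `onset`,
#'   `duration`, `cag`, `vonsattel_grade` and the Hadzi-Vonsattel
#'   `hv_striatal` / `hv_cortical` involvement scores.
#' @export
reference_table <- function(which = c("de_by_significance", "de_by_des",
                                      "case_samples", "control_samples")) {
  which <- match.arg(which)
  file <- switch(which,
                 de_by_significance = "hd_ba9_top_de_by_significance.tsv",
                 de_by_des = "hd_ba9_top_de_by_des.tsv",
                 case_samples = "hd_ba9_case_samples.tsv",
                 control_samples = "hd_ba9_control_samples.tsv")
  path <- system.file("extdata", file, package = "desweep", mustWork = TRUE)
  read_tsv(path)
}
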
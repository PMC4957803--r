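#' Published miR-155 target-screen summary table
#'
#' The 18 candidate miR-155 targets reported for inflammatory (M1)
#' macrophages: genes repressed in WT M1 activation and re-induced at
#' least 2-fold in KO-M1 vs WT-M1, with their Pearson correlation against
#' miR-155 expression (`r`, `p_r`) and fold change / p-value pairs for the
#' three screen contrasts (WT-M1 vs WT-M0, KO-M1 vs WT-M1, KO-M1 vs
#' KO-M0). Ships with the package as a worked example for
#' [build_target_report()].
#'
#' @return data.frame with the [build_target_report()] input columns.
#' @export
published_target_screen <- function() {
  path <- system.file("extdata", "mir155_target_screen.tsv",
                      package = "mirdep", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
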
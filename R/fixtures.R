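# Bundled worked-example data: the splice-screening metrics of the four
# diagnostic variants (MED12, CCDC22, TMEM67, CASK) from the motivating
# congenital-anomaly trio-WES cohort, and the LOEUF scores of its three
# X-linked disease genes. Small curated tables used in examples, tests and
# the analysis scripts.

#' Worked-example splice-screening metrics
#'
#' Per-variant screening metrics of the four diagnostic variants the
#' stepwise reanalysis is designed to recover: SpliceAI delta scores with
#' pre-mRNA positions, Pangolin gain/loss scores, maximum-entropy
#' splice-motif scores for the reference and alternate alleles, gnomAD minor
#' allele frequency (0 for all four), region and intron offset.
#'
#' @return A data frame, one row per variant (MED12, CCDC22, TMEM67, CASK).
#' @export
#' @examples
#' m <- worked_example_metrics()
#' percent_motif_variation(m$maxent_ref, m$maxent_alt)
worked_example_metrics <- function() {
  path <- system.file("extdata", "worked_example_splice_metrics.tsv",
                      package = "triosplice", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$intron_offset <- as.integer(tab$intron_offset)
  tab
}

#' X-linked disease-gene constraint fixture
#'
#' LOEUF scores of the three X-linked disease genes identified by the
#' reanalysis (MED12 0.071, CCDC22 0.123, CASK 0.073) with their inheritance
#' modes — all well below the 0.35 constraint gate, and below 0.2,
#' illustrating the strong intolerance of X-linked disease genes that makes
#' the constraint-driven steps productive on chrX.
#'
#' @return A constraint table (see [read_annotation_table()]).
#' @export
xlinked_constraint_fixture <- function() {
  path <- system.file("extdata", "xlinked_constraint.tsv",
                      package = "triosplice", mustWork = TRUE)
  read_annotation_table(path, "constraint")
}
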
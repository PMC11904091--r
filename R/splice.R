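# Splice screening: the near-exon intronic window, SpliceAI delta-score
# thresholding, maximum-entropy motif score change, and rule-based
# splice-consequence inference.

#' Build a one-row SpliceAI score record
#'
#' Convenience constructor for the four delta scores (acceptor gain/loss,
#' donor gain/loss, each in \[0, 1\]) and their pre-mRNA positions, plus
#' optional Pangolin deltas.
#'
#' @param ag,al,dg,dl SpliceAI delta scores (acceptor gain, acceptor loss,
#'   donor gain, donor loss).
#' @param ag_pos,al_pos,dg_pos,dl_pos Signed positions relative to the
#'   variant (pre-mRNA), meaningful only when the matching delta is > 0.
#' @param pangolin_gain,pangolin_loss Optional Pangolin splice gain/loss
#'   scores with positions `pangolin_gain_pos`, `pangolin_loss_pos`.
#' @param pangolin_gain_pos,pangolin_loss_pos Signed Pangolin positions.
#' @return A one-row data frame with the splice-score columns.
#' @export
splice_scores <- function(ag = 0, al = 0, dg = 0, dl = 0,
                          ag_pos = NA, al_pos = NA, dg_pos = NA, dl_pos = NA,
                          pangolin_gain = NA, pangolin_gain_pos = NA,
                          pangolin_loss = NA, pangolin_loss_pos = NA) {
  ds <- c(ag, al, dg, dl)
  if (any(!is.na(ds) & (ds < 0 | ds > 1))) {
    stop("SpliceAI delta scores must lie in [0, 1]")
  }
  data.frame(ds_ag = ag, ds_al = al, ds_dg = dg, ds_dl = dl,
             dp_ag = as.integer(ag_pos), dp_al = as.integer(al_pos),
             dp_dg = as.integer(dg_pos), dp_dl = as.integer(dl_pos),
             pangolin_gain = as.numeric(pangolin_gain),
             pangolin_gain_pos = as.integer(pangolin_gain_pos),
             pangolin_loss = as.numeric(pangolin_loss),
             pangolin_loss_pos = as.integer(pangolin_loss_pos),
             stringsAsFactors = FALSE)
}

#' Maximum SpliceAI delta score
#'
#' The screening aggregate: the maximum of the four delta scores (acceptor
#' gain/loss, donor gain/loss). Missing components count as 0; a record with
#' no scores at all yields `NA`.
#'
#' @param scores A data frame with `ds_ag`, `ds_al`, `ds_dg`, `ds_dl`
#'   columns (e.g. [splice_scores()] or a trio-variant table).
#' @return Numeric vector, one value per row.
#' @export
max_delta <- function(scores) {
  ds <- cbind(scores$ds_ag, scores$ds_al, scores$ds_dg, scores$ds_dl)
  all_na <- rowSums(!is.na(ds)) == 0L
  out <- do.call(pmax, c(as.data.frame(ds), na.rm = TRUE))
  out[all_na] <- NA_real_
  out
}

#' Is an intron offset within the screening window?
#'
#' The reanalysis screens intronic variants up to a fixed distance from the
#' exon-intron boundary (default 150 bp on each side). Exonic positions
#' (offset `NA`) are always in scope.
#'
#' @param offset Signed intron offsets (`NA` = exonic).
#' @param window_bp Positive window size in bp (default 150).
#' @return Logical vector.
#' @export
in_window <- function(offset, window_bp = 150) {
  stopifnot(is.numeric(window_bp), length(window_bp) == 1L, window_bp > 0)
  is.na(offset) | abs(offset) <= window_bp
}

#' Percent variation of a splice-motif score
#'
#' Relative change of the maximum-entropy splice-motif score caused by the
#' variant: `100 * (alt - ref) / |ref|`, reported to two decimals. The
#' absolute-value denominator keeps the sign meaningful when the reference
#' motif score is negative (motif scores are log-odds and may be negative).
#'
#' @param ref_score,alt_score Numeric vectors of motif scores for the
#'   reference and alternate alleles; `ref_score` must be nonzero.
#' @return Numeric vector of percent changes (2 decimals).
#' @export
#' @examples
#' percent_motif_variation(9.5, 1.43)   # -84.95
#' percent_motif_variation(5.96, -1.06) # -117.79
percent_motif_variation <- function(ref_score, alt_score) {
  if (any(!is.na(ref_score) & ref_score == 0)) {
    stop("percent_motif_variation: reference motif score of 0 is undefined")
  }
  round(100 * (alt_score - ref_score) / abs(ref_score), 2)
}

#' Infer the splicing consequence of a variant
#'
#' Rule-based interpretation of the dominant SpliceAI event (the delta type
#' with the largest score) in the light of the variant's intron offset:
#' \itemize{
#'   \item donor loss at a donor-proximal offset (`offset > 0`) predicts
#'     intron retention — the weakened donor is read through;
#'   \item an acceptor gain in the intron upstream of the canonical acceptor
#'     (`offset <= -2`) where the variant supplies the G of a novel AG
#'     acceptor dinucleotide predicts an exon extension of `|offset| - 1` bp
#'     (the intronic bases between the novel and the canonical acceptor are
#'     incorporated into the transcript);
#'   \item all other geometries return `unknown` rather than guessing.
#' }
#' Delta ties resolve in the fixed order acceptor gain, acceptor loss,
#' donor gain, donor loss.
#'
#' @param intron_offset Signed intron offset (`NA` = exonic).
#' @param scores A one-row data frame with `ds_ag`, `ds_al`, `ds_dg`,
#'   `ds_dl` (e.g. [splice_scores()]).
#' @param alt Alternate allele (used for the novel-acceptor dinucleotide
#'   check; `NA` disables the exon-extension call).
#' @return A list with `event` (`acceptor_gain`, `acceptor_loss`,
#'   `donor_gain`, `donor_loss`, `none`), `predicted_effect`
#'   (`intron_retention`, `exon_extension`, `exon_truncation`,
#'   `exon_skipping_possible`, `unknown`) and `affected_length_bp`
#'   (integer, `NA` unless the effect is an extension/truncation).
#' @export
#' @examples
#' infer_consequence(-6, splice_scores(ag = 0.9, al = 0.13), alt = "G")
infer_consequence <- function(intron_offset, scores, alt = NA_character_) {
  ds <- c(acceptor_gain = scores$ds_ag[1L], acceptor_loss = scores$ds_al[1L],
          donor_gain = scores$ds_dg[1L], donor_loss = scores$ds_dl[1L])
  ds[is.na(ds)] <- 0
  if (max(ds) < .Machine$double.eps) {
    return(list(event = "none", predicted_effect = "unknown",
                affected_length_bp = NA_integer_))
  }
  event <- names(ds)[which.max(ds)]
  offset <- intron_offset[1L]
  effect <- "unknown"
  len <- NA_integer_
  if (event == "donor_loss" && !is.na(offset) && offset > 0) {
    effect <- "intron_retention"
  } else if (event == "acceptor_gain" && !is.na(offset) && offset <= -2 &&
             !is.na(alt) && toupper(alt) == "G") {
    effect <- "exon_extension"
    len <- abs(offset) - 1L
  }
  list(event = event, predicted_effect = effect, affected_length_bp = len)
}

#' Add splice-consequence columns to a variant table
#'
#' Applies [infer_consequence()] row-wise, filling `splice_event`,
#' `predicted_effect` and `affected_length_bp`.
#'
#' @param variants A trio-variant table with splice-score columns.
#' @return The table with three consequence columns added.
#' @export
infer_consequences <- function(variants) {
  n <- nrow(variants)
  variants$splice_event <- rep(NA_character_, n)
  variants$predicted_effect <- rep(NA_character_, n)
  variants$affected_length_bp <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    res <- infer_consequence(variants$intron_offset[i], variants[i, ],
                             variants$alt[i])
    variants$splice_event[i] <- res$event
    variants$predicted_effect[i] <- res$predicted_effect
    variants$affected_length_bp[i] <- res$affected_length_bp
  }
  variants
}

#' Screen variants for splicing relevance
#'
#' A variant passes when it lies inside the screening window and is either
#' exonic / at a canonical splice site (always evaluated) or intronic with a
#' maximum SpliceAI delta above the threshold. Evidence tags record which
#' clause fired; intronic variants failing the SpliceAI threshold but with a
#' Pangolin gain or loss above it are tagged `pangolin_rescue` (Pangolin
#' never gates, it only annotates the disagreement between the two tools).
#'
#' @param variants A trio-variant table with `region`, `intron_offset` and
#'   splice-score columns.
#' @param delta_threshold SpliceAI delta threshold (default 0.2; the screen
#'   requires a delta strictly greater).
#' @param window_bp Screening window per boundary in bp (default 150).
#' @return A data frame with logical `pass` and character `tags`
#'   (comma-separated), one row per variant.
#' @export
screen_variants <- function(variants, delta_threshold = 0.2, window_bp = 150) {
  stopifnot(delta_threshold > 0)
  n <- nrow(variants)
  if (!n) {
    return(data.frame(pass = logical(0), tags = character(0),
                      stringsAsFactors = FALSE))
  }
  windowed <- in_window(variants$intron_offset, window_bp)
  exon_like <- !is.na(variants$region) &
    variants$region %in% c("exonic", "canonical_splice_site")
  md <- max_delta(variants)
  delta_hit <- !is.na(md) & md > delta_threshold
  pang <- pmax(variants$pangolin_gain, variants$pangolin_loss, na.rm = TRUE)
  pang[is.na(variants$pangolin_gain) & is.na(variants$pangolin_loss)] <- NA_real_
  pass <- windowed & (exon_like | delta_hit)
  tags <- vapply(seq_len(n), function(i) {
    t <- character(0)
    if (!windowed[i]) t <- c(t, "out_of_window")
    if (exon_like[i]) t <- c(t, paste0("region_", variants$region[i]))
    if (delta_hit[i]) t <- c(t, "spliceai_delta")
    if (!delta_hit[i] && !is.na(pang[i]) && pang[i] > delta_threshold) {
      t <- c(t, "pangolin_rescue")
    }
    paste(t, collapse = ",")
  }, "")
  data.frame(pass = pass, tags = tags, stringsAsFactors = FALSE)
}
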
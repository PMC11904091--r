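# Shared fixture builders: everything is constructed in code at test time.

make_trio <- function(sex = "male", family = "FAM1") {
  trio_pedigree("P1", "M1", "F1", proband_sex = sex, family_id = family)
}

# One-row trio-variant table with sensible defaults.
mk_var <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                   gt_proband = "het", gt_mother = "hom_ref",
                   gt_father = "hom_ref", af = NA_real_,
                   gene = NA_character_, region = NA_character_,
                   intron_offset = NA_integer_,
                   ds_ag = NA_real_, ds_al = NA_real_,
                   ds_dg = NA_real_, ds_dl = NA_real_,
                   pangolin_gain = NA_real_, pangolin_loss = NA_real_,
                   maxent_ref = NA_real_, maxent_alt = NA_real_) {
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                   gt_proband = gt_proband, gt_mother = gt_mother,
                   gt_father = gt_father, af = af, gene = gene,
                   region = region, intron_offset = as.integer(intron_offset),
                   ds_ag = ds_ag, ds_al = ds_al, ds_dg = ds_dg, ds_dl = ds_dl,
                   pangolin_gain = pangolin_gain, pangolin_loss = pangolin_loss,
                   maxent_ref = maxent_ref, maxent_alt = maxent_alt,
                   stringsAsFactors = FALSE)
  triosplice:::as_variant_table(df)
}

mk_vars <- function(...) {
  do.call(rbind, list(...))
}

# Two-exon plus-strand toy model: exon1 [1000,1200), exon2 [2000,2200).
toy_model <- function(strand = "+", gene = "TOY") {
  gene_model(gene, paste0(gene, ".t1"), "chr1", strand,
             rbind(c(1000, 1200), c(2000, 2200)))
}

# Minimal constraint table.
mk_constraint <- function(gene, chrom, loeuf, modes) {
  data.frame(gene = gene, chrom = chrom, loeuf = loeuf, modes = modes,
             chrom_class = ifelse(toupper(sub("chr", "", chrom)) == "X",
                                  "chrX", "autosome"),
             stringsAsFactors = FALSE)
}

# Independent brute-force compound-het oracle: enumerate unordered het pairs
# and test opposite-parent transmissibility directly.
brute_force_comphet <- function(variants) {
  carr <- c("het", "hom_alt", "hemi_alt")
  hets <- which(variants$gt_proband == "het")
  out <- list()
  if (length(hets) >= 2L) {
    for (a in seq_len(length(hets) - 1L)) {
      for (b in seq(a + 1L, length(hets))) {
        i <- hets[a]; j <- hets[b]
        if (variants$pos[i] == variants$pos[j]) next
        mi <- variants$gt_mother[i] %in% carr
        fi <- variants$gt_father[i] %in% carr
        mj <- variants$gt_mother[j] %in% carr
        fj <- variants$gt_father[j] %in% carr
        if ((mi && fj) || (mj && fi)) {
          k <- sort(c(variant_key(variants[i, ]), variant_key(variants[j, ])))
          out[[length(out) + 1L]] <- data.frame(
            pair = paste(k, collapse = "+"),
            ambiguous = (mi && fi) || (mj && fj),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(pair = character(0), ambiguous = logical(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$pair), , drop = FALSE]
}

# Textbook Welch formula, independent of stats::t.test.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}
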
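# Trio inheritance classification: a total, deterministic decision table over
# (chromosome class, proband sex, trio genotypes). Genotype-only logic, no
# allele depths or mosaicism modelling, matching how trio filtering is done in
# practice for congenital-anomaly exomes.

INHERITANCE_MODELS <- c(
  "de_novo_autosomal", "de_novo_x",
  "inherited_maternal_het", "inherited_paternal_het",
  "autosomal_recessive_hom", "x_recessive_hom",
  "x_hemizygous_de_novo", "x_hemizygous_maternal",
  "mendelian_error", "unclassifiable"
)

CARRIER_GENOTYPES <- c("het", "hom_alt", "hemi_alt")

call_ <- function(model, confidence = "certain") {
  c(model = model, phase_confidence = confidence)
}

# chrX coercions for male samples whose caller emitted diploid genotypes.
male_x_gt <- function(g) {
  switch(g, hom_ref = "hemi_ref", hom_alt = "hemi_alt", g)
}

classify_one <- function(p, m, f, chrom, sex) {
  if (is_chry_or_mt(chrom)) return(call_("unclassifiable"))
  if (any(c(p, m, f) == "missing")) return(call_("unclassifiable", "ambiguous"))
  if (!is_chrx(chrom)) {
    # autosome: haploid genotypes are anomalous
    if (any(c(p, m, f) %in% c("hemi_ref", "hemi_alt"))) {
      return(call_("unclassifiable"))
    }
    mc <- m %in% CARRIER_GENOTYPES
    fc <- f %in% CARRIER_GENOTYPES
    if (p == "hom_ref") {
      if (m == "hom_alt" || f == "hom_alt") return(call_("mendelian_error"))
      return(call_("unclassifiable"))  # non-carrier
    }
    if (p == "het") {
      if (m == "hom_alt" && f == "hom_alt") return(call_("mendelian_error"))
      if (!mc && !fc) return(call_("de_novo_autosomal"))
      if (mc && !fc) return(call_("inherited_maternal_het"))
      if (fc && !mc) return(call_("inherited_paternal_het"))
      return(call_("unclassifiable", "ambiguous"))  # transmitting parent unknown
    }
    # p == hom_alt: one alt allele required from each parent
    if (!mc || !fc) return(call_("mendelian_error"))
    return(call_("autosomal_recessive_hom"))
  }
  # chrX
  if (sex == "unknown") return(call_("unclassifiable"))
  if (m %in% c("hemi_ref", "hemi_alt")) return(call_("unclassifiable"))
  f <- male_x_gt(f)
  if (sex == "male") {
    p <- male_x_gt(p)
    if (!p %in% c("hemi_ref", "hemi_alt")) return(call_("unclassifiable"))
    # the son's X comes from the mother; the father's genotype is irrelevant
    if (p == "hemi_ref") {
      if (m == "hom_alt") return(call_("mendelian_error"))
      return(call_("unclassifiable"))
    }
    if (m %in% CARRIER_GENOTYPES) return(call_("x_hemizygous_maternal"))
    return(call_("x_hemizygous_de_novo"))
  }
  # female proband: diploid X, father contributes his single X
  if (p %in% c("hemi_ref", "hemi_alt")) return(call_("unclassifiable"))
  if (f == "het") return(call_("unclassifiable"))  # anomalous diploid-het father
  mc <- m %in% CARRIER_GENOTYPES
  fc <- f == "hemi_alt"
  if (p == "hom_ref") {
    if (m == "hom_alt" || fc) return(call_("mendelian_error"))
    return(call_("unclassifiable"))
  }
  if (p == "het") {
    if (m == "hom_alt" && fc) return(call_("mendelian_error"))
    if (!mc && !fc) return(call_("de_novo_x"))
    if (mc && !fc) return(call_("inherited_maternal_het"))
    if (fc && !mc) return(call_("inherited_paternal_het"))
    return(call_("unclassifiable", "ambiguous"))
  }
  # p == hom_alt
  if (!mc || !fc) return(call_("mendelian_error"))
  call_("x_recessive_hom")
}

#' Classify trio genotype combinations into inheritance models
#'
#' Vectorized, total decision table over (proband, mother, father) genotype
#' enums, chromosome and proband sex. De novo calls require both parents
#' hom-ref (or, on chrX for a male proband, mother hom-ref — the son's X is
#' maternal). Mendelian errors are genotype combinations impossible under
#' biparental transmission (e.g. a hom-alt proband with a hom-ref parent on
#' an autosome). A heterozygous proband whose variant is carried by both
#' parents cannot be phased by transmission and is `unclassifiable` with
#' `phase_confidence = "ambiguous"`. chrY and mitochondrial records, missing
#' genotypes, unknown proband sex on chrX, and anomalous ploidy all map to
#' `unclassifiable`.
#'
#' @param gt_proband,gt_mother,gt_father Character vectors of genotype enums
#'   (`hom_ref`, `het`, `hom_alt`, `hemi_ref`, `hemi_alt`, `missing`).
#' @param chrom Chromosome names (recycled).
#' @param proband_sex `"male"`, `"female"` or `"unknown"` (scalar).
#' @return A data frame with columns `model` and `phase_confidence`.
#' @export
#' @examples
#' classify_genotypes("hemi_alt", "hom_ref", "hemi_ref", "chrX", "male")
classify_genotypes <- function(gt_proband, gt_mother, gt_father, chrom,
                               proband_sex = "unknown") {
  n <- max(length(gt_proband), length(gt_mother), length(gt_father),
           length(chrom))
  gt_proband <- rep_len(gt_proband, n)
  gt_mother <- rep_len(gt_mother, n)
  gt_father <- rep_len(gt_father, n)
  chrom <- rep_len(chrom, n)
  out <- t(vapply(seq_len(n), function(i) {
    classify_one(gt_proband[i], gt_mother[i], gt_father[i], chrom[i],
                 proband_sex)
  }, c(model = "", phase_confidence = "")))
  data.frame(model = unname(out[, "model"]),
             phase_confidence = unname(out[, "phase_confidence"]),
             stringsAsFactors = FALSE)
}

#' Classify a single variant's trio inheritance
#'
#' @param variant A one-row trio-variant table (or list with `gt_proband`,
#'   `gt_mother`, `gt_father`, `chrom`).
#' @param pedigree A [trio_pedigree()].
#' @return A list with `model` and `phase_confidence`.
#' @seealso [classify_genotypes()] for the vectorized decision table.
#' @export
classify_trio_genotype <- function(variant, pedigree) {
  stopifnot(inherits(pedigree, "trio_pedigree"))
  res <- classify_genotypes(variant$gt_proband[1L], variant$gt_mother[1L],
                            variant$gt_father[1L], variant$chrom[1L],
                            pedigree$proband_sex)
  as.list(res[1L, ])
}

#' Add inheritance calls to a trio-variant table
#'
#' @param variants A trio-variant table.
#' @param pedigree A [trio_pedigree()].
#' @return The table with `inheritance` and `phase_confidence` columns.
#' @export
classify_variants <- function(variants, pedigree) {
  stopifnot(inherits(pedigree, "trio_pedigree"))
  if (!nrow(variants)) {
    variants$inheritance <- character(0)
    variants$phase_confidence <- character(0)
    return(variants)
  }
  res <- classify_genotypes(variants$gt_proband, variants$gt_mother,
                            variants$gt_father, variants$chrom,
                            pedigree$proband_sex)
  variants$inheritance <- res$model
  variants$phase_confidence <- res$phase_confidence
  variants
}

#' Detect compound-heterozygous variant pairs in one gene
#'
#' Phasing is by parental transmission only: a pair is emitted when one
#' heterozygous proband variant can be assigned to the mother and the other
#' to the father (trans configuration). A variant carried by both parents
#' cannot be phased unambiguously; pairs involving such a variant are kept
#' with `ambiguity_flag = TRUE` rather than discarded. Two variants
#' transmitted by the same single parent are cis-by-transmission and never
#' paired; de novo heterozygotes (carried by neither parent) do not pair.
#'
#' @param variants A trio-variant table whose rows share one gene symbol;
#'   only rows with a heterozygous proband are considered.
#' @param pedigree A [trio_pedigree()] (reserved for interface symmetry; the
#'   genotype columns already encode the trio).
#' @return A data frame with one row per pair: `gene`, maternal and paternal
#'   variant keys and positions, `ambiguity_flag`; ordered by genomic
#'   position.
#' @export
detect_compound_het <- function(variants, pedigree) {
  empty <- data.frame(gene = character(0),
                      maternal_key = character(0), maternal_pos = integer(0),
                      paternal_key = character(0), paternal_pos = integer(0),
                      ambiguity_flag = logical(0), stringsAsFactors = FALSE)
  v <- variants[variants$gt_proband == "het", , drop = FALSE]
  if (nrow(v) < 2L) return(empty)
  genes <- unique(v$gene[!is.na(v$gene)])
  if (length(genes) > 1L) {
    stop("detect_compound_het expects variants from a single gene; got ",
         paste(genes, collapse = ", "))
  }
  keys <- variant_key(v)
  mc <- v$gt_mother %in% CARRIER_GENOTYPES
  fc <- v$gt_father %in% CARRIER_GENOTYPES
  pairs <- list()
  for (i in seq_len(nrow(v) - 1L)) {
    for (j in seq(i + 1L, nrow(v))) {
      if (v$pos[i] == v$pos[j]) next
      i_mat_j_pat <- mc[i] && fc[j]
      j_mat_i_pat <- mc[j] && fc[i]
      if (!i_mat_j_pat && !j_mat_i_pat) next
      mat <- if (i_mat_j_pat) i else j
      pat <- if (i_mat_j_pat) j else i
      ambiguous <- (mc[i] && fc[i]) || (mc[j] && fc[j])
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene = if (length(genes)) genes else NA_character_,
        maternal_key = keys[mat], maternal_pos = v$pos[mat],
        paternal_key = keys[pat], paternal_pos = v$pos[pat],
        ambiguity_flag = ambiguous, stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs)) return(empty)
  out <- do.call(rbind, pairs)
  out <- out[order(pmin(out$maternal_pos, out$paternal_pos),
                   pmax(out$maternal_pos, out$paternal_pos)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mendelian-error rate of a variant set
#'
#' Fraction of classifiable variants (inheritance model other than
#' `unclassifiable`) whose trio genotypes are impossible under biparental
#' transmission. A basic QC metric for called trios and for the synthetic
#' generator's planted error rate.
#'
#' @param variants A non-empty trio-variant table.
#' @param pedigree A [trio_pedigree()].
#' @return A fraction in \[0, 1\] (`NA` if no variant is classifiable).
#' @export
mendelian_error_rate <- function(variants, pedigree) {
  if (!nrow(variants)) stop("mendelian_error_rate: empty variant set")
  calls <- classify_variants(variants, pedigree)$inheritance
  classifiable <- calls != "unclassifiable"
  if (!any(classifiable)) {
    warning("no classifiable variants")
    return(NA_real_)
  }
  mean(calls[classifiable] == "mendelian_error")
}
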
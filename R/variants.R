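# Internal representation: one normalized variant per row (single ALT after
# multiallelic splitting), trio genotypes as enums, splice annotations flat.

GENOTYPE_LEVELS <- c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt", "missing")
REGION_LEVELS <- c("exonic", "canonical_splice_site", "intronic", "intergenic")

VARIANT_COLUMNS <- c(
  chrom = "character", pos = "integer", ref = "character", alt = "character",
  gene = "character", transcript = "character",
  region = "character", intron_offset = "integer",
  gt_proband = "character", gt_mother = "character", gt_father = "character",
  af = "numeric",
  ds_ag = "numeric", ds_al = "numeric", ds_dg = "numeric", ds_dl = "numeric",
  dp_ag = "integer", dp_al = "integer", dp_dg = "integer", dp_dl = "integer",
  pangolin_gain = "numeric", pangolin_gain_pos = "integer",
  pangolin_loss = "numeric", pangolin_loss_pos = "integer",
  maxent_ref = "numeric", maxent_alt = "numeric",
  info = "character"
)

#' Empty trio-variant table
#'
#' Returns a zero-row data frame with the full trio-variant column layout used
#' throughout the package (coordinates, trio genotypes, population allele
#' frequency, SpliceAI deltas and positions, Pangolin deltas, splice-motif
#' scores, raw INFO pass-through).
#'
#' @return A zero-row `data.frame`.
#' @export
empty_variant_table <- function() {
  cols <- lapply(VARIANT_COLUMNS, function(cl) vector(cl, 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

# Fill missing columns with NA of the right type and order canonically.
as_variant_table <- function(df) {
  n <- nrow(df)
  for (nm in names(VARIANT_COLUMNS)) {
    if (is.null(df[[nm]])) {
      df[[nm]] <- vector(VARIANT_COLUMNS[[nm]], 1L)[NA][rep(1L, n)]
    }
  }
  extra <- setdiff(names(df), names(VARIANT_COLUMNS))
  df <- df[, c(names(VARIANT_COLUMNS), extra), drop = FALSE]
  df$pos <- as.integer(df$pos)
  df$intron_offset <- as.integer(df$intron_offset)
  rownames(df) <- NULL
  df
}

#' Variant key
#'
#' Canonical `chrom:pos:ref:alt` identifier used for deduplication, step
#' exclusivity, and truth-table lookups.
#'
#' @param variants A trio-variant table.
#' @return Character vector of keys.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

is_chrx <- function(chrom) {
  toupper(sub("^chr", "", chrom, ignore.case = TRUE)) == "X"
}

is_chry_or_mt <- function(chrom) {
  toupper(sub("^chr", "", chrom, ignore.case = TRUE)) %in% c("Y", "M", "MT")
}

# Decode one GT string (FORMAT field already reduced to GT) into a genotype
# enum for allele index `alt_index`. "/" and "|" separators are equivalent.
# Single-allele calls on chrX for a male sample are hemizygous; diploid male
# X calls are coerced ("1/1" -> hemi_alt, "0/0" -> hemi_ref) since many
# callers emit diploid genotypes on X. A single-allele call for a female on X
# or for anyone on an autosome is anomalous and handled conservatively.
decode_gt <- function(gt, alt_index, on_x, is_male, sample_id = "sample") {
  if (is.na(gt) || !nzchar(gt)) return("missing")
  field <- sub(":.*$", "", gt)
  alleles <- strsplit(field, "[/|]")[[1L]]
  if (length(alleles) < 1L || length(alleles) > 2L ||
      !all(grepl("^([0-9]+|\\.)$", alleles))) {
    warning("unparsable genotype '", gt, "' for ", sample_id,
            "; set to missing", call. = FALSE)
    return("missing")
  }
  if (any(alleles == ".")) return("missing")
  carries <- sum(as.integer(alleles) == alt_index)
  if (length(alleles) == 1L) {
    if (!on_x) {
      warning("haploid genotype '", gt, "' on an autosome for ", sample_id,
              "; set to missing", call. = FALSE)
      return("missing")
    }
    if (!is_male) {
      warning("haploid X genotype '", gt, "' for female sample ", sample_id,
              "; treated as diploid", call. = FALSE)
      return(if (carries > 0L) "het" else "hom_ref")
    }
    return(if (carries > 0L) "hemi_alt" else "hemi_ref")
  }
  g <- c("hom_ref", "het", "hom_alt")[carries + 1L]
  if (on_x && is_male && g != "het") {
    g <- c(hom_ref = "hemi_ref", hom_alt = "hemi_alt")[[g]]
  }
  g
}

# Inverse of decode_gt for VCF emission.
encode_gt <- function(genotype) {
  switch(genotype,
         hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
         hemi_ref = "0", hemi_alt = "1",
         missing = "./.",
         stop("unknown genotype enum: ", genotype))
}
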
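# Trio VCF input/output. Reading goes through vcfR; records are normalized to
# one row per ALT allele with trio genotypes decoded into enums.

# Parse one INFO string into a named character list ("A=1;B=x;FLAG").
parse_info <- function(info) {
  if (is.na(info) || !nzchar(info) || info == ".") return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1L]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) if (length(x) >= 2L) paste(x[-1L], collapse = "=") else TRUE)
  names(vals) <- vapply(kv, `[[`, "", 1L)
  vals
}

num_or_na <- function(x) {
  suppressWarnings(as.numeric(x))
}

# SpliceAI INFO dialect: ALT|GENE|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL
# (comma-separated entries for multiallelic sites). Unicode minus signs, as
# found in copy-pasted annotation tables, are normalized to ASCII.
parse_spliceai <- function(value, alt, alt_index, n_alts) {
  out <- list(gene = NA_character_,
              ds_ag = NA_real_, ds_al = NA_real_, ds_dg = NA_real_, ds_dl = NA_real_,
              dp_ag = NA_integer_, dp_al = NA_integer_, dp_dg = NA_integer_,
              dp_dl = NA_integer_)
  if (is.null(value) || isTRUE(value)) return(out)
  value <- gsub("−", "-", value)
  entries <- strsplit(value, ",", fixed = TRUE)[[1L]]
  fields <- lapply(entries, function(e) strsplit(e, "|", fixed = TRUE)[[1L]])
  pick <- which(vapply(fields, function(f) length(f) >= 1L && f[1L] == alt, FALSE))
  f <- if (length(pick)) {
    fields[[pick[1L]]]
  } else if (length(fields) == n_alts) {
    fields[[alt_index]]
  } else {
    fields[[1L]]
  }
  if (length(f) != 10L) return(out)
  out$gene <- if (nzchar(f[2L])) f[2L] else NA_character_
  ds <- num_or_na(f[3:6])
  dp <- suppressWarnings(as.integer(num_or_na(f[7:10])))
  out[c("ds_ag", "ds_al", "ds_dg", "ds_dl")] <- as.list(ds)
  out[c("dp_ag", "dp_al", "dp_dg", "dp_dl")] <- as.list(dp)
  out
}

# Pangolin INFO dialect used here: GAIN_SCORE:GAIN_POS|LOSS_SCORE:LOSS_POS.
parse_pangolin <- function(value) {
  out <- list(pangolin_gain = NA_real_, pangolin_gain_pos = NA_integer_,
              pangolin_loss = NA_real_, pangolin_loss_pos = NA_integer_)
  if (is.null(value) || isTRUE(value)) return(out)
  value <- gsub("−", "-", value)
  halves <- strsplit(value, "|", fixed = TRUE)[[1L]]
  parse_half <- function(h) {
    sp <- strsplit(h, ":", fixed = TRUE)[[1L]]
    c(num_or_na(sp[1L]), if (length(sp) >= 2L) num_or_na(sp[2L]) else NA_real_)
  }
  if (length(halves) >= 1L) {
    g <- parse_half(halves[1L])
    out$pangolin_gain <- g[1L]
    out$pangolin_gain_pos <- as.integer(g[2L])
  }
  if (length(halves) >= 2L) {
    l <- parse_half(halves[2L])
    out$pangolin_loss <- l[1L]
    out$pangolin_loss_pos <- as.integer(l[2L])
  }
  out
}

#' Read a trio VCF into a normalized variant table
#'
#' Reads a VCF 4.2 file with genotypes for the three pedigree samples and
#' returns one row per (record, ALT allele): multiallelic records are split,
#' `/` and `|` genotype separators are equivalent, and chrX genotypes are
#' decoded sex-aware (a single-allele or homozygous-alt call for a male
#' proband becomes `hemi_alt`). SpliceAI annotations
#' (`SpliceAI=ALT|GENE|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL`),
#' Pangolin annotations (`PANGOLIN=gain:pos|loss:pos`), maximum-entropy
#' splice-motif scores (`MAXENT=ref|alt`) and `AF` are parsed from INFO when
#' present; the raw INFO string is retained in the `info` column. Records are
#' sorted by (chrom, pos, ref, alt).
#'
#' Unparsable genotypes are set to `missing` with a warning and the record is
#' kept. A pedigree sample absent from the VCF header is an error.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param pedigree A [trio_pedigree()]; `proband_sex` drives chrX decoding.
#' @return A trio-variant table (see [empty_variant_table()] for the layout).
#' @export
read_trio_vcf <- function(path, pedigree) {
  stopifnot(inherits(pedigree, "trio_pedigree"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) return(empty_variant_table())
  gt <- vcf@gt
  samples <- colnames(gt)[-1L]
  need <- c(proband = pedigree$proband_id,
            mother = pedigree$mother_id,
            father = pedigree$father_id)
  if (!all(need %in% samples)) {
    stop("sample mismatch: pedigree sample(s) ",
         paste(setdiff(need, samples), collapse = ", "),
         " absent from VCF header (has: ", paste(samples, collapse = ", "), ")")
  }
  male <- c(proband = pedigree$proband_sex == "male", mother = FALSE, father = TRUE)

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    chrom <- fix[i, "CHROM"]
    pos <- as.integer(fix[i, "POS"])
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    info_str <- fix[i, "INFO"]
    info <- parse_info(info_str)
    on_x <- is_chrx(chrom)
    fmt <- strsplit(gt[i, 1L], ":", fixed = TRUE)[[1L]]
    gti <- match("GT", fmt)
    raw_gt <- vapply(need, function(s) {
      v <- strsplit(gt[i, s], ":", fixed = TRUE)[[1L]]
      if (is.na(gti) || gti > length(v)) NA_character_ else v[gti]
    }, "")
    af_all <- if (!is.null(info$AF) && !isTRUE(info$AF)) {
      num_or_na(strsplit(info$AF, ",", fixed = TRUE)[[1L]])
    } else {
      NA_real_
    }
    mx <- if (!is.null(info$MAXENT) && !isTRUE(info$MAXENT)) {
      num_or_na(strsplit(gsub("−", "-", info$MAXENT), "|", fixed = TRUE)[[1L]])
    } else {
      c(NA_real_, NA_real_)
    }
    pang <- parse_pangolin(info$PANGOLIN)

    sub <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      sai <- parse_spliceai(info$SpliceAI, alts[k], k, length(alts))
      genos <- vapply(names(need), function(role) {
        decode_gt(raw_gt[[role]], k, on_x, male[[role]],
                  sample_id = need[[role]])
      }, "")
      sub[[k]] <- data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alts[k],
        gene = sai$gene, transcript = NA_character_,
        region = NA_character_, intron_offset = NA_integer_,
        gt_proband = genos[["proband"]], gt_mother = genos[["mother"]],
        gt_father = genos[["father"]],
        af = if (length(af_all) >= k) af_all[k] else af_all[1L],
        ds_ag = sai$ds_ag, ds_al = sai$ds_al, ds_dg = sai$ds_dg, ds_dl = sai$ds_dl,
        dp_ag = sai$dp_ag, dp_al = sai$dp_al, dp_dg = sai$dp_dg, dp_dl = sai$dp_dl,
        pangolin_gain = pang$pangolin_gain,
        pangolin_gain_pos = pang$pangolin_gain_pos,
        pangolin_loss = pang$pangolin_loss,
        pangolin_loss_pos = pang$pangolin_loss_pos,
        maxent_ref = mx[1L], maxent_alt = if (length(mx) >= 2L) mx[2L] else NA_real_,
        info = if (is.na(info_str)) "." else info_str,
        stringsAsFactors = FALSE
      )
    }
    rows[[i]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  as_variant_table(out)
}

fmt_num <- function(x, digits = 6L) {
  ifelse(is.na(x), ".", formatC(x, format = "g", digits = digits))
}

build_info_string <- function(v) {
  parts <- character(0)
  if (!is.na(v$af)) parts <- c(parts, paste0("AF=", fmt_num(v$af, 8L)))
  if (any(!is.na(c(v$ds_ag, v$ds_al, v$ds_dg, v$ds_dl)))) {
    zero <- function(x) ifelse(is.na(x), "0.00", formatC(x, format = "g", digits = 4L))
    zint <- function(x) ifelse(is.na(x), "0", as.character(x))
    parts <- c(parts, paste0(
      "SpliceAI=", v$alt, "|", ifelse(is.na(v$gene), "", v$gene), "|",
      zero(v$ds_ag), "|", zero(v$ds_al), "|", zero(v$ds_dg), "|", zero(v$ds_dl), "|",
      zint(v$dp_ag), "|", zint(v$dp_al), "|", zint(v$dp_dg), "|", zint(v$dp_dl)))
  }
  if (!is.na(v$pangolin_gain) || !is.na(v$pangolin_loss)) {
    half <- function(s, p) paste0(fmt_num(s, 4L), ":", ifelse(is.na(p), "0", p))
    parts <- c(parts, paste0("PANGOLIN=",
                             half(v$pangolin_gain, v$pangolin_gain_pos), "|",
                             half(v$pangolin_loss, v$pangolin_loss_pos)))
  }
  if (!is.na(v$maxent_ref) || !is.na(v$maxent_alt)) {
    parts <- c(parts, paste0("MAXENT=", fmt_num(v$maxent_ref, 6L), "|",
                             fmt_num(v$maxent_alt, 6L)))
  }
  if (!length(parts)) "." else paste(parts, collapse = ";")
}

#' Write a trio-variant table as a VCF 4.2 file
#'
#' Emits one record per row (rows are already single-ALT after multiallelic
#' splitting) with GT for proband, mother and father and the package's INFO
#' keys (`AF`, `SpliceAI`, `PANGOLIN`, `MAXENT`). Hemizygous genotypes are
#' written as single-allele calls. Output is deterministic: identical input
#' yields byte-identical files.
#'
#' @param variants A trio-variant table.
#' @param pedigree A [trio_pedigree()] providing the sample column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(variants, pedigree, path) {
  stopifnot(inherits(pedigree, "trio_pedigree"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=triosplice",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    paste0("##INFO=<ID=SpliceAI,Number=.,Type=String,Description=\"SpliceAI ",
           "deltas: ALT|GENE|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL\">"),
    paste0("##INFO=<ID=PANGOLIN,Number=1,Type=String,Description=\"Pangolin ",
           "deltas: gain_score:gain_pos|loss_score:loss_pos\">"),
    paste0("##INFO=<ID=MAXENT,Number=1,Type=String,Description=\"Maximum-entropy ",
           "splice motif scores: ref|alt\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
          pedigree$proband_id, pedigree$mother_id, pedigree$father_id, sep = "\t")
  )
  body <- character(0)
  if (nrow(variants)) {
    variants <- variants[order(variants$chrom, variants$pos, variants$ref,
                               variants$alt), , drop = FALSE]
    body <- vapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
            build_info_string(v), "GT",
            encode_gt(v$gt_proband), encode_gt(v$gt_mother),
            encode_gt(v$gt_father), sep = "\t")
    }, "")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write prioritized candidate variants as TSV or JSON
#'
#' One row (or JSON object) per candidate with its step provenance,
#' inheritance call, gene annotation and screening metrics, ordered
#' deterministically by (step, chrom, pos, alt). Writing the same candidates
#' twice produces byte-identical output.
#'
#' @param candidates A candidate table as produced by the pipeline steps or
#'   [run_reanalysis()] (`$candidates`).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(candidates, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  keep <- intersect(
    c("step", "chrom", "pos", "ref", "alt", "gene", "transcript", "region",
      "intron_offset", "gt_proband", "gt_mother", "gt_father", "inheritance",
      "phase_confidence", "af", "loeuf", "gene_category",
      "ds_ag", "ds_al", "ds_dg", "ds_dl", "pangolin_gain", "pangolin_loss",
      "maxent_ref", "maxent_alt", "splice_event", "predicted_effect",
      "affected_length_bp", "evidence_tags", "case_id"),
    names(candidates))
  out <- candidates[, keep, drop = FALSE]
  if (nrow(out)) {
    ord <- order(if (is.null(out$step)) rep("", nrow(out)) else out$step,
                 out$chrom, out$pos, out$alt)
    out <- out[ord, , drop = FALSE]
  }
  rownames(out) <- NULL
  if (format == "tsv") {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
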
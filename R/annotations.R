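# Gene-level annotation tables: constraint (LOEUF + inheritance modes),
# phenotype gene panels, and population allele frequencies.

#' Read a gene annotation table
#'
#' Three TSV layouts are supported, selected by `kind`:
#' \describe{
#'   \item{`constraint`}{columns `gene`, `chrom`, `loeuf`, `modes`
#'     (comma-separated subset of AD/AR/ADR/XLD/XLR/XLDR, may be empty);
#'     returns a data frame keyed by gene with a derived `chrom_class`
#'     (`autosome`/`chrX`). Duplicate gene rows with conflicting LOEUF are an
#'     error (ambiguous annotation); exact duplicates are collapsed. Missing
#'     LOEUF values (`NA` or empty) are allowed: not every gene has a score.}
#'   \item{`panel`}{columns `panel`, `gene`; returns a named list mapping
#'     panel name to a character vector of gene symbols. A gene may sit in
#'     several panels.}
#'   \item{`frequency`}{columns `chrom`, `pos`, `ref`, `alt`, `af`; returns a
#'     data frame keyed by variant.}
#' }
#'
#' @param path Path to a tab-separated file with a header line.
#' @param kind One of `"constraint"`, `"panel"`, `"frequency"`.
#' @return See Details; depends on `kind`.
#' @export
read_annotation_table <- function(path, kind = c("constraint", "panel", "frequency")) {
  kind <- match.arg(kind)
  # read everything as character (a REF/ALT of "T" must not become logical)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           na.strings = c("NA", ".", ""),
                           colClasses = "character")
  need <- switch(kind,
                 constraint = c("gene", "chrom", "loeuf", "modes"),
                 panel = c("panel", "gene"),
                 frequency = c("chrom", "pos", "ref", "alt", "af"))
  if (!all(need %in% names(tab))) {
    stop("format error: ", kind, " table must have columns ",
         paste(need, collapse = ", "))
  }
  if (kind == "constraint") {
    tab$loeuf <- as.numeric(tab$loeuf)
    tab$modes <- ifelse(is.na(tab$modes), "", tab$modes)
    if (anyDuplicated(tab$gene)) {
      dup <- unique(tab$gene[duplicated(tab$gene)])
      for (g in dup) {
        lo <- unique(tab$loeuf[tab$gene == g])
        if (length(lo[!is.na(lo)]) > 1L) {
          stop("ambiguous annotation: gene ", g,
               " has conflicting LOEUF values (",
               paste(lo, collapse = ", "), ")")
        }
      }
      tab <- tab[!duplicated(tab$gene), , drop = FALSE]
    }
    tab$chrom_class <- ifelse(is_chrx(tab$chrom), "chrX", "autosome")
    rownames(tab) <- NULL
    return(tab)
  }
  if (kind == "panel") {
    return(lapply(split(tab$gene, tab$panel), unique))
  }
  tab$pos <- as.integer(tab$pos)
  tab$af <- as.numeric(tab$af)
  rownames(tab) <- NULL
  tab
}

#' Write a constraint, panel or frequency table as TSV
#'
#' @param tab A data frame (constraint/frequency) or named list of gene
#'   vectors (panel).
#' @param path Output path.
#' @param kind One of `"constraint"`, `"panel"`, `"frequency"`.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(tab, path,
                                   kind = c("constraint", "panel", "frequency")) {
  kind <- match.arg(kind)
  if (kind == "panel" && is.list(tab) && !is.data.frame(tab)) {
    tab <- data.frame(
      panel = rep(names(tab), lengths(tab)),
      gene = unlist(tab, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  if (kind == "constraint") {
    tab <- tab[, intersect(c("gene", "chrom", "loeuf", "modes"), names(tab)),
               drop = FALSE]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Classify a gene's inheritance-mode category
#'
#' Maps a gene's disease inheritance modes and chromosome class onto one of
#' the eight categories used in constraint comparisons: `AD`, `ADR`, `AR`,
#' `A_other` for autosomal genes and `XLD`, `XLR`, `XLDR`, `X_other` for
#' chrX genes. A gene carrying both dominant and recessive modes is `ADR` /
#' `XLDR`. An autosomal gene with an X-linked mode is a data error.
#'
#' @param modes Character vector of comma-separated mode strings (one element
#'   per gene), e.g. `"AD"`, `"AD,AR"`, `"XLR"`, `""`.
#' @param chrom_class Character vector, `"autosome"` or `"chrX"`, recycled.
#' @return Character vector of category labels.
#' @export
mode_category <- function(modes, chrom_class) {
  n <- max(length(modes), length(chrom_class))
  modes <- rep_len(as.character(modes), n)
  chrom_class <- rep_len(chrom_class, n)
  vapply(seq_len(n), function(i) {
    m <- toupper(trimws(strsplit(ifelse(is.na(modes[i]), "", modes[i]),
                                 ",", fixed = TRUE)[[1L]]))
    m <- m[nzchar(m)]
    x_modes <- any(m %in% c("XLD", "XLR", "XLDR"))
    if (chrom_class[i] == "autosome") {
      if (x_modes) {
        stop("data error: autosomal gene annotated with X-linked mode(s): ",
             paste(m, collapse = ","))
      }
      if ("ADR" %in% m || ("AD" %in% m && "AR" %in% m)) return("ADR")
      if ("AD" %in% m) return("AD")
      if ("AR" %in% m) return("AR")
      return("A_other")
    }
    if ("XLDR" %in% m || ("XLD" %in% m && "XLR" %in% m)) return("XLDR")
    if ("XLD" %in% m) return("XLD")
    if ("XLR" %in% m) return("XLR")
    "X_other"
  }, "")
}

#' Attach gene-level constraint annotations to variants
#'
#' Case-sensitive join on gene symbol: adds `loeuf`, `modes`, `chrom_class`
#' and the derived `gene_category` columns. Variants whose gene is absent
#' from the table (or has no symbol) keep `loeuf = NA` and are categorized
#' `A_other` / `X_other` from the variant's own chromosome; they are never
#' dropped.
#'
#' @param variants A trio-variant table with a `gene` column.
#' @param constraint A constraint table from [read_annotation_table()] or
#'   [generate_constraint_table()].
#' @return The variant table with annotation columns added.
#' @export
annotate_genes <- function(variants, constraint) {
  idx <- match(variants$gene, constraint$gene)
  variants$loeuf <- constraint$loeuf[idx]
  variants$modes <- ifelse(is.na(idx), "", constraint$modes[idx])
  variants$chrom_class <- ifelse(
    is.na(idx),
    ifelse(is_chrx(variants$chrom), "chrX", "autosome"),
    constraint$chrom_class[idx])
  if (nrow(variants)) {
    variants$gene_category <- mode_category(variants$modes, variants$chrom_class)
  } else {
    variants$gene_category <- character(0)
    variants$loeuf <- numeric(0)
    variants$modes <- character(0)
    variants$chrom_class <- character(0)
  }
  variants
}

#' Attach population allele frequencies from a frequency table
#'
#' Joins on (chrom, pos, ref, alt); variants absent from the table keep
#' their current `af` (typically `NA`, treated downstream as novel).
#'
#' @param variants A trio-variant table.
#' @param frequency A frequency table from
#'   `read_annotation_table(kind = "frequency")`.
#' @return The variant table with `af` filled where matched.
#' @export
annotate_frequency <- function(variants, frequency) {
  if (!nrow(variants) || !nrow(frequency)) return(variants)
  key_v <- variant_key(variants)
  key_f <- paste(frequency$chrom, frequency$pos, frequency$ref,
                 frequency$alt, sep = ":")
  idx <- match(key_v, key_f)
  hit <- !is.na(idx)
  variants$af[hit] <- frequency$af[idx[hit]]
  variants
}
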
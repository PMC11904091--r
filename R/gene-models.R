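# Exon-interval gene models (0-based half-open, BED convention) and the
# coordinate geometry that turns genomic positions into HGVS-style intron
# offsets (+n downstream of a donor, -n upstream of an acceptor, in
# transcript orientation).

#' Construct a gene model from exon intervals
#'
#' @param gene Gene symbol.
#' @param transcript Transcript identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of 0-based half-open exon
#'   intervals; sorted internally and required to be non-overlapping.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene, transcript, chrom, strand, exons) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, "start"] >= exons[, "end"])) {
    stop("format error: exon interval with start >= end in ", gene)
  }
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] < exons[-nrow(exons), "end"])) {
    stop("format error: overlapping exons in ", gene)
  }
  structure(
    list(gene = gene, transcript = transcript, chrom = chrom,
         strand = strand, exons = exons),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model ", x$gene, " (", x$transcript, ") ", x$chrom, x$strand,
      " ", nrow(x$exons), " exon(s), span ",
      x$exons[1L, 1L], "-", x$exons[nrow(x$exons), 2L], "\n", sep = "")
  invisible(x)
}

#' Read exon-level gene models from a BED file
#'
#' One exon per line, BED6 columns (chrom, start, end, name, score, strand),
#' 0-based half-open coordinates, name field `gene|transcript` (a name
#' without `|` is used as both). Exons are grouped per transcript and sorted.
#'
#' @param path Path to a BED file; an empty file yields an empty list.
#' @return A named list of [gene_model()] objects (names = gene symbols),
#'   with class `gene_model_set`.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(structure(list(), class = "gene_model_set"))
  }
  bed <- utils::read.table(text = lines, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("format error: BED file needs >= 4 columns")
  names(bed)[1:4] <- c("chrom", "start", "end", "name")
  bed$strand <- if (ncol(bed) >= 6L) bed[[6L]] else "+"
  bad <- which(bed$start >= bed$end)
  if (length(bad)) {
    stop("format error: exon interval with start >= end at line ", bad[1L],
         " (", lines[bad[1L]], ")")
  }
  nm <- strsplit(bed$name, "|", fixed = TRUE)
  bed$gene <- vapply(nm, `[[`, "", 1L)
  bed$transcript <- vapply(nm, function(x) if (length(x) >= 2L) x[2L] else x[1L], "")
  models <- lapply(split(bed, bed$transcript), function(b) {
    if (length(unique(b$chrom)) != 1L || length(unique(b$strand)) != 1L) {
      stop("format error: transcript ", b$transcript[1L],
           " spans multiple chromosomes or strands")
    }
    gene_model(b$gene[1L], b$transcript[1L], b$chrom[1L], b$strand[1L],
               cbind(b$start, b$end))
  })
  names(models) <- vapply(models, `[[`, "", "gene")
  models <- models[order(names(models))]
  structure(models, class = "gene_model_set")
}

#' Write gene models as a BED6 file
#'
#' @param models A list of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed <- function(models, path) {
  rows <- unlist(lapply(models, function(m) {
    sprintf("%s\t%d\t%d\t%s|%s\t0\t%s",
            m$chrom, as.integer(m$exons[, "start"]),
            as.integer(m$exons[, "end"]),
            m$gene, m$transcript, m$strand)
  }), use.names = FALSE)
  writeLines(rows, path)
  invisible(path)
}

#' Intron offset of a genomic position relative to a gene model
#'
#' Computes the HGVS-style offset in transcript orientation: positions
#' downstream of a splice donor are `+n` (n >= 1), positions upstream of a
#' splice acceptor are `-n`; intronic positions take the offset of the nearer
#' boundary (exact midpoint ties go to the donor side). On the minus strand
#' the genomic directions invert. Exonic positions have no offset; positions
#' outside the model span are intergenic.
#'
#' @param pos 1-based genomic position.
#' @param model A [gene_model()].
#' @return A list with `offset` (signed integer or `NA`) and `region`
#'   (one of `"exonic"`, `"canonical_splice_site"` for |offset| <= 2,
#'   `"intronic"`, `"intergenic"`).
#' @export
#' @examples
#' m <- gene_model("G", "G.t1", "chr1", "+", rbind(c(100, 200), c(500, 600)))
#' intron_offset(203, m)  # 3 bases past the donor: +3, intronic
#' intron_offset(495, m)  # 6 bases before the acceptor: -6, intronic
intron_offset <- function(pos, model) {
  stopifnot(inherits(model, "gene_model"), length(pos) == 1L, pos >= 1)
  ex <- model$exons
  p0 <- pos - 1  # 0-based
  if (p0 < ex[1L, "start"] || p0 >= ex[nrow(ex), "end"]) {
    return(list(offset = NA_integer_, region = "intergenic"))
  }
  if (any(p0 >= ex[, "start"] & p0 < ex[, "end"])) {
    return(list(offset = NA_integer_, region = "exonic"))
  }
  prev_end <- max(ex[ex[, "end"] <= p0, "end"])     # exclusive end of left exon
  next_start <- min(ex[ex[, "start"] > p0, "start"])
  dist_left <- pos - prev_end        # >= 1, distance into intron from left exon
  dist_right <- next_start - pos + 1 # >= 1, distance to right exon
  if (model$strand == "+") {
    donor <- dist_left
    acceptor <- dist_right
  } else {
    donor <- dist_right
    acceptor <- dist_left
  }
  offset <- if (donor <= acceptor) donor else -acceptor
  region <- if (abs(offset) <= 2L) "canonical_splice_site" else "intronic"
  list(offset = as.integer(offset), region = region)
}

#' Genomic position at a given intron offset
#'
#' Inverse of [intron_offset()] for a chosen intron: returns the 1-based
#' genomic position whose HGVS-style offset within intron `intron_index`
#' (between exons `intron_index` and `intron_index + 1` in genomic order)
#' equals `offset`. Used to plant variants at controlled distances from the
#' exon-intron boundary.
#'
#' @param model A [gene_model()].
#' @param intron_index Intron number in genomic order (1-based).
#' @param offset Signed non-zero offset; `abs(offset)` must not exceed half
#'   the intron length (otherwise the position would map to the opposite
#'   boundary).
#' @return 1-based genomic position.
#' @export
intron_position <- function(model, intron_index, offset) {
  stopifnot(inherits(model, "gene_model"), offset != 0)
  ex <- model$exons
  if (intron_index < 1L || intron_index > nrow(ex) - 1L) {
    stop("no intron ", intron_index, " in ", model$gene)
  }
  left_end <- ex[intron_index, "end"]
  right_start <- ex[intron_index + 1L, "start"]
  intron_len <- right_start - left_end
  if (abs(offset) > intron_len %/% 2L) {
    stop("offset ", offset, " exceeds half the intron length (", intron_len,
         ") in ", model$gene)
  }
  plus <- model$strand == "+"
  pos <- if (offset > 0) {
    if (plus) left_end + offset else right_start - offset + 1
  } else {
    if (plus) right_start + offset + 1 else left_end - offset
  }
  as.integer(pos)
}

#' Annotate variants with gene, region and intron offset
#'
#' Assigns each variant to the first gene model whose span (first exon start
#' to last exon end) covers it on the same chromosome, and fills the `gene`,
#' `transcript`, `region` and `intron_offset` columns. Variants covered by no
#' model are marked `intergenic` (a gene symbol already present, e.g. from a
#' SpliceAI annotation, is retained).
#'
#' @param variants A trio-variant table.
#' @param models A `gene_model_set` from [read_gene_models()] or
#'   [generate_gene_models()].
#' @return The variant table with location columns filled.
#' @export
annotate_regions <- function(variants, models) {
  if (!nrow(variants)) return(variants)
  spans <- data.frame(
    gene = vapply(models, `[[`, "", "gene"),
    transcript = vapply(models, `[[`, "", "transcript"),
    chrom = vapply(models, `[[`, "", "chrom"),
    start = vapply(models, function(m) m$exons[1L, "start"], 0),
    end = vapply(models, function(m) m$exons[nrow(m$exons), "end"], 0),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(variants))) {
    p0 <- variants$pos[i] - 1
    hit <- which(spans$chrom == variants$chrom[i] &
                   spans$start <= p0 & p0 < spans$end)
    if (!length(hit)) {
      variants$region[i] <- "intergenic"
      variants$intron_offset[i] <- NA_integer_
      next
    }
    m <- models[[hit[1L]]]
    loc <- intron_offset(variants$pos[i], m)
    variants$gene[i] <- m$gene
    variants$transcript[i] <- m$transcript
    variants$region[i] <- loc$region
    variants$intron_offset[i] <- loc$offset
  }
  variants
}
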
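# Stepwise reanalysis orchestration.
#
# Step 0 is the initial-analysis scope: rare exonic / canonical-splice-site
# variants with a clean trio inheritance call. The reanalysis then runs:
#   Step 1 — constraint prioritization of the step-0 scope (LOEUF gate,
#            dominant / X-linked gene modes);
#   Step 2 — phenotype-driven gene panels, all regions within the intronic
#            window, SpliceAI-screened;
#   Step 3 — genome-wide constrained genes, all regions within the window,
#            SpliceAI-screened, restricted to de novo / X-linked models.
# A variant is admitted once; later steps never re-emit it.

#' Pipeline configuration
#'
#' @param loeuf_threshold Constraint gate (default 0.35, inclusive).
#' @param delta_threshold SpliceAI delta threshold (default 0.2, strict).
#' @param window_bp Intronic screening window per boundary (default 150 bp).
#' @param max_af Population allele-frequency cutoff (default 1e-4); unknown
#'   frequency is treated as novel.
#' @param panels Named list mapping phenotype label to a character vector of
#'   panel genes.
#' @param step3_models Inheritance models admissible at step 3 (default: the
#'   de novo autosomal/X and X-hemizygous models).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(loeuf_threshold = 0.35,
                            delta_threshold = 0.2,
                            window_bp = 150,
                            max_af = 1e-4,
                            panels = list(),
                            step3_models = c("de_novo_autosomal", "de_novo_x",
                                             "x_hemizygous_de_novo",
                                             "x_hemizygous_maternal")) {
  stopifnot(loeuf_threshold > 0, delta_threshold > 0, window_bp > 0,
            max_af >= 0, max_af <= 1,
            all(step3_models %in% INHERITANCE_MODELS))
  structure(
    list(loeuf_threshold = loeuf_threshold,
         delta_threshold = delta_threshold,
         window_bp = window_bp,
         max_af = max_af,
         panels = panels,
         step3_models = step3_models),
    class = "pipeline_config"
  )
}

#' Population allele-frequency filter
#'
#' Keeps variants whose population allele frequency is at most `max_af`;
#' unknown frequency counts as novel (kept) — absence from the reference
#' database is itself the operative rarity signal.
#'
#' @param variants A trio-variant table with an `af` column.
#' @param max_af Frequency cutoff in \[0, 1\].
#' @return The filtered table.
#' @export
frequency_filter <- function(variants, max_af = 1e-4) {
  stopifnot(max_af >= 0, max_af <= 1)
  keep <- is.na(variants$af) | variants$af <= max_af
  variants[keep, , drop = FALSE]
}

clean_inheritance <- function(variants) {
  !(variants$inheritance %in% c("mendelian_error", "unclassifiable"))
}

with_step <- function(variants, step, tags = NULL) {
  variants$step <- rep(step, nrow(variants))
  if (is.null(variants$evidence_tags)) {
    variants$evidence_tags <- rep("", nrow(variants))
  }
  if (!is.null(tags)) {
    variants$evidence_tags <- ifelse(
      nzchar(variants$evidence_tags) & nzchar(tags),
      paste(variants$evidence_tags, tags, sep = ","),
      paste0(variants$evidence_tags, tags))
  }
  variants
}

#' Step 0: initial exon / splice-site analysis scope
#'
#' Rare (frequency-filtered) variants in exons or canonical splice sites
#' (the two intronic bases flanking each exon) with a clean inheritance
#' call — neither a Mendelian error nor unclassifiable.
#'
#' @param variants A prepared trio-variant table (region, inheritance and
#'   frequency columns present).
#' @param config A [pipeline_config()].
#' @return Candidate subset labelled `step0`.
#' @export
step0_initial <- function(variants, config = pipeline_config()) {
  v <- frequency_filter(variants, config$max_af)
  keep <- !is.na(v$region) &
    v$region %in% c("exonic", "canonical_splice_site") &
    clean_inheritance(v)
  with_step(v[keep, , drop = FALSE], "step0", "initial_scope")
}

#' Step 1: constraint prioritization of the initial scope
#'
#' Gates step-0 candidates on the LOEUF constraint threshold and on gene
#' inheritance modes: dominant or X-linked disease genes (AD, ADR, XLD,
#' XLR, XLDR) pass, and chrX genes without a documented mode (`X_other`)
#' pass when the call is de novo on chrX — constrained non-disease X genes
#' are candidate-gene territory. Output is ordered by ascending LOEUF
#' (most constrained first).
#'
#' @param candidates Step-0 output.
#' @param config A [pipeline_config()].
#' @return Candidate subset labelled `step1`.
#' @export
step1_constraint <- function(candidates, config = pipeline_config()) {
  v <- candidates
  gate <- passes_constraint_gate(v$loeuf, config$loeuf_threshold)
  modes_ok <- v$gene_category %in% c("AD", "ADR", "XLD", "XLR", "XLDR") |
    (v$gene_category == "X_other" &
       v$inheritance %in% c("de_novo_x", "x_hemizygous_de_novo"))
  out <- v[gate & modes_ok, , drop = FALSE]
  out <- out[order(out$loeuf, out$chrom, out$pos), , drop = FALSE]
  out$step <- NULL
  with_step(out, "step1", "constraint_gate")
}

#' Step 2: phenotype-driven gene-panel screening
#'
#' For cases whose clinical phenotype maps to a configured gene panel, all
#' variants (exonic, splice-site and intronic) in panel genes are screened:
#' frequency filter, clean inheritance call, and [screen_variants()]
#' (window plus SpliceAI delta for intronic records). No constraint gate —
#' this step is phenotype-driven.
#'
#' @param variants A prepared trio-variant table (all regions).
#' @param phenotype Phenotype label; must name a configured panel.
#' @param config A [pipeline_config()] with a non-empty `panels` map.
#' @param exclude_keys Variant keys already admitted at earlier steps.
#' @return Candidate subset labelled `step2`.
#' @export
step2_panel <- function(variants, phenotype, config = pipeline_config(),
                        exclude_keys = character(0)) {
  if (!phenotype %in% names(config$panels)) {
    stop("unknown phenotype '", phenotype, "'; configured panels: ",
         if (length(config$panels)) paste(names(config$panels), collapse = ", ")
         else "(none)")
  }
  genes <- config$panels[[phenotype]]
  v <- frequency_filter(variants, config$max_af)
  v <- v[!is.na(v$gene) & v$gene %in% genes & clean_inheritance(v), ,
         drop = FALSE]
  scr <- screen_variants(v, config$delta_threshold, config$window_bp)
  sel <- scr$pass & !(variant_key(v) %in% exclude_keys)
  out <- v[sel, , drop = FALSE]
  tags <- scr$tags[sel]
  out$step <- NULL
  with_step(out, "step2", paste0("panel_", phenotype,
                                 ifelse(nzchar(tags), paste0(",", tags), "")))
}

#' Step 3: genome-wide screening of constrained genes
#'
#' For cases still undiagnosed, all variants within the intronic window in
#' LOEUF-gated genes are screened with SpliceAI, restricted to the
#' configured inheritance models (by default de novo and X-linked
#' hemizygous — the models under which a single constrained-gene hit is
#' diagnostic). Variants admitted at earlier steps are excluded.
#'
#' @param variants A prepared trio-variant table (all regions).
#' @param config A [pipeline_config()].
#' @param exclude_keys Variant keys already admitted at earlier steps.
#' @return Candidate subset labelled `step3`, ordered by ascending LOEUF.
#' @export
step3_constrained_genomewide <- function(variants, config = pipeline_config(),
                                         exclude_keys = character(0)) {
  v <- frequency_filter(variants, config$max_af)
  keep <- passes_constraint_gate(v$loeuf, config$loeuf_threshold) &
    v$inheritance %in% config$step3_models
  v <- v[keep, , drop = FALSE]
  scr <- screen_variants(v, config$delta_threshold, config$window_bp)
  sel <- scr$pass & !(variant_key(v) %in% exclude_keys)
  out <- v[sel, , drop = FALSE]
  tags <- scr$tags[sel]
  ord <- order(out$loeuf, out$chrom, out$pos)
  out <- out[ord, , drop = FALSE]
  tags <- tags[ord]
  out$step <- NULL
  with_step(out, "step3", paste0("constraint_gate",
                                 ifelse(nzchar(tags), paste0(",", tags), "")))
}

#' Run the full stepwise reanalysis for one trio
#'
#' Prepares the variant table (region annotation from gene models, gene
#' constraint annotation, inheritance classification, splice-consequence
#' inference) if not already done, then executes step 0 and reanalysis
#' steps 1-3. In the merged candidate table each variant carries exactly one
#' step label — its first admission. A step-0 candidate that also passes the
#' step-1 constraint gate is labelled `step1` (constraint prioritization is
#' the reanalysis event; the variant was visible, but not prioritized, in
#' the initial scope); steps 2 and 3 exclude keys admitted earlier.
#'
#' @param variants A trio-variant table (raw from [read_trio_vcf()] or
#'   already prepared).
#' @param pedigree A [trio_pedigree()].
#' @param models Optional `gene_model_set` for region annotation.
#' @param constraint Optional constraint table for gene annotation.
#' @param config A [pipeline_config()].
#' @param phenotype Optional phenotype label; step 2 runs only when it maps
#'   to a configured panel.
#' @return A `reanalysis_report` list: `candidates` (merged, one step label
#'   per variant), `counts` (named per-step input/output counts),
#'   `diagnosis_stage` (first step with an admission, or `"undiagnosed"`),
#'   `pedigree`, `phenotype`, `config`.
#' @export
run_reanalysis <- function(variants, pedigree, models = NULL,
                           constraint = NULL, config = pipeline_config(),
                           phenotype = NULL) {
  stopifnot(inherits(pedigree, "trio_pedigree"))
  v <- variants
  if (!is.null(models) && (is.null(v$region) || all(is.na(v$region)))) {
    v <- annotate_regions(v, models)
  }
  if (!is.null(constraint) && is.null(v$loeuf)) {
    v <- annotate_genes(v, constraint)
  }
  if (is.null(v$loeuf)) v$loeuf <- NA_real_
  if (is.null(v$gene_category)) {
    v$gene_category <- ifelse(is_chrx(v$chrom), "X_other", "A_other")
  }
  if (is.null(v$inheritance)) v <- classify_variants(v, pedigree)
  v <- infer_consequences(v)

  s0 <- step0_initial(v, config)
  s1 <- step1_constraint(s0, config)
  s0_only <- s0[!(variant_key(s0) %in% variant_key(s1)), , drop = FALSE]
  earlier <- variant_key(s0)
  s2 <- if (!is.null(phenotype) && phenotype %in% names(config$panels)) {
    step2_panel(v, phenotype, config, exclude_keys = earlier)
  } else {
    with_step(v[0L, , drop = FALSE], "step2")
  }
  earlier <- c(earlier, variant_key(s2))
  s3 <- step3_constrained_genomewide(v, config, exclude_keys = earlier)

  candidates <- rbind(s0_only, s1, s2, s3)
  rownames(candidates) <- NULL
  counts <- c(input = nrow(variants),
              step0 = nrow(s0), step1 = nrow(s1),
              step2 = nrow(s2), step3 = nrow(s3))
  stage_counts <- c(step0 = nrow(s0_only), step1 = nrow(s1),
                    step2 = nrow(s2), step3 = nrow(s3))
  nonzero <- names(stage_counts)[stage_counts > 0L]
  structure(
    list(candidates = candidates,
         counts = counts,
         diagnosis_stage = if (length(nonzero)) nonzero[1L] else "undiagnosed",
         pedigree = pedigree,
         phenotype = phenotype,
         config = config),
    class = "reanalysis_report"
  )
}

#' @export
print.reanalysis_report <- function(x, ...) {
  cat("Trio reanalysis report [", x$pedigree$family_id, "]\n", sep = "")
  cat("  variants in:", x$counts[["input"]], "\n")
  cat("  step0 scope:", x$counts[["step0"]],
      "| step1:", x$counts[["step1"]],
      "| step2:", x$counts[["step2"]],
      "| step3:", x$counts[["step3"]], "\n")
  cat("  first admission:", x$diagnosis_stage, "\n")
  invisible(x)
}

#' Run the reanalysis from files
#'
#' Thin wrapper over [run_reanalysis()] that reads the trio VCF, PED, exon
#' BED and annotation tables from disk.
#'
#' @param vcf,ped,bed,constraint_tsv Paths to the trio VCF, PED file, exon
#'   BED and constraint TSV.
#' @param panels_tsv Optional panel TSV (panel, gene).
#' @param phenotype Optional phenotype label for step 2.
#' @param config A [pipeline_config()]; its `panels` are replaced by
#'   `panels_tsv` when given.
#' @return A `reanalysis_report`.
#' @export
run_reanalysis_files <- function(vcf, ped, bed, constraint_tsv,
                                 panels_tsv = NULL, phenotype = NULL,
                                 config = pipeline_config()) {
  pedigree <- read_pedigree(ped)
  variants <- read_trio_vcf(vcf, pedigree)
  models <- read_gene_models(bed)
  constraint <- read_annotation_table(constraint_tsv, "constraint")
  if (!is.null(panels_tsv)) {
    config$panels <- read_annotation_table(panels_tsv, "panel")
  }
  run_reanalysis(variants, pedigree, models, constraint, config, phenotype)
}

#' Diagnostic-yield accounting over a cohort ledger
#'
#' Computes, from a per-case ledger (case id, clinical outcome, phenotype
#' category, diagnosis stage), the percentage diagnosed at the initial
#' analysis, the percentage of initially undiagnosed cases rescued by the
#' reanalysis steps, per-outcome and per-phenotype breakdowns, and the size
#' of the step-3 universe (cases still undiagnosed after steps 1 and 2).
#' Percentages are reported to one decimal.
#'
#' @param ledger Data frame with columns `case_id` (unique), `outcome`,
#'   `phenotype_category`, `diagnosis_stage` (one of `initial`, `step1`,
#'   `step2`, `step3`, `undiagnosed`).
#' @return A list: `n_cases`, `n_initial`, `initial_yield_pct`,
#'   `n_undiagnosed_initial`, `n_reanalysis`, `reanalysis_yield_pct`,
#'   `n_step3_universe`, `by_stage`, `by_outcome`, `by_phenotype`.
#' @export
tally_yield <- function(ledger) {
  if (is.null(ledger) || !nrow(ledger)) stop("tally_yield: empty ledger")
  if (anyDuplicated(ledger$case_id)) {
    stop("tally_yield: duplicate case ids in ledger")
  }
  stages <- c("initial", "step1", "step2", "step3", "undiagnosed")
  if (!all(ledger$diagnosis_stage %in% stages)) {
    stop("tally_yield: diagnosis_stage must be one of ",
         paste(stages, collapse = ", "))
  }
  n <- nrow(ledger)
  n_initial <- sum(ledger$diagnosis_stage == "initial")
  n_undiag <- n - n_initial
  n_rean <- sum(ledger$diagnosis_stage %in% c("step1", "step2", "step3"))
  by_stage <- as.data.frame(table(factor(ledger$diagnosis_stage, stages)),
                            stringsAsFactors = FALSE)
  names(by_stage) <- c("stage", "n")
  breakdown <- function(field) {
    split_by <- split(ledger, ledger[[field]])
    out <- do.call(rbind, lapply(names(split_by), function(k) {
      g <- split_by[[k]]
      data.frame(group = k, n = nrow(g),
                 n_diagnosed = sum(g$diagnosis_stage != "undiagnosed"),
                 diagnosed_pct = round(
                   100 * mean(g$diagnosis_stage != "undiagnosed"), 1),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  }
  list(
    n_cases = n,
    n_initial = n_initial,
    initial_yield_pct = round(100 * n_initial / n, 1),
    n_undiagnosed_initial = n_undiag,
    n_reanalysis = n_rean,
    reanalysis_yield_pct = if (n_undiag > 0) round(100 * n_rean / n_undiag, 1)
                           else NA_real_,
    n_step3_universe = n_undiag -
      sum(ledger$diagnosis_stage %in% c("step1", "step2")),
    by_stage = by_stage,
    by_outcome = breakdown("outcome"),
    by_phenotype = breakdown("phenotype_category")
  )
}
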
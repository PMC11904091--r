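---
title: "Stepwise trio-WES reanalysis: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise trio-WES reanalysis: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triosplice)
```

## The procedure

`triosplice` models the diagnostic workflow of a trio whole-exome study of
congenital anomalies as a ladder of progressively wider, progressively more
specific screens over one trio VCF:

* **Step 0 (initial scope).** Rare variants (population allele frequency at
  most `max_af`; unknown frequency counts as novel) in exons or at the
  canonical splice sites — the two intronic bases flanking each exon — with
  a clean trio inheritance call. This reproduces what a standard first-pass
  interpretation sees.
* **Step 1 (constraint prioritization).** The step-0 scope re-ranked and
  gated by gene constraint: LOEUF at or below `loeuf_threshold`, restricted
  to dominant and X-linked gene modes (AD, ADR, XLD, XLR, XLDR), with one
  extension: constrained chrX genes without a documented disease mode pass
  when the call is de novo on chrX, since highly constrained non-disease X
  genes are exactly where novel dominant X-linked disorders surface.
  Output is ordered by ascending LOEUF, most constrained first.
* **Step 2 (phenotype panels).** For cases whose clinical picture maps to a
  configured gene panel, *all* panel-gene variants — exonic, splice-site and
  intronic within the screening window — are screened with SpliceAI. No
  constraint gate: this step is phenotype-driven, and recessive panel genes
  are typically not constrained.
* **Step 3 (constrained genome-wide).** For cases still undiagnosed, all
  variants within the window in LOEUF-gated genes, restricted to the de
  novo and X-hemizygous inheritance models (`step3_models`), screened with
  SpliceAI. A single inherited heterozygote in a dominant gene carried by a
  healthy parent is not a diagnosis; the de novo / hemizygous restriction
  encodes that.

Inheritance filtering applies at every step. "Diagnosis" here means
admission of at least one candidate; clinical variant classification
(ACMG/AMP criteria) stays with the analyst — the reports carry evidence
tags, not verdicts.

### Step provenance

Step 1 operates on step 0's output, so a constraint-prioritized variant is
literally visible in both. In the merged per-trio report each variant
carries exactly one step label — the step that first makes it a
*prioritized* candidate: variants passing the step-1 gate are labelled
`step1`, step-0 candidates never reprioritized keep `step0`, and steps 2
and 3 exclude keys admitted earlier. That matches how such cases are
actually resolved: a variant can be "detected" in the initial analysis yet
only become a diagnosis once constraint draws attention to its gene.

## The inheritance decision table

`classify_genotypes()` is a total, deterministic function over (proband,
mother, father) genotype enums × chromosome class × proband sex; every
combination maps to exactly one model. Design points:

* **Genotype-only logic.** No allele depths, no mosaicism model, no
  statistical de novo caller: the decision table mirrors GT-level trio
  filtering.
* **De novo** requires a carrier proband with both parents hom-ref; on chrX
  for a male proband only the mother matters — the son's X is maternal, so
  a hemizygous-alt father changes nothing.
* **Mendelian errors** are combinations impossible under biparental
  transmission (hom-alt proband with a hom-ref parent on an autosome,
  hom-ref proband with a hom-alt parent, a het daughter of two homozygous-alt
  parents, …). They are excluded from every step but kept in the raw table.
* **Ambiguous phase.** A het proband whose variant is carried by *both*
  parents has an undecidable transmitting parent. The model set has no
  biparental-het entry and forcing a maternal or paternal call would break
  the mother/father swap symmetry the classifier is tested against, so the
  call is `unclassifiable` with `phase_confidence = "ambiguous"`. Compound-het
  detection is unaffected: it works on carrier sets directly and flags
  pairs involving such variants as ambiguous rather than dropping them.
* **`x_recessive_hom`.** A homozygous-alt daughter of a carrier mother and a
  hemizygous-alt father is biologically coherent and fits no other label;
  the model set carries this extra value rather than misfiling the case
  under the autosomal-recessive label.
* **Hemizygous coercions.** Callers routinely emit diploid genotypes on
  male X; `1/1` is read as `hemi_alt` and `0/0` as `hemi_ref`. A
  single-allele genotype for a female on X is treated as diploid with a
  warning. chrY and mitochondrial records pass through unclassified.
* **A de novo X variant in a female proband** is a heterozygote and is
  classified `de_novo_x`; reports of "hemizygous" variants in
  karyotypically female probands are read as heterozygous.

Compound-heterozygote phasing is by parental transmission only (the trio's
native phasing signal): one het assigned to each parent forms a trans pair;
two hets from the same parent are cis-by-transmission and never pair.

## Splice screening

* **Window.** Exome capture reaches a bounded stretch of intron around each
  exon; the screen uses a fixed symmetric window of `window_bp = 150` bases
  per boundary, the conventional figure for near-exon intronic coverage.
  Exonic positions are always in scope.
* **Offsets.** Intron offsets are HGVS-style and transcript-oriented: `+n`
  downstream of a donor, `−n` upstream of an acceptor; on the minus strand
  the genomic directions invert. |offset| ≤ 2 is a canonical splice site.
  An intronic position takes the offset of the nearer boundary; exact
  midpoint ties go to the donor side (a tie can only occur ≥ 250 bp into an
  intron, far outside the window, so the choice is cosmetic).
* **Delta aggregation.** SpliceAI emits four deltas (acceptor/donor ×
  gain/loss); the screen thresholds their **maximum** at
  `delta_threshold = 0.2` (strictly greater), the standard single-number
  use of this annotation. Ties between deltas resolve in the fixed order
  acceptor gain, acceptor loss, donor gain, donor loss.
* **Pangolin never gates.** Pangolin scores are carried as corroborating
  evidence; when Pangolin exceeds the threshold but SpliceAI does not, the
  variant is tagged `pangolin_rescue` for the analyst and still fails the
  screen — no Pangolin threshold is part of the procedure.
* **Motif score change.** The maximum-entropy splice-motif comparison is
  reported as `100 · (S_alt − S_ref) / |S_ref|`, two decimals. The
  absolute-value denominator keeps the sign meaningful when the reference
  score is negative (motif scores are log-odds); a reference score of
  exactly 0 is undefined and an error.
* **Consequence inference** is deliberately conservative: a dominant donor
  loss at a donor-proximal offset predicts intron retention; a dominant
  acceptor gain in the intron at offset ≤ −2, where the variant supplies
  the G of a novel AG acceptor, predicts an exon extension of
  `|offset| − 1` bases (the intronic bases between the novel and canonical
  acceptor enter the transcript — at offset −6, a 5-bp extension). Every
  other geometry returns `unknown` rather than guessing.

## Constraint

The LOEUF gate is **inclusive** at the boundary (`loeuf ≤ 0.35` passes):
descriptions of the cutoff vary between "below 0.35" and "≤ 0.35", the
inclusive reading is the more permissive, and the threshold is a config
parameter in any case. Genes without a LOEUF score fail the gate — they
cannot be prioritized by constraint — but are never dropped from the
phenotype-driven step 2.

Category comparisons (`compare_loeuf_by_inheritance()`) test each X-linked
category (XLD, XLR, XLDR, X_other) against autosomal-dominant genes with
Welch's unequal-variance t test (two-sided, Welch–Satterthwaite degrees of
freedom), reporting raw p values plus a labelled Bonferroni column over the
emitted comparisons; categories with fewer than two scored genes are
skipped with a warning. Degenerate input (both groups essentially constant)
returns t = 0, p = 1 at equal means. Numeric p values are reported rather
than significance stars.

## The synthetic cohort generator

Real patient-level data from such studies are not shareable, so the
generator stands in, emulating exactly the structure the pipeline's
correctness depends on:

* **Genome.** Contigs `chr1`–`chr5` plus `chrX`, genes tiled round-robin
  without overlap (10 kb spacers), 2–20 exons of 50–300 bp separated by
  0.5–5 kb introns, both strands. No reference FASTA exists and none is
  needed — the pipeline never consults sequence, only coordinates and
  annotations.
* **Constraint.** LOEUF per inheritance-mode category from truncated
  normals: X-linked disease categories centred at 0.15 (sd 0.08), AD at
  0.60, AR at 0.90, autosomal "other" at 1.0 (sd 0.2–0.3), 5% of genes
  unscored. The means encode the X-vs-AD constraint asymmetry; the sds are
  chosen so the categories overlap realistically while a 500-per-category
  Welch test is decisive.
* **Background variation** is *always parentally transmitted*: one carrier
  parent, Mendelian transmission to the proband (sex-aware on chrX). The
  generator never plants background de novos — a novel background de novo
  in a constrained gene would be a correct step-3 admission, and the
  recovery tests require the step-3 output to equal the truth table
  exactly. Allele frequencies are a mixture of 30% novel (af 0) and 70%
  log-uniform on [1e-4, 0.5], so the frequency filter has real work to do;
  background SpliceAI deltas are Beta(1, 30) — concentrated below 0.1 with
  rare excursions past 0.2. An optional `mendelian_error_rate` rewrites a
  flagged fraction of backgrounds to genotype-impossible patterns for QC
  testing.
* **Planted variants** get the exact genotype pattern of their inheritance
  model, af 0, and their specified splice scores. Their genes' LOEUF and
  mode annotations are **pinned** to the specified study-like values
  (0.07/0.12/0.9/0.073) rather than sampled, so that recovery at the
  intended step is a property of the construction, not of a lucky draw.
  The default plant covers the four diagnostic archetypes: a canonical
  splice-site de novo and an exonic hemizygous missense in constrained
  X-linked genes (step 1), a compound het whose intronic partner carries a
  0.38 donor-loss delta in a recessive panel gene (step 2), and a
  deep-intronic de novo hemizygous acceptor gain at offset −6 (step 3).
* **The bundled 128-case ledger** encodes the motivating cohort's totals —
  128 cases, 51 diagnosed initially (39.8%), 4 of the remaining 77
  diagnosed across steps 1–3 (5.2%), 74 left for step 3 after steps 1–2.
  Its per-case outcome and phenotype labels are synthetic placeholders
  assigned deterministically; only the totals are faithful, and the
  per-outcome/per-phenotype breakdowns computed from it illustrate the
  accounting rather than reproduce published subgroup figures.

What passing tests on this generator do **not** show: robustness to caller
artefacts (multi-sample VCF quirks, half-calls, low-depth de novo false
positives), indel normalization (multiallelic records are split but not
left-aligned — the pipeline consumes pre-normalized VCFs), real human gene
architecture, linkage between variants, or the behaviour of SpliceAI
itself, whose scores are consumed as annotations throughout.

## Problem sizes and determinism

The shipped tests and scripts use a 30-trio cohort (40 background variants
per trio) for end-to-end recovery, 100 trios for the filter-monotonicity
and step-exclusivity properties, 500 genes per category for the constraint
comparison, and 1000 replicates for the Welch null-uniformity check —
sizes at which every stochastic assertion sits far from its decision
boundary while the whole suite runs in well under a minute. All generator
randomness derives from a single integer seed; an identical configuration
produces byte-identical VCF/BED/TSV output, which the suite asserts
directly.

## Known limitations

* Phasing is transmission-only; a variant carried by both parents can make
  a compound-het pair only with an ambiguity flag, and read-backed phasing
  is out of scope.
* Step 2 runs only for cases whose phenotype maps to a supplied panel;
  panel content is the user's responsibility.
* Exon-extension lengths are computed only for the novel-AG acceptor-gain
  geometry; donor-gain and exon-skipping consequences are reported as
  events with effect `unknown`.
* Copy-number analysis, RNA-seq validation and automated ACMG
  classification are outside the package's scope by design.
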
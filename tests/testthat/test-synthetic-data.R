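test_that("gene-model generation covers contigs, strands and architecture", {
  cfg <- sim_config(seed = 1, n_genes = 10)
  models <- generate_gene_models(cfg)
  expect_length(models, 10L)
  chroms <- vapply(models, `[[`, "", "chrom")
  strands <- vapply(models, `[[`, "", "strand")
  expect_gte(sum(chroms == "chrX"), 1L)
  expect_gte(sum(strands == "-"), 1L)
  for (m in models) {
    expect_true(all(m$exons[, "start"] < m$exons[, "end"]))
    if (nrow(m$exons) > 1L) {
      expect_true(all(diff(m$exons[, "start"]) > 0))
      expect_true(all(m$exons[-1L, "start"] >= m$exons[-nrow(m$exons), "end"]))
    }
  }
  # fixed exon count is honoured
  cfg2 <- sim_config(seed = 2, n_genes = 6, exons_per_gene = c(2, 2))
  ex_counts <- vapply(generate_gene_models(cfg2),
                      function(m) nrow(m$exons), 0L)
  expect_true(all(ex_counts == 2L))
  # genes on one contig never overlap
  models6 <- generate_gene_models(sim_config(seed = 3, n_genes = 18))
  for (chr in unique(vapply(models6, `[[`, "", "chrom"))) {
    on_chr <- Filter(function(m) m$chrom == chr, models6)
    spans <- t(vapply(on_chr, function(m) {
      c(m$exons[1L, "start"], m$exons[nrow(m$exons), "end"])
    }, c(0, 0)))
    spans <- spans[order(spans[, 1L]), , drop = FALSE]
    if (nrow(spans) > 1L) {
      expect_true(all(spans[-1L, 1L] >= spans[-nrow(spans), 2L]))
    }
  }
})

test_that("generator output is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 41, n_trios = 4, n_genes = 18,
                    background_variants_per_trio = 8)
  dirs <- c(withr::local_tempdir(), withr::local_tempdir())
  for (d in dirs) {
    models <- generate_gene_models(cfg)
    cohort <- generate_trio_cohort(cfg, models)
    write_cohort(cohort, d)
  }
  files <- list.files(dirs[1L])
  expect_gt(length(files), 5L)
  for (f in files) {
    expect_identical(readLines(file.path(dirs[1L], f)),
                     readLines(file.path(dirs[2L], f)),
                     label = f)
  }
})

test_that("constraint sampling puts X-linked categories below AD", {
  cfg <- sim_config(seed = 13)
  tab <- generate_constraint_table(cfg, n_per_category = 500)$constraint
  by_cat <- tapply(tab$loeuf, tab$category, mean, na.rm = TRUE)
  expect_lt(by_cat[["XLR"]], by_cat[["AD"]])
  expect_lt(by_cat[["XLD"]], by_cat[["AD"]])
  w <- welch_t_test(tab$loeuf[tab$category == "XLD"],
                    tab$loeuf[tab$category == "AD"])
  expect_lt(w$p_value, 0.001)
  expect_true(all(tab$loeuf >= 0, na.rm = TRUE))

  # degenerate distributions collapse to the point mass
  cfg_pt <- sim_config(seed = 13, loeuf_by_category = list(
    XLD = c(0.1, 0), XLR = c(0.1, 0), XLDR = c(0.1, 0), X_other = c(0.1, 0),
    AD = c(0.1, 0), AR = c(0.1, 0), ADR = c(0.1, 0), A_other = c(0.1, 0)),
    missing_loeuf_frac = 0)
  pt <- generate_constraint_table(cfg_pt, n_per_category = 20)$constraint
  expect_true(all(pt$loeuf == 0.1))
})

test_that("backgrounds are Mendelian-consistent unless errors are planted", {
  cfg <- sim_config(seed = 5, n_trios = 6, background_variants_per_trio = 40,
                    planted_spec = default_planted_spec()[0L, ],
                    mendelian_error_rate = 0)
  cohort <- generate_trio_cohort(cfg, generate_gene_models(cfg))
  for (trio in cohort$trios) {
    expect_equal(mendelian_error_rate(trio$variants, trio$pedigree), 0)
  }

  cfg_err <- sim_config(seed = 6, n_trios = 10,
                        background_variants_per_trio = 60,
                        planted_spec = default_planted_spec()[0L, ],
                        mendelian_error_rate = 0.05)
  cohort_err <- generate_trio_cohort(cfg_err, generate_gene_models(cfg_err))
  all_vars <- do.call(rbind, lapply(cohort_err$trios, `[[`, "variants"))
  # observed rate equals the generator's own flag-derived expectation
  observed <- vapply(cohort_err$trios, function(trio) {
    mendelian_error_rate(trio$variants, trio$pedigree)
  }, 0)
  expected <- vapply(cohort_err$trios, function(trio) {
    calls <- classify_variants(trio$variants, trio$pedigree)$inheritance
    sum(trio$variants$mendel_error) / sum(calls != "unclassifiable")
  }, 0)
  expect_equal(observed, expected)
  # and the planted 5% is recovered up to binomial noise on the cohort
  pooled <- mean(all_vars$mendel_error)
  expect_gt(pooled, 0.05 - 3 * sqrt(0.05 * 0.95 / nrow(all_vars)))
  expect_lt(pooled, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(all_vars)))
})

test_that("planted variants classify to their intended inheritance models", {
  cfg <- sim_config(seed = 9)
  cohort <- generate_trio_cohort(cfg, generate_gene_models(cfg))
  expect_equal(nrow(cohort$truth), 5L)
  for (i in seq_len(nrow(cohort$truth))) {
    trio <- cohort$trios[[cohort$truth$case_id[i]]]
    idx <- match(cohort$truth$key[i], variant_key(trio$variants))
    expect_false(is.na(idx))
    call <- classify_genotypes(trio$variants$gt_proband[idx],
                               trio$variants$gt_mother[idx],
                               trio$variants$gt_father[idx],
                               trio$variants$chrom[idx],
                               trio$pedigree$proband_sex)
    expect_equal(call$model, cohort$truth$model[i],
                 label = cohort$truth$label[i])
  }
})

test_that("planted X-hemizygous models refuse an all-female cohort", {
  cfg <- sim_config(seed = 10, proband_sexes = "female")
  expect_error(generate_trio_cohort(cfg, generate_gene_models(cfg)),
               "male proband")
})

test_that("an empty plan with no background yields empty outputs", {
  cfg <- sim_config(seed = 11, n_trios = 2, background_variants_per_trio = 0,
                    planted_spec = default_planted_spec()[0L, ])
  cohort <- generate_trio_cohort(cfg, generate_gene_models(cfg))
  expect_equal(nrow(cohort$truth), 0L)
  for (trio in cohort$trios) expect_equal(nrow(trio$variants), 0L)
  expect_true(all(cohort$ledger$diagnosis_stage == "undiagnosed"))
})

test_that("cohort VCFs round-trip through the trio reader", {
  cfg <- sim_config(seed = 15, n_trios = 2, background_variants_per_trio = 12,
                    planted_spec = default_planted_spec()[0L, ])
  cohort <- generate_trio_cohort(cfg, generate_gene_models(cfg))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  for (trio in cohort$trios) {
    back <- read_trio_vcf(file.path(dir, paste0(trio$case_id, ".vcf")),
                          trio$pedigree)
    cols <- c("chrom", "pos", "ref", "alt",
              "gt_proband", "gt_mother", "gt_father")
    expect_equal(back[, cols], trio$variants[, cols], ignore_attr = TRUE)
  }
})

test_that("the bundled ledger arithmetic is internally consistent", {
  ledger <- bundled_cohort_ledger()
  expect_equal(nrow(ledger), 128L)
  tab <- table(ledger$diagnosis_stage)
  expect_equal(unname(tab[["initial"]]), 51L)
  expect_equal(sum(ledger$diagnosis_stage != "initial"), 77L)
  n_rean <- sum(ledger$diagnosis_stage %in% c("step1", "step2", "step3"))
  expect_equal(n_rean, 4L)
  expect_lte(n_rean, 77L)
  expect_equal(51L + 77L, 128L)
  expect_false(anyDuplicated(ledger$case_id) > 0L)
})
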
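GENOS <- c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt", "missing")

test_that("worked inheritance calls match the trio decision table", {
  # de novo hemizygous on chrX: male proband carries, mother hom-ref
  expect_equal(
    classify_genotypes("hemi_alt", "hom_ref", "hemi_ref", "chrX", "male")$model,
    "x_hemizygous_de_novo")
  # maternally inherited het (autosome)
  expect_equal(
    classify_genotypes("het", "het", "hom_ref", "chr8", "female")$model,
    "inherited_maternal_het")
  # recessive homozygote forced by allele bookkeeping
  expect_equal(
    classify_genotypes("hom_alt", "het", "het", "chr2", "male")$model,
    "autosomal_recessive_hom")
  # non-carrier proband
  expect_equal(
    classify_genotypes("hom_ref", "het", "hom_ref", "chr2", "male")$model,
    "unclassifiable")
  # impossible: hom-alt proband with a hom-ref parent
  expect_equal(
    classify_genotypes("hom_alt", "hom_ref", "het", "chr2", "male")$model,
    "mendelian_error")
  # de novo on chrX in a female proband
  expect_equal(
    classify_genotypes("het", "hom_ref", "hemi_ref", "chrX", "female")$model,
    "de_novo_x")
  # maternally inherited hemizygous
  expect_equal(
    classify_genotypes("hemi_alt", "het", "hemi_ref", "chrX", "male")$model,
    "x_hemizygous_maternal")
  # missing genotype -> unclassifiable
  expect_equal(
    classify_genotypes("het", "missing", "hom_ref", "chr2", "male")$model,
    "unclassifiable")
  # chrY / mitochondrial pass through
  expect_equal(classify_genotypes("hemi_alt", "hom_ref", "hemi_ref", "chrY",
                                  "male")$model, "unclassifiable")
})

test_that("the decision table is exhaustive and deterministic", {
  grid <- expand.grid(p = GENOS, m = GENOS, f = GENOS,
                      chrom = c("chr7", "chrX"),
                      sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  res <- vapply(seq_len(nrow(grid)), function(i) {
    classify_genotypes(grid$p[i], grid$m[i], grid$f[i], grid$chrom[i],
                       grid$sex[i])$model
  }, "")
  # total function over the genotype space, one known model each
  expect_true(all(res %in% triosplice:::INHERITANCE_MODELS))
  # chromosome scoping of models
  x_models <- c("de_novo_x", "x_hemizygous_de_novo", "x_hemizygous_maternal",
                "x_recessive_hom")
  a_models <- c("de_novo_autosomal", "autosomal_recessive_hom")
  expect_false(any(res[grid$chrom == "chr7"] %in% x_models))
  expect_false(any(res[grid$chrom == "chrX"] %in% a_models))
  # repeat evaluation gives identical answers
  res2 <- vapply(seq_len(nrow(grid)), function(i) {
    classify_genotypes(grid$p[i], grid$m[i], grid$f[i], grid$chrom[i],
                       grid$sex[i])$model
  }, "")
  expect_identical(res, res2)
})

test_that("swapping parents swaps maternal/paternal calls on autosomes", {
  swap_map <- c(inherited_maternal_het = "inherited_paternal_het",
                inherited_paternal_het = "inherited_maternal_het")
  grid <- expand.grid(p = GENOS, m = GENOS, f = GENOS,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    a <- classify_genotypes(grid$p[i], grid$m[i], grid$f[i], "chr3", "male")$model
    b <- classify_genotypes(grid$p[i], grid$f[i], grid$m[i], "chr3", "male")$model
    expected <- if (a %in% names(swap_map)) unname(swap_map[a]) else a
    expect_identical(b, expected)
  }
})

test_that("compound-het pairing matches the worked examples", {
  trio <- make_trio("male")
  # one maternal-only + one paternal-only het -> a single unambiguous pair
  v <- mk_vars(
    mk_var("chr1", 100L, "G", "T", "het", "het", "hom_ref", gene = "TMEM67"),
    mk_var("chr1", 900L, "A", "G", "het", "hom_ref", "het", gene = "TMEM67"))
  pairs <- detect_compound_het(v, trio)
  expect_equal(nrow(pairs), 1L)
  expect_false(pairs$ambiguity_flag)
  expect_equal(pairs$maternal_pos, 100L)
  expect_equal(pairs$paternal_pos, 900L)

  # two maternally transmitted hets are cis-by-transmission: no pair
  v2 <- mk_vars(
    mk_var("chr1", 100L, "G", "T", "het", "het", "hom_ref", gene = "G"),
    mk_var("chr1", 900L, "A", "G", "het", "hom_alt", "hom_ref", gene = "G"))
  expect_equal(nrow(detect_compound_het(v2, trio)), 0L)

  # 3 maternal-only x 2 paternal-only -> full cross-product of 6 pairs
  v3 <- do.call(rbind, c(
    lapply(1:3, function(i) mk_var("chr1", 100L * i, "A", "T", "het", "het",
                                   "hom_ref", gene = "G")),
    lapply(4:5, function(i) mk_var("chr1", 100L * i, "A", "T", "het",
                                   "hom_ref", "het", gene = "G"))))
  p3 <- detect_compound_het(v3, trio)
  expect_equal(nrow(p3), 6L)
  expect_false(any(p3$ambiguity_flag))

  # a variant seen in both parents pairs, but ambiguously
  v4 <- mk_vars(
    mk_var("chr1", 100L, "A", "T", "het", "het", "het", gene = "G"),
    mk_var("chr1", 900L, "A", "G", "het", "hom_ref", "het", gene = "G"))
  p4 <- detect_compound_het(v4, trio)
  expect_equal(nrow(p4), 1L)
  expect_true(p4$ambiguity_flag)
})

test_that("compound-het detection equals the brute-force oracle", {
  trio <- make_trio("female")
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(2:8, 1L)
    pos <- sample(1:5000, n)
    v <- do.call(rbind, lapply(seq_len(n), function(i) {
      mk_var("chr5", pos[i], "A", "T",
             gt_proband = sample(c("het", "hom_ref"), 1L, prob = c(0.8, 0.2)),
             gt_mother = sample(c("hom_ref", "het", "hom_alt"), 1L),
             gt_father = sample(c("hom_ref", "het", "hom_alt"), 1L),
             gene = "G")
    }))
    got <- detect_compound_het(v, trio)
    want <- brute_force_comphet(v)
    got_df <- data.frame(
      pair = vapply(seq_len(nrow(got)), function(i) {
        paste(sort(c(got$maternal_key[i], got$paternal_key[i])),
              collapse = "+")
      }, ""),
      ambiguous = got$ambiguity_flag, stringsAsFactors = FALSE)
    got_df <- got_df[order(got_df$pair), , drop = FALSE]
    expect_identical(got_df$pair, want$pair)
    expect_identical(got_df$ambiguous, want$ambiguous)
  }
})

test_that("mendelian error rate counts impossible trios among classifiable ones", {
  trio <- make_trio("male")
  consistent <- mk_vars(
    mk_var("chr1", 1L, gt_proband = "het", gt_mother = "het"),
    mk_var("chr1", 2L, gt_proband = "hom_alt", gt_mother = "het",
           gt_father = "het"))
  expect_equal(mendelian_error_rate(consistent, trio), 0)

  impossible <- mk_var("chr1", 3L, gt_proband = "hom_alt",
                       gt_mother = "hom_ref", gt_father = "hom_ref")
  expect_equal(mendelian_error_rate(impossible, trio), 1)
  expect_equal(mendelian_error_rate(rbind(consistent, impossible), trio), 1 / 3)

  expect_error(mendelian_error_rate(empty_variant_table(), trio), "empty")
})
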
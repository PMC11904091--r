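test_that("intron offsets follow HGVS orientation on both strands", {
  m <- toy_model("+")  # exons [1000,1200) and [2000,2200), intron 1200..2000
  # 3 bases past the donor (exon 1 ends at 1-based 1200)
  expect_equal(intron_offset(1203, m), list(offset = 3L, region = "intronic"))
  # 6 bases before the acceptor (exon 2 starts at 1-based 2001)
  expect_equal(intron_offset(1995, m), list(offset = -6L, region = "intronic"))
  # canonical +/-2 window
  expect_equal(intron_offset(1201, m),
               list(offset = 1L, region = "canonical_splice_site"))
  expect_equal(intron_offset(1999, m),
               list(offset = -2L, region = "canonical_splice_site"))
  # inside an exon / outside the model
  expect_equal(intron_offset(1100, m)$region, "exonic")
  expect_equal(intron_offset(50, m)$region, "intergenic")
  expect_equal(intron_offset(9999, m)$region, "intergenic")

  # minus strand: the donor sits at the genomically-right exon
  mm <- toy_model("-")
  expect_equal(intron_offset(1998, mm), list(offset = 3L, region = "intronic"))
  expect_equal(intron_offset(1206, mm), list(offset = -6L, region = "intronic"))
})

test_that("intron_position inverts intron_offset", {
  for (strand in c("+", "-")) {
    m <- toy_model(strand)
    for (off in c(-150L, -6L, -2L, -1L, 1L, 2L, 3L, 150L)) {
      pos <- intron_position(m, 1L, off)
      expect_equal(intron_offset(pos, m)$offset, off,
                   label = paste("strand", strand, "offset", off))
    }
  }
})

test_that("offsets are invariant under coordinate reflection with strand flip", {
  set.seed(99)
  for (rep in 1:40) {
    n_ex <- sample(2:5, 1)
    lens <- sample(50:200, n_ex, replace = TRUE)
    gaps <- sample(300:2000, n_ex - 1, replace = TRUE)
    starts <- cumsum(c(1000, head(lens, -1) + gaps))
    strand <- sample(c("+", "-"), 1)
    m <- gene_model("G", "G.t1", "chr1", strand, cbind(starts, starts + lens))
    C <- max(starts + lens) + 5000
    refl_exons <- cbind(C - (starts + lens), C - starts)
    m_refl <- gene_model("G", "G.t1", "chr1",
                         if (strand == "+") "-" else "+", refl_exons)
    span <- c(starts[1] + 1, max(starts + lens))
    for (pos in sample(span[1]:span[2], 20)) {
      a <- intron_offset(pos, m)
      b <- intron_offset(C - pos + 1, m_refl)
      expect_identical(a, b)
    }
  }
})

test_that("the screening window admits exonic and near-boundary positions", {
  expect_true(in_window(-6L, 150))
  expect_true(in_window(NA_integer_, 150))  # exonic
  expect_true(in_window(150L, 150))
  expect_false(in_window(151L, 150))
  expect_false(in_window(-200L, 150))
})

test_that("max_delta aggregates the four SpliceAI deltas", {
  # dominant acceptor loss
  expect_equal(max_delta(splice_scores(ag = 0.80, al = 0.97)), 0.97)
  # a weak donor loss fails the 0.2 screen on its own
  expect_equal(max_delta(splice_scores(dl = 0.05)), 0.05)
  expect_equal(max_delta(splice_scores()), 0)
  # missing scores yield NA, not 0
  v <- mk_var()
  expect_true(is.na(max_delta(v)))
  # component-wise lower bound
  set.seed(5)
  ds <- matrix(runif(400), ncol = 4)
  s <- data.frame(ds_ag = ds[, 1], ds_al = ds[, 2], ds_dg = ds[, 3],
                  ds_dl = ds[, 4])
  md <- max_delta(s)
  expect_true(all(md >= ds))
})

test_that("percent motif variation reproduces the four worked examples exactly", {
  m <- worked_example_metrics()
  pv <- percent_motif_variation(m$maxent_ref, m$maxent_alt)
  expect_equal(pv[m$gene == "MED12"], -84.95)
  expect_equal(round(pv[m$gene == "CCDC22"], 1), -26.9)
  expect_equal(round(pv[m$gene == "TMEM67"], 1), -117.8)
  expect_equal(round(pv[m$gene == "CASK"], 1), -57.3)

  # identity and scale invariance
  expect_equal(percent_motif_variation(3.7, 3.7), 0)
  set.seed(8)
  for (i in 1:20) {
    r <- runif(1, -10, 10); a <- runif(1, -10, 10); c <- runif(1, 0.1, 50)
    if (abs(r) < 1e-6) next
    expect_equal(percent_motif_variation(c * r, c * a),
                 percent_motif_variation(r, a), tolerance = 0.011)
  }
  expect_error(percent_motif_variation(0, 5), "undefined")
})

test_that("splice consequences follow the dominant event and geometry", {
  # acceptor gain at -6 creating a novel AG: 5-bp exon extension
  cask <- infer_consequence(-6L, splice_scores(ag = 0.9, al = 0.13), alt = "G")
  expect_equal(cask$event, "acceptor_gain")
  expect_equal(cask$predicted_effect, "exon_extension")
  expect_equal(cask$affected_length_bp, 5L)

  # donor loss at +3: read-through, intron retention
  tmem <- infer_consequence(3L, splice_scores(dl = 0.38), alt = "G")
  expect_equal(tmem$event, "donor_loss")
  expect_equal(tmem$predicted_effect, "intron_retention")
  expect_true(is.na(tmem$affected_length_bp))

  # no signal at all
  none <- infer_consequence(10L, splice_scores(), alt = "A")
  expect_equal(none$event, "none")
  expect_equal(none$predicted_effect, "unknown")

  # acceptor gain without the novel-AG base is not called an extension
  notg <- infer_consequence(-6L, splice_scores(ag = 0.9), alt = "T")
  expect_equal(notg$predicted_effect, "unknown")

  # dominant acceptor loss at a canonical acceptor: event reported,
  # effect left open
  med12 <- infer_consequence(-1L, splice_scores(ag = 0.80, al = 0.97),
                             alt = "C")
  expect_equal(med12$event, "acceptor_loss")
  expect_equal(med12$predicted_effect, "unknown")
})

test_that("variant screening combines window, region and delta evidence", {
  vars <- mk_vars(
    mk_var("chrX", 1L, region = "intronic", intron_offset = -6L, ds_ag = 0.9),
    mk_var("chr1", 2L, region = "intronic", intron_offset = -50L, ds_ag = 0.1),
    mk_var("chr1", 3L, region = "exonic"),
    mk_var("chr1", 4L, region = "canonical_splice_site", intron_offset = 1L),
    mk_var("chr1", 5L, region = "intronic", intron_offset = 200L, ds_al = 0.95),
    mk_var("chr1", 6L, region = "intronic", intron_offset = 10L, ds_dl = 0.05,
           pangolin_loss = 0.22))
  scr <- screen_variants(vars)
  expect_equal(scr$pass, c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_match(scr$tags[1], "spliceai_delta")
  expect_match(scr$tags[5], "out_of_window")
  # Pangolin disagreement is annotated, never gating
  expect_match(scr$tags[6], "pangolin_rescue")

  # monotone in the delta threshold: a stricter screen admits no new variant
  set.seed(12)
  rand <- do.call(rbind, lapply(1:50, function(i) {
    mk_var("chr1", i, region = sample(c("exonic", "intronic"), 1),
           intron_offset = if (runif(1) < 0.5) NA_integer_
                           else sample(c(-200:-1, 1:200), 1),
           ds_ag = runif(1), ds_al = runif(1), ds_dg = runif(1),
           ds_dl = runif(1))
  }))
  thresholds <- sort(runif(6, 0.05, 0.9))
  passes <- lapply(thresholds, function(th) screen_variants(rand, th)$pass)
  for (i in seq_len(length(thresholds) - 1L)) {
    expect_true(all(passes[[i]][passes[[i + 1L]]]))
  }
})

test_that("three of the four worked-example variants clear the 0.2 delta screen", {
  m <- worked_example_metrics()
  md <- max_delta(m)
  expect_equal(sum(md > 0.2), 3L)
  expect_equal(m$gene[md <= 0.2], "CCDC22")
})
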
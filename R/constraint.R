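# Gene-constraint gating and the LOEUF-by-inheritance-category comparison.
# LOEUF (loss-of-function observed/expected upper bound fraction) is low for
# genes depleted of LoF variants in the population; genes under ~0.35 are
# haploinsufficiency candidates and anchor the constraint-driven reanalysis
# steps.

#' Constraint gate on a gene's LOEUF score
#'
#' `TRUE` iff the gene has a LOEUF score and it does not exceed the
#' threshold. The boundary is inclusive (a score of exactly 0.35 passes the
#' default gate); genes without a score fail — they cannot be prioritized by
#' constraint, though panel-driven screening still considers them.
#'
#' @param loeuf Numeric vector of LOEUF scores (`NA` = unscored).
#' @param threshold Positive gate threshold (default 0.35).
#' @return Logical vector.
#' @export
passes_constraint_gate <- function(loeuf, threshold = 0.35) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  !is.na(loeuf) & loeuf <= threshold
}

#' Welch's two-sample t test on constraint scores
#'
#' Two-sided Welch (unequal-variance) t test with Welch-Satterthwaite
#' degrees of freedom, as used to compare LOEUF distributions between
#' inheritance-mode categories. Wraps [stats::t.test()]. Degenerate input
#' (both groups essentially constant) returns `t = 0, p = 1` when the means
#' agree and `|t| = Inf, p = 0` otherwise.
#'
#' @param values_a,values_b Numeric vectors with at least two non-missing
#'   values each.
#' @param group_a,group_b Labels for the two groups.
#' @return A one-row data frame: `group_a`, `group_b`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `t_statistic`, `degrees_freedom`, `p_value`.
#' @export
welch_t_test <- function(values_a, values_b, group_a = "a", group_b = "b") {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("welch_t_test: fewer than 2 values in a group")
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  eps <- .Machine$double.eps * 100
  if (va <= eps && vb <= eps) {
    dm <- mean(a) - mean(b)
    t_stat <- if (abs(dm) <= eps) 0 else sign(dm) * Inf
    p <- if (t_stat == 0) 1 else 0
    df <- length(a) + length(b) - 2
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  data.frame(group_a = group_a, group_b = group_b,
             n_a = length(a), n_b = length(b),
             mean_a = mean(a), mean_b = mean(b),
             t_statistic = t_stat, degrees_freedom = df, p_value = p,
             stringsAsFactors = FALSE)
}

#' Compare LOEUF distributions across inheritance-mode categories
#'
#' Classifies every gene in a constraint table into the eight mode
#' categories (see [mode_category()]), summarizes LOEUF per category
#' (n, mean, median), and runs Welch's t test of each X-linked category
#' (XLD, XLR, XLDR, X_other) against autosomal-dominant (AD) genes — the
#' comparison under which X-linked disease genes show systematically lower
#' (more constrained) scores. Categories with fewer than two scored genes
#' are skipped with a warning. Raw two-sided p values are reported together
#' with a Bonferroni-adjusted column over the emitted comparisons.
#'
#' @param constraint_table A constraint table (see
#'   [read_annotation_table()]); needs `gene`, `loeuf`, `modes`,
#'   `chrom_class` columns.
#' @return A list with `summary` (per-category data frame) and
#'   `comparisons` (one row per X-category-vs-AD Welch test, possibly
#'   zero rows).
#' @export
compare_loeuf_by_inheritance <- function(constraint_table) {
  tab <- constraint_table
  tab$category <- mode_category(tab$modes, tab$chrom_class)
  cats <- c("AD", "ADR", "AR", "A_other", "XLD", "XLR", "XLDR", "X_other")
  present <- intersect(cats, unique(tab$category))
  summary <- do.call(rbind, lapply(present, function(cat) {
    lo <- tab$loeuf[tab$category == cat]
    data.frame(category = cat, n = length(lo), n_scored = sum(!is.na(lo)),
               mean_loeuf = mean(lo, na.rm = TRUE),
               median_loeuf = stats::median(lo, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL

  empty <- data.frame(group_a = character(0), group_b = character(0),
                      n_a = integer(0), n_b = integer(0),
                      mean_a = numeric(0), mean_b = numeric(0),
                      t_statistic = numeric(0), degrees_freedom = numeric(0),
                      p_value = numeric(0), p_bonferroni = numeric(0),
                      stringsAsFactors = FALSE)
  ad <- tab$loeuf[tab$category == "AD" & !is.na(tab$loeuf)]
  if (length(ad) < 2L) {
    warning("fewer than 2 scored AD genes; no comparisons performed")
    return(list(summary = summary, comparisons = empty))
  }
  comparisons <- list()
  for (cat in c("XLD", "XLR", "XLDR", "X_other")) {
    x <- tab$loeuf[tab$category == cat & !is.na(tab$loeuf)]
    if (length(x) < 2L) {
      if (cat %in% present) {
        warning("category ", cat, " has fewer than 2 scored genes; skipped")
      }
      next
    }
    comparisons[[cat]] <- welch_t_test(x, ad, group_a = cat, group_b = "AD")
  }
  if (!length(comparisons)) {
    return(list(summary = summary, comparisons = empty))
  }
  comp <- do.call(rbind, comparisons)
  comp$p_bonferroni <- pmin(1, comp$p_value * nrow(comp))
  rownames(comp) <- NULL
  list(summary = summary, comparisons = comp)
}
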
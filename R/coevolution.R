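# Co-evolution tests: do epistatically interacting gene pairs have more
# similar evolutionary rates (dN/dS) than random pairs? The similarity
# statistic is the mean absolute rate difference over pairs; the null is
# built by resampling the same number of random distinct-gene pairs from the
# rate table, and the empirical p uses the plus-one rule so it is never
# exactly zero.

#' Read a gene evolutionary-rate table
#'
#' Two-column TSV (gene id, rate); a header line is detected and skipped
#' automatically. Rates must be finite and non-negative.
#'
#' @param path path to the TSV.
#' @return A tibble: `gene`, `rate`.
#' @export
read_rate_table <- function(path) {
  first <- readr::read_tsv(path, col_names = FALSE, n_max = 1,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  has_header <- suppressWarnings(is.na(as.numeric(first[[2]][1])))
  tb <- readr::read_tsv(path, col_names = c("gene", "rate"),
                        skip = if (has_header) 1L else 0L,
                        col_types = "cd", progress = FALSE)
  if (any(!is.finite(tb$rate)) || any(tb$rate < 0)) {
    abort("rate table contains non-finite or negative rates")
  }
  if (anyDuplicated(tb$gene)) abort("duplicate gene in rate table")
  tb
}

rate_lookup <- function(rates) {
  setNames(rates$rate, rates$gene)
}

# pairs scorable in the rate table, with a logged count of exclusions
scorable_pairs <- function(pairs, lookup, context) {
  ok <- pairs$gene_a %in% names(lookup) & pairs$gene_b %in% names(lookup)
  dropped <- sum(!ok)
  if (dropped > 0L) {
    message(sprintf("%s: %d of %d pairs dropped (gene missing from rate table)",
                    context, dropped, nrow(pairs)))
  }
  pairs[ok, , drop = FALSE]
}

#' Resampling test for rate similarity of interacting pairs
#'
#' Observed statistic: mean `|rate_a - rate_b|` over the given pairs. Null:
#' the same number of random distinct-gene pairs drawn uniformly from the
#' rate universe, `n_resamples` times. The left-tail empirical p (similarity
#' means a *smaller* difference) uses the plus-one rule
#' `p = (1 + #{null <= observed}) / (1 + N)`.
#'
#' @param pairs tibble with `gene_a`, `gene_b`.
#' @param rates tibble with `gene`, `rate` (see [read_rate_table()]).
#' @param n_resamples number of null resamples (default 10000; must be >= 1).
#' @param seed integer seed for reproducibility.
#' @param universe optional character vector restricting the resampling
#'   universe (e.g. model genes); default all genes in `rates`.
#' @return An object of class `rate_resample_test`: list with `observed`,
#'   `null` (numeric vector of null means), `p`, `n_pairs`, `n_resamples`,
#'   `seed`.
#' @export
pair_rate_test <- function(pairs, rates, n_resamples = 10000, seed = 1,
                           universe = NULL) {
  if (n_resamples < 1) abort("n_resamples must be at least 1")
  lookup <- rate_lookup(rates)
  if (!is.null(universe)) lookup <- lookup[names(lookup) %in% universe]
  if (length(lookup) < 2L) abort("rate universe has fewer than 2 genes")
  sp <- scorable_pairs(pairs, lookup, "pair_rate_test")
  m <- nrow(sp)
  if (m == 0L) abort("no scorable pairs: no pair has both genes in the rate table")
  observed <- mean(abs(lookup[sp$gene_a] - lookup[sp$gene_b]))

  vals <- unname(lookup)
  ng <- length(vals)
  null <- with_seed(seed, {
    i <- sample.int(ng, n_resamples * m, replace = TRUE)
    j <- sample.int(ng - 1L, n_resamples * m, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j) # distinct-gene pairs
    d <- abs(vals[i] - vals[j])
    colMeans(matrix(d, nrow = m))
  })
  p <- (1 + sum(null <= observed + 1e-12)) / (1 + n_resamples)
  structure(
    list(observed = observed, null = null, p = p, n_pairs = m,
         n_resamples = n_resamples, seed = seed),
    class = "rate_resample_test"
  )
}

#' @export
print.rate_resample_test <- function(x, ...) {
  cat(sprintf(
    "<rate_resample_test> %d pairs: observed mean |rate diff| = %.4f, null mean = %.4f, p = %.4g (%d resamples)\n",
    x$n_pairs, x$observed, mean(x$null), x$p, x$n_resamples))
  invisible(x)
}

#' @export
#' @method tidy rate_resample_test
tidy.rate_resample_test <- function(x, ...) {
  tibble(
    observed = x$observed,
    null_mean = mean(x$null),
    null_sd = stats::sd(x$null),
    p_value = x$p,
    n_pairs = x$n_pairs,
    n_resamples = x$n_resamples
  )
}

#' @export
#' @method glance rate_resample_test
glance.rate_resample_test <- function(x, ...) {
  tidy.rate_resample_test(x)
}

welch_row <- function(a, b) {
  degenerate <- length(a) < 2L || length(b) < 2L ||
    (stats::var(a) == 0 && stats::var(b) == 0)
  if (degenerate) {
    return(tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                  mean_a = mean(a), mean_b = mean(b),
                  n_a = length(a), n_b = length(b), degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
         n_a = length(a), n_b = length(b), degenerate = FALSE)
}

#' Welch t-test on the rates of two gene groups
#'
#' Two-sided Welch t-test comparing per-gene evolutionary rates between two
#' gene sets (a gene in both groups is counted in both). Degenerate inputs
#' (group smaller than 2, or both groups with zero variance) are flagged
#' rather than tested.
#'
#' @param genes_a,genes_b character vectors of gene ids.
#' @param rates tibble with `gene`, `rate`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`, `degenerate`.
#' @export
group_rate_ttest <- function(genes_a, genes_b, rates) {
  lookup <- rate_lookup(rates)
  a <- lookup[intersect(unique(genes_a), names(lookup))]
  b <- lookup[intersect(unique(genes_b), names(lookup))]
  if (length(a) < 2L || length(b) < 2L) {
    abort("both groups need at least 2 genes with rates")
  }
  welch_row(unname(a), unname(b))
}

#' Welch t-test on per-pair rate differences of two pair sets
#'
#' Computes `|rate_a - rate_b|` per pair in each set and compares the two
#' difference samples with a two-sided Welch t-test. A single pair per side
#' is flagged degenerate.
#'
#' @param pairs_a,pairs_b tibbles with `gene_a`, `gene_b`.
#' @param rates tibble with `gene`, `rate`.
#' @return One-row tibble as in [group_rate_ttest()].
#' @export
pair_vs_pair_ttest <- function(pairs_a, pairs_b, rates) {
  lookup <- rate_lookup(rates)
  sa <- scorable_pairs(pairs_a, lookup, "pair_vs_pair_ttest (set a)")
  sb <- scorable_pairs(pairs_b, lookup, "pair_vs_pair_ttest (set b)")
  if (nrow(sa) == 0L || nrow(sb) == 0L) abort("no scorable pairs in one of the sets")
  da <- abs(lookup[sa$gene_a] - lookup[sa$gene_b])
  db <- abs(lookup[sb$gene_a] - lookup[sb$gene_b])
  welch_row(unname(da), unname(db))
}
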
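test_that("the epistasis value is the product deviation", {
  expect_equal(epistasis(1, 1, 1), 0)
  expect_equal(epistasis(0.5, 0.5, 0.5), 0.25) # within-pathway masking
  expect_equal(epistasis(1, 1, 0.5), -0.5) # redundant-branch sickness
  expect_equal(epistasis(c(1, 0.5), c(1, 0.5), c(1, 0.5)), c(0, 0.25))
})

test_that("condition records carry exact epsilons and threshold flags", {
  sc <- fitness_screen(fx_condition("parallel"))
  rec <- condition_epistasis(sc, threshold = 0.01)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$epsilon, -0.5, tolerance = 1e-9)
  expect_true(rec$passes)
  expect_equal(rec$sign, -1)
  # stored epsilon satisfies its defining equation bit-exactly
  expect_identical(rec$epsilon, rec$W_xy - rec$W_x * rec$W_y)
  # a harsher threshold removes the record from the network
  rec06 <- condition_epistasis(sc, threshold = 0.6)
  expect_equal(nrow(rec06), 1L)
  expect_false(any(rec06$passes))
  # records cover C(n,2) pairs regardless of threshold
  tc <- twocarbon_records()
  expect_equal(nrow(tc$records$reference), choose(4, 2))
  # a missing single aborts naming the gene
  broken <- sc[!(is.na(sc$gene_b) & sc$gene_a == "g1"), ]
  expect_error(condition_epistasis(broken), "missing single-mutant fitness")
})

test_that("threshold monotonicity: raising the threshold never adds pairs", {
  rec <- twocarbon_records()$records$alt_carbon
  thresholds <- c(0.01, 0.05, 0.2, 0.3)
  passing <- vapply(thresholds, function(th) {
    sum(abs(rec$epsilon) >= th)
  }, numeric(1))
  expect_true(all(diff(passing) <= 0))
})

test_that("differential epistasis detects the planted condition switch", {
  tc <- twocarbon_records()
  d <- differential_epistasis(tc$records$alt_carbon, tc$records$reference)
  planted <- d[d$gene_a == "g3" & d$gene_b == "g4", ]
  expect_equal(planted$d_epsilon, 0.25, tolerance = 1e-9)
  expect_true(planted$passes)
  expect_equal(planted$sign, 1)
  # the stable pathway pair does not move
  stable <- d[d$gene_a == "g1" & d$gene_b == "g2", ]
  expect_equal(stable$d_epsilon, 0, tolerance = 1e-9)
  # identical records give all-zero differentials
  d0 <- differential_epistasis(tc$records$reference, tc$records$reference)
  expect_true(all(abs(d0$d_epsilon) < 1e-12))
  expect_false(any(d0$passes))
  # mismatched universes error
  expect_error(
    differential_epistasis(tc$records$alt_carbon,
                           tc$records$reference[-1, ]),
    "universe"
  )
})

test_that("sign summaries match the exact binomial tail sum", {
  universe <- gene_pairs(sprintf("g%03d", 1:15))
  signs <- c(rep(1, 72), rep(-1, 28), rep(0, nrow(universe) - 100))
  d <- tibble::tibble(
    condition = "x",
    gene_a = universe$gene_a, gene_b = universe$gene_b,
    epsilon_ref = 0, epsilon_cond = 0.02 * signs,
    d_epsilon = 0.02 * signs,
    passes = signs != 0, sign = signs, sign_change = FALSE
  )
  ss <- sign_summary(d)
  expect_equal(ss$n_positive, 72)
  expect_equal(ss$n_negative, 28)
  expect_equal(ss$ratio, 72 / 28)
  expect_lt(ss$binomial_p, 1e-4)
  expect_equal(ss$binomial_p, oracle_binom_two_sided(72, 100),
               tolerance = 1e-10)
  # a couple more count configurations against the brute tail sum
  for (k in c(5, 50, 95)) {
    di <- d[seq_len(100), ]
    di$sign <- c(rep(1, k), rep(-1, 100 - k))
    di$passes <- TRUE
    expect_equal(sign_summary(di)$binomial_p, oracle_binom_two_sided(k, 100),
                 tolerance = 1e-10, label = paste("k =", k))
  }
})

test_that("similarity is the shared-sign overlap over the union", {
  universe <- gene_pairs(c("a", "b", "c", "d"))
  ra <- toy_records(universe, c("a|b" = 1, "a|c" = 1))
  rb <- toy_records(universe, c("a|c" = 1, "a|d" = -1))
  # union of 3 passing pairs, 1 shared with equal sign
  expect_equal(epistasis_similarity(ra, rb), 100 / 3, tolerance = 1e-9)
  # symmetry
  expect_equal(epistasis_similarity(ra, rb), epistasis_similarity(rb, ra))
  # self-similarity and disjoint sets
  expect_equal(epistasis_similarity(ra, ra), 100)
  rc <- toy_records(universe, c("b|c" = 1))
  expect_equal(epistasis_similarity(ra, rc), 0)
  # empty union is flagged undefined
  r0 <- toy_records(universe, c())
  expect_warning(s0 <- epistasis_similarity(r0, r0), "undefined")
  expect_true(is.na(s0))
  # matrix form
  sm <- similarity_matrix(list(a = ra, b = rb, c = rc))
  expect_equal(nrow(sm), 3L)
  expect_equal(sm$similarity[sm$condition_a == "a" & sm$condition_b == "b"],
               100 / 3, tolerance = 1e-9)
})

test_that("stability classes split interactions by condition count", {
  tc <- twocarbon_records()
  st <- epistasis_stability(tc$records[c("glucose_low", "alt_carbon")])
  pair <- function(a, b) st[st$gene_a == a & st$gene_b == b, ]
  expect_equal(pair("g1", "g2")$class, "stable")
  expect_equal(pair("g3", "g4")$class, "dynamic")
  expect_equal(pair("g1", "g2")$n_conditions, 2L)
  # histogram bins sum to the number of ever-passing pairs
  ever <- sum(st$n_conditions > 0)
  expect_equal(sum(table(st$n_conditions[st$n_conditions > 0])), ever)
  # per-condition class fractions sum to 1
  fr <- stability_fractions(st, tc$records[c("glucose_low", "alt_carbon")])
  sums <- tapply(fr$fraction, fr$condition, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
  expect_error(epistasis_stability(tc$records["reference"]), "at least 2")
})

test_that("system correlations use average-rank Spearman with exact small-n p", {
  base <- tibble::tibble(
    condition = sprintf("c%d", 1:6),
    ratio = c(3, 1, 4, 1.5, 9, 2.6)
  )
  # identical and reversed covariates
  s1 <- system_correlations(dplyr::mutate(base, cov = ratio), "cov")
  expect_equal(s1$rho, 1, tolerance = 1e-12)
  s2 <- system_correlations(dplyr::mutate(base, cov = -ratio), "cov")
  expect_equal(s2$rho, -1, tolerance = 1e-12)
  # hand dataset with a tie against the brute-force rank oracle
  cov <- c(2, 2, 5, 1, 7, 3)
  s3 <- system_correlations(dplyr::mutate(base, cov = cov), "cov")
  expect_equal(s3$rho, oracle_spearman_rho(cov, base$ratio), tolerance = 1e-12)
  expect_equal(s3$method, "exact permutation")
  # exact permutation p agrees with enumerating all 720 permutations
  rx <- rank(cov)
  ry <- rank(base$ratio)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  expect_equal(s3$p, mean(abs(rhos) >= abs(s3$rho) - 1e-12), tolerance = 1e-12)
  expect_error(system_correlations(base[1:4, ]), "at least 5")
})

test_that("enrichment matches the hypergeometric tail sum", {
  universe <- sprintf("g%02d", 1:40)
  selected <- universe[1:10]
  ann <- list(term_in = universe[1:5], term_out = universe[30:40],
              term_empty = character(0))
  e <- enrichment(selected, universe, ann)
  row <- e[e$term == "term_in", ]
  expect_equal(row$k, 5L)
  expect_equal(row$p, oracle_hyper_tail(5, 5, 40, 10), tolerance = 1e-12)
  expect_equal(row$fold, (5 / 10) / (5 / 40))
  # selecting the whole universe makes every term unremarkable
  e_all <- enrichment(universe, universe, ann)
  expect_true(all(e_all$p == 1))
  # empty annotation gives an empty table; bad selection errors
  expect_equal(nrow(enrichment(selected, universe, list())), 0L)
  expect_error(enrichment(c(selected, "zz"), universe, ann), "subset")
  # BH adjustment is monotone in p
  expect_true(all(diff(e$q[order(e$p)]) >= -1e-12))
})
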
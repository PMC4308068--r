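# Epistasis statistics: per-condition records, differential epistasis against
# the reference, cross-condition similarity, stability classes, system-level
# Spearman correlations and a generic over-representation test.
#
# Epistasis of a gene pair is epsilon = W_xy - W_x * W_y; an interaction
# "exists" when |epsilon| >= threshold (default 0.01, sensitivity analyses at
# 0.05). All percentage denominators use the full C(n, 2) pair universe.

#' Epistasis value
#'
#' `epsilon = W_xy - W_x * W_y`: positive epistasis is alleviating (the
#' double mutant is fitter than expected from the singles), negative is
#' aggravating, with synthetic lethality as the extreme case.
#'
#' @param W_x,W_y,W_xy relative fitnesses (vectorised).
#' @return Numeric epsilon.
#' @export
epistasis <- function(W_x, W_y, W_xy) {
  W_xy - W_x * W_y
}

#' Per-condition epistasis records from a fitness screen
#'
#' Joins single-mutant fitnesses onto every screened pair and computes
#' epsilon, its sign, and the threshold flag. The set of passing records is
#' that condition's epistasis network.
#'
#' @param screen a [fitness_screen()] tibble for one condition.
#' @param threshold interaction threshold on `|epsilon|` (default 0.01).
#' @return A tibble: `condition`, `gene_a`, `gene_b`, `W_x`, `W_y`, `W_xy`,
#'   `epsilon`, `passes`, `sign`; one row per screened pair.
#' @export
condition_epistasis <- function(screen, threshold = 0.01) {
  stopifnot(threshold > 0)
  if (length(unique(screen$condition)) != 1L) {
    abort("condition_epistasis expects a screen from a single condition")
  }
  singles <- screen |> dplyr::filter(is.na(.data$gene_b))
  doubles <- screen |> dplyr::filter(!is.na(.data$gene_b))
  w1 <- setNames(singles$W, singles$gene_a)
  miss <- setdiff(unique(c(doubles$gene_a, doubles$gene_b)), names(w1))
  if (length(miss) > 0L) {
    abort(paste0("missing single-mutant fitness for gene(s): ",
                 paste(miss, collapse = ", ")))
  }
  out <- doubles |>
    dplyr::transmute(
      condition = .data$condition,
      gene_a = .data$gene_a,
      gene_b = .data$gene_b,
      W_x = unname(w1[.data$gene_a]),
      W_y = unname(w1[.data$gene_b]),
      W_xy = .data$W,
      epsilon = epistasis(.data$W_x, .data$W_y, .data$W_xy)
    ) |>
    dplyr::mutate(
      passes = abs(.data$epsilon) >= threshold,
      sign = sign(.data$epsilon)
    )
  dupes <- out$gene_a[duplicated(pair_key(out$gene_a, out$gene_b))]
  if (length(dupes) > 0L) {
    abort(paste0("duplicate fitness record for pair starting at gene ",
                 dupes[1]))
  }
  out
}

check_same_universe <- function(records_a, records_b) {
  ka <- sort(pair_key(records_a$gene_a, records_a$gene_b))
  kb <- sort(pair_key(records_b$gene_a, records_b$gene_b))
  if (length(ka) != length(kb) || any(ka != kb)) {
    abort("records do not share the same gene-pair universe")
  }
}

#' Differential epistasis between a condition and the reference
#'
#' `d_epsilon` is the change in epsilon from the reference (abundant-glucose)
#' environment to the perturbed condition, per gene pair; a pair passes when
#' `|d_epsilon| >= d_threshold`.
#'
#' @param records_cond,records_ref [condition_epistasis()] tibbles over the
#'   same pair universe.
#' @param d_threshold differential threshold (default 0.01; 0.05 as the
#'   sensitivity setting).
#' @return A tibble: `condition`, `gene_a`, `gene_b`, `epsilon_ref`,
#'   `epsilon_cond`, `d_epsilon`, `passes`, `sign`, `sign_change` (the pair
#'   passes the epsilon threshold in both environments with opposite sign).
#' @export
differential_epistasis <- function(records_cond, records_ref,
                                   d_threshold = 0.01) {
  stopifnot(d_threshold > 0)
  check_same_universe(records_cond, records_ref)
  ref <- records_ref |>
    dplyr::select("gene_a", "gene_b",
                  epsilon_ref = "epsilon", passes_ref = "passes",
                  sign_ref = "sign")
  records_cond |>
    dplyr::select("condition", "gene_a", "gene_b",
                  epsilon_cond = "epsilon", passes_cond = "passes",
                  sign_cond = "sign") |>
    dplyr::inner_join(ref, by = c("gene_a", "gene_b")) |>
    dplyr::transmute(
      condition = .data$condition,
      gene_a = .data$gene_a,
      gene_b = .data$gene_b,
      epsilon_ref = .data$epsilon_ref,
      epsilon_cond = .data$epsilon_cond,
      d_epsilon = .data$epsilon_cond - .data$epsilon_ref,
      passes = abs(.data$d_epsilon) >= d_threshold,
      sign = sign(.data$d_epsilon),
      sign_change = .data$passes_ref & .data$passes_cond &
        .data$sign_ref * .data$sign_cond < 0
    )
}

#' Sign summary of passing differential records
#'
#' Counts passing differential records by sign and tests the positive:
#' negative imbalance with a two-sided exact binomial test against 0.5.
#'
#' @param diff_records a [differential_epistasis()] tibble (one condition).
#' @return One-row tibble: `condition`, `n_positive`, `n_negative`, `ratio`
#'   (`NA` when there are no negatives), `prop_positive`, `binomial_p`.
#' @export
sign_summary <- function(diff_records) {
  passing <- diff_records |> dplyr::filter(.data$passes)
  n_pos <- sum(passing$sign > 0)
  n_neg <- sum(passing$sign < 0)
  p <- if (n_pos + n_neg > 0) {
    binom.test(n_pos, n_pos + n_neg, p = 0.5,
               alternative = "two.sided")$p.value
  } else {
    NA_real_
  }
  tibble(
    condition = unique(diff_records$condition)[1],
    n_positive = n_pos,
    n_negative = n_neg,
    ratio = if (n_neg > 0) n_pos / n_neg else NA_real_,
    prop_positive = if (n_pos + n_neg > 0) n_pos / (n_pos + n_neg) else NA_real_,
    binomial_p = p
  )
}

#' Epistatic similarity between two conditions
#'
#' The percentage of gene pairs with a similar epistatic relation: pairs
#' passing the threshold in both conditions with the same sign (overlap),
#' divided by pairs passing in either condition (union), times 100.
#'
#' @param records_a,records_b [condition_epistasis()] tibbles over the same
#'   pair universe.
#' @return Percentage in `[0, 100]`; `NA` (with a warning) when the union is
#'   empty.
#' @export
epistasis_similarity <- function(records_a, records_b) {
  check_same_universe(records_a, records_b)
  a <- records_a |> dplyr::arrange(.data$gene_a, .data$gene_b)
  b <- records_b |> dplyr::arrange(.data$gene_a, .data$gene_b)
  either <- a$passes | b$passes
  if (!any(either)) {
    warn("no pair passes the threshold in either condition; similarity undefined")
    return(NA_real_)
  }
  both_same <- a$passes & b$passes & a$sign == b$sign
  100 * sum(both_same) / sum(either)
}

#' Pairwise similarity matrix across conditions
#'
#' @param records_list named list of [condition_epistasis()] tibbles.
#' @return A tibble of all unordered condition pairs with their similarity
#'   percentage: `condition_a`, `condition_b`, `similarity`.
#' @export
similarity_matrix <- function(records_list) {
  nms <- names(records_list)
  stopifnot(length(nms) >= 2L)
  cmb <- combn(nms, 2L)
  tibble(
    condition_a = cmb[1L, ],
    condition_b = cmb[2L, ],
    similarity = vapply(seq_len(ncol(cmb)), function(i) {
      suppressWarnings(
        epistasis_similarity(records_list[[cmb[1L, i]]],
                             records_list[[cmb[2L, i]]]))
    }, numeric(1))
  )
}

#' Stability of epistatic interactions across conditions
#'
#' Counts, for every gene pair, the number of conditions in which its
#' epistasis passes the threshold, and assigns the stability class:
#' `"dynamic"` (exactly 1 condition), `"stable"` (all conditions),
#' `"intermediate"` (in between), `"none"` (never passes).
#'
#' @param records_list named list of [condition_epistasis()] tibbles with
#'   equal pair universes (>= 2 conditions).
#' @return An object of class `epistasis_stability`: a tibble `gene_a`,
#'   `gene_b`, `n_conditions`, `class`, with the number of conditions `K` as
#'   attribute `n_conditions_total`.
#' @export
epistasis_stability <- function(records_list) {
  K <- length(records_list)
  if (K < 2L) abort("stability needs at least 2 screened conditions")
  nms <- names(records_list)
  for (i in seq_len(K - 1L)) {
    check_same_universe(records_list[[i]], records_list[[i + 1L]])
  }
  counts <- records_list |>
    purrr::map(~ dplyr::arrange(.x, .data$gene_a, .data$gene_b)) |>
    purrr::map(~ as.integer(.x$passes)) |>
    purrr::reduce(`+`)
  base <- dplyr::arrange(records_list[[1L]], .data$gene_a, .data$gene_b)
  out <- tibble(
    gene_a = base$gene_a,
    gene_b = base$gene_b,
    n_conditions = counts,
    class = dplyr::case_when(
      counts == 0L ~ "none",
      counts == 1L ~ "dynamic",
      counts == K ~ "stable",
      TRUE ~ "intermediate"
    )
  )
  structure(out, class = c("epistasis_stability", class(out)),
            n_conditions_total = K, condition_names = nms)
}

#' Per-condition stability-class decomposition
#'
#' For each condition, the fraction of its passing pairs that are stable,
#' intermediate, or dynamic overall.
#'
#' @param stability an [epistasis_stability()] table.
#' @param records_list the same named list of records it was built from.
#' @return A tibble: `condition`, `class`, `n`, `fraction`.
#' @export
stability_fractions <- function(stability, records_list) {
  cls <- stability |>
    dplyr::select("gene_a", "gene_b", "class")
  purrr::imap(records_list, function(rec, nm) {
    rec |>
      dplyr::filter(.data$passes) |>
      dplyr::inner_join(cls, by = c("gene_a", "gene_b")) |>
      dplyr::count(.data$class) |>
      dplyr::mutate(condition = nm, fraction = .data$n / sum(.data$n))
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("condition", "class", "n", "fraction")
}

# Spearman rank correlation with average ranks; exact permutation p-value
# below n = 9, t approximation at n >= 9.
spearman_test <- function(x, y) {
  n <- length(x)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- cor(rx, ry)
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_, method = "undefined"))
  if (n < 9) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    list(rho = rho, p = p, method = "exact permutation")
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    list(rho = rho, p = min(1, p), method = "t approximation")
  }
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Correlation of system properties with the positive:negative ratio
#'
#' Rank-correlates condition-level covariates (e.g. essential-gene count,
#' number of nonzero wild-type fluxes, mean single-mutant fitness) against
#' the positive:negative differential-epistasis ratio across conditions.
#'
#' @param summaries a tibble with one row per condition, a `ratio` column,
#'   and one column per covariate.
#' @param covariates character vector of covariate column names; default all
#'   numeric columns except `ratio`.
#' @return A tibble: `property`, `rho`, `p`, `n`, `method`.
#' @export
system_correlations <- function(summaries, covariates = NULL) {
  if (nrow(summaries) < 5L) {
    abort("system_correlations needs at least 5 conditions")
  }
  if (is.null(covariates)) {
    num <- vapply(summaries, is.numeric, logical(1))
    covariates <- setdiff(names(summaries)[num], "ratio")
  }
  dplyr::bind_rows(lapply(covariates, function(cv) {
    keep <- !is.na(summaries$ratio) & !is.na(summaries[[cv]])
    st <- spearman_test(summaries[[cv]][keep], summaries$ratio[keep])
    tibble(property = cv, rho = st$rho, p = st$p, n = sum(keep),
           method = st$method)
  }))
}

#' Condition-level covariate summary
#'
#' Computes, for one condition, the covariates used by
#' [system_correlations()]: the number of essential genes, the number of
#' nonzero wild-type fluxes (`|v| > 1e-9`), and the mean single-mutant
#' relative fitness.
#'
#' @param condition an `fba_condition`.
#' @param screen the condition's [fitness_screen()] tibble.
#' @return One-row tibble: `condition`, `essential_genes`, `active_fluxes`,
#'   `mean_single_W`.
#' @export
condition_summary <- function(condition, screen) {
  singles <- screen |> dplyr::filter(is.na(.data$gene_b))
  tibble(
    condition = condition$name,
    essential_genes = length(condition_essentials(condition)),
    active_fluxes = sum(abs(condition$wildtype_flux) > 1e-9),
    mean_single_W = mean(singles$W)
  )
}

#' Over-representation (enrichment) test
#'
#' Generic hypergeometric over-representation of annotation terms in a gene
#' selection, with Benjamini-Hochberg adjustment. No annotation content is
#' bundled; the map is supplied by the user.
#'
#' @param selected character vector of selected genes.
#' @param universe character vector of background genes (must contain
#'   `selected`).
#' @param annotation named list: term -> character vector of annotated genes.
#' @return A tibble, one row per term: `term`, `k` (selected & annotated),
#'   `K` (annotated in universe), `n` (selected), `N` (universe), `fold`,
#'   `p` (hypergeometric upper tail), `q` (BH).
#' @export
enrichment <- function(selected, universe, annotation) {
  if (length(setdiff(selected, universe)) > 0L) {
    abort("selected genes must be a subset of the universe")
  }
  if (length(annotation) == 0L) {
    return(tibble(term = character(0), k = integer(0), K = integer(0),
                  n = integer(0), N = integer(0), fold = numeric(0),
                  p = numeric(0), q = numeric(0)))
  }
  N <- length(unique(universe))
  n <- length(unique(selected))
  rows <- lapply(names(annotation), function(term) {
    ann <- intersect(annotation[[term]], universe)
    K <- length(ann)
    k <- length(intersect(ann, selected))
    p <- if (K == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term = term, k = k, K = K, n = n, N = N,
           fold = if (K > 0L && n > 0L) (k / n) / (K / N) else NA_real_,
           p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- p.adjust(out$p, method = "BH")
  out
}
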
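# Flux-restriction mutants and relative fitness.
#
# A mutant in gene g restricts every reaction g touches to at most a fraction
# (default 50%) of its wild-type geometric-FBA flux, in the wild-type
# direction: with wild-type flux w the mutant bounds are
# [min(0, f*w), max(0, f*w)] intersected with the original bounds. The cap is
# an inequality, not an equality pin, so mutants are always feasible; a
# wild-type-zero reaction is pinned to zero. A reaction shared by both genes
# of a double mutant receives the identical cap once — uniform restriction,
# no compounding.

#' Apply a flux-restriction mutation to a condition's model
#'
#' @param condition an `fba_condition` (supplies the calibrated model and the
#'   wild-type geometric-FBA flux).
#' @param genes character vector of 1 or 2 gene ids.
#' @param fraction restriction fraction in `[0, 1]` (default 0.5; 0 is a full
#'   knockout, 1 leaves the wild-type optimum admissible).
#' @return The constrained `metabolic_model`.
#' @export
apply_restriction <- function(condition, genes, fraction = 0.5) {
  stopifnot(inherits(condition, "fba_condition"))
  if (length(genes) < 1L) abort("mutant spec needs at least one gene")
  if (fraction < 0 || fraction > 1) abort("fraction must be in [0, 1]")
  m <- condition$model
  missing <- setdiff(genes, model_genes(m))
  if (length(missing) > 0L) {
    abort(paste0("gene(s) absent from model: ", paste(missing, collapse = ", ")))
  }
  w <- condition$wildtype_flux
  rxns <- unique(unlist(m$gene_to_reactions[genes], use.names = FALSE))
  cap <- fraction * w[rxns]
  m$lb[rxns] <- pmax(m$lb[rxns], pmin(0, cap))
  m$ub[rxns] <- pmin(m$ub[rxns], pmax(0, cap))
  m
}

#' Fitness of a restriction mutant
#'
#' Relative fitness `W` is the mutant's optimal growth divided by the
#' condition's wild-type growth. An infeasible restricted model is scored
#' `W = 0` (lethal) with a warning.
#'
#' @inheritParams apply_restriction
#' @return A one-row tibble: `condition`, `gene_a`, `gene_b` (`NA` for a
#'   single mutant), `absolute_growth`, `W`.
#' @export
mutant_fitness <- function(condition, genes, fraction = 0.5) {
  m <- apply_restriction(condition, genes, fraction)
  res <- solve_fba(m)
  growth <- if (res$status == "optimal") {
    res$objective_value
  } else {
    warn(paste0("infeasible mutant {", paste(genes, collapse = ","),
                "} in condition ", condition$name, ": scored W = 0"))
    0
  }
  genes <- sort(genes)
  W <- growth / condition$wildtype_growth
  tibble(
    condition = condition$name,
    gene_a = genes[1],
    gene_b = if (length(genes) > 1L) genes[2] else NA_character_,
    absolute_growth = growth,
    W = W
  )
}

#' Single- and double-mutant fitness screen
#'
#' Computes every single-mutant fitness once, then all double mutants over
#' the requested pairs. With a `cache_dir`, results are written to a TSV
#' stamped with a hash of the condition model, wild-type flux and fraction;
#' a warm cache is returned without any LP solves, and a cache written under
#' a different hash is refused as stale.
#'
#' @param condition an `fba_condition`.
#' @param pairs tibble with columns `gene_a`, `gene_b`; default all
#'   [gene_pairs()] of the model.
#' @param fraction restriction fraction (default 0.5).
#' @param cache_dir optional directory for the on-disk fitness cache.
#' @return A tibble: `condition`, `gene_a`, `gene_b` (`NA` for singles),
#'   `absolute_growth`, `W`, ordered singles first then pairs, each in
#'   canonical order.
#' @export
fitness_screen <- function(condition, pairs = NULL, fraction = 0.5,
                           cache_dir = NULL) {
  stopifnot(inherits(condition, "fba_condition"))
  if (is.null(pairs)) pairs <- gene_pairs(condition$model)
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))

  stamp <- substr(rlang::hash(list(
    model_hash(condition$model), round(condition$wildtype_flux, 10),
    fraction, genes, pair_key(pairs$gene_a, pairs$gene_b)
  )), 1, 12)

  if (!is.null(cache_dir)) {
    safe_name <- gsub("[^A-Za-z0-9_.-]", "_", condition$name)
    hit <- file.path(cache_dir, paste0("fitness_", safe_name, "_", stamp, ".tsv"))
    stale <- setdiff(
      list.files(cache_dir, pattern = paste0("^fitness_", safe_name, "_.*\\.tsv$"),
                 full.names = TRUE),
      hit
    )
    if (length(stale) > 0L) {
      abort(paste0("stale fitness cache for condition ", condition$name,
                   " (model/fraction hash mismatch): ", stale[1],
                   "; delete it to recompute"))
    }
    if (file.exists(hit)) {
      return(readr::read_tsv(hit, col_types = "cccdd", na = "NA",
                             progress = FALSE))
    }
  }

  singles <- dplyr::bind_rows(lapply(genes, function(g) {
    mutant_fitness(condition, g, fraction)
  }))
  doubles <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
    mutant_fitness(condition, c(pairs$gene_a[i], pairs$gene_b[i]), fraction)
  }))
  out <- dplyr::bind_rows(singles, doubles) |>
    dplyr::arrange(!is.na(.data$gene_b), .data$gene_a, .data$gene_b)

  if (!is.null(cache_dir)) {
    if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
    readr::write_tsv(out, hit, na = "NA")
  }
  out
}
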
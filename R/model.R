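# The metabolic_model S3 container: stoichiometry, bounds, objective and
# gene-reaction associations. Kept as a plain list; all analysis results
# downstream are tibbles.

#' Construct a metabolic model
#'
#' A constraint-based metabolic model: a stoichiometric matrix `S` (rows =
#' metabolites, columns = reactions), per-reaction flux bounds, a biomass
#' objective reaction, and a flattened gene-to-reaction association map.
#' Boolean gene-protein-reaction structure (AND/OR) is intentionally reduced
#' to plain membership: mutants restrict every reaction a gene touches
#' uniformly, so complex logic plays no role.
#'
#' @param metabolites character vector of metabolite ids.
#' @param reactions character vector of reaction ids.
#' @param S numeric matrix, `length(metabolites)` rows by
#'   `length(reactions)` columns.
#' @param lb,ub numeric per-reaction flux bounds (uptake through an exchange
#'   reaction is a negative flux; "uptake levels" are magnitudes of that
#'   negative flux).
#' @param objective reaction id of the biomass objective.
#' @param gene_to_reactions named list mapping each gene id to a character
#'   vector of reaction ids. Genes mapping to zero reactions are rejected.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, S, lb, ub, objective,
                            gene_to_reactions = list()) {
  metabolites <- as.character(metabolites)
  reactions <- as.character(reactions)
  S <- as.matrix(S)
  dimnames(S) <- list(metabolites, reactions)
  lb <- setNames(as.numeric(lb), reactions)
  ub <- setNames(as.numeric(ub), reactions)
  m <- structure(
    list(
      metabolites = metabolites,
      reactions = reactions,
      S = S,
      lb = lb,
      ub = ub,
      objective = objective,
      # canonical gene order so reloads and round-trips are element-identical
      gene_to_reactions = lapply(
        gene_to_reactions[order(names(gene_to_reactions))], as.character)
    ),
    class = "metabolic_model"
  )
  validate_model(m)
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: matrix dimensions, `lb <= ub`, objective
#' membership, gene associations pointing at existing reactions, and no gene
#' mapped to zero reactions.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly usable, after passing all checks.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!all(dim(model$S) == c(length(model$metabolites), length(model$reactions)))) {
    abort("stoichiometry dimensions do not match metabolite/reaction lists")
  }
  if (anyDuplicated(model$reactions)) abort("duplicate reaction id")
  if (anyDuplicated(model$metabolites)) abort("duplicate metabolite id")
  bad <- model$lb > model$ub
  if (any(bad)) {
    abort(paste0("lower bound exceeds upper bound for reaction(s): ",
                 paste(model$reactions[bad], collapse = ", ")))
  }
  if (length(model$objective) != 1L || !model$objective %in% model$reactions) {
    abort("no objective defined: objective reaction missing from model")
  }
  g2r <- model$gene_to_reactions
  if (length(g2r) > 0L) {
    if (is.null(names(g2r)) || any(names(g2r) == "")) {
      abort("gene_to_reactions must be a named list")
    }
    if (anyDuplicated(names(g2r))) abort("duplicate gene id")
    n_rxn <- vapply(g2r, length, integer(1))
    if (any(n_rxn == 0L)) {
      abort(paste0("gene(s) mapped to no reaction: ",
                   paste(names(g2r)[n_rxn == 0L], collapse = ", ")))
    }
    unknown <- setdiff(unique(unlist(g2r)), model$reactions)
    if (length(unknown) > 0L) {
      abort(paste0("gene association references unknown reaction(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>\n")
  cat("  metabolites:", length(x$metabolites), "\n")
  cat("  reactions:  ", length(x$reactions),
      sprintf("(%d exchange)", length(exchange_reactions(x))), "\n")
  cat("  genes:      ", length(x$gene_to_reactions), "\n")
  cat("  objective:  ", x$objective, "\n")
  invisible(x)
}

#' Gene ids of a model
#' @param model a `metabolic_model`.
#' @return Character vector of gene ids (association-map order).
#' @export
model_genes <- function(model) {
  names(model$gene_to_reactions)
}

#' Exchange reactions of a model
#'
#' Exchange (boundary) reactions are detected structurally: a column of the
#' stoichiometric matrix with exactly one nonzero entry. Uptake is a negative
#' flux through such a reaction.
#'
#' @param model a `metabolic_model`.
#' @return Character vector of exchange reaction ids.
#' @export
exchange_reactions <- function(model) {
  nz <- colSums(model$S != 0)
  # the biomass drain is also a boundary column in small toys; it is an
  # objective, not a nutrient exchange
  setdiff(model$reactions[nz == 1L], model$objective)
}

#' Gene-reaction association map, both directions
#'
#' @param model a `metabolic_model`.
#' @return A list with `gene_to_reactions` (named list gene -> reaction ids)
#'   and `reaction_to_genes` (named list reaction -> gene ids); the two views
#'   are mutually consistent inverses.
#' @export
gene_reaction_map <- function(model) {
  g2r <- model$gene_to_reactions
  pairs <- tibble(
    gene = rep(names(g2r), lengths(g2r)),
    reaction = unlist(g2r, use.names = FALSE)
  )
  r2g <- split(pairs$gene, pairs$reaction)
  list(
    gene_to_reactions = g2r,
    reaction_to_genes = lapply(r2g, unique)
  )
}

#' All unordered gene pairs
#'
#' Enumerates every unordered pair of genes once, in canonical lexicographic
#' order. This list is the denominator "all gene pairs" used by the
#' percentage statistics downstream.
#'
#' @param x a `metabolic_model` or a character vector of gene ids.
#' @return A tibble with columns `gene_a`, `gene_b` (`gene_a < gene_b`),
#'   `choose(n, 2)` rows.
#' @export
gene_pairs <- function(x) {
  genes <- if (inherits(x, "metabolic_model")) model_genes(x) else as.character(x)
  genes <- sort(unique(genes))
  if (length(genes) < 2L) abort("need at least 2 genes to form pairs")
  cmb <- combn(genes, 2L)
  tibble(gene_a = cmb[1L, ], gene_b = cmb[2L, ])
}

# canonical string key for a pair (used in joins and caches)
pair_key <- function(gene_a, gene_b) {
  paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "\r")
}

# stable content hash of the parts of a model that affect simulation
model_hash <- function(model) {
  rlang::hash(list(
    model$metabolites, model$reactions, round(model$S, 12),
    round(model$lb, 12), round(model$ub, 12), model$objective,
    model$gene_to_reactions
  ))
}
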
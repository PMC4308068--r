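# Synthetic metabolic networks with designed epistasis structure, and
# synthetic evolutionary-rate tables with planted co-evolving pairs.
# Stoichiometric coefficients are small integers so toy LPs are exactly
# solvable and the brute-force oracle used in the tests is exact.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Built-in toy fixtures with known epistasis structure
#'
#' Four hand-designed toy networks covering the canonical interaction motifs:
#'
#' * `"serial"`: a linear pathway `EX -> A -(g1)-> B -(g2)-> C -> biomass`
#'   with uptake cap 10. Within-pathway masking: halving either gene halves
#'   growth, the double mutant is no worse, so epsilon = +0.25.
#' * `"parallel"`: two redundant branches `A -> B` carried by `g1` and `g2`.
#'   Either single mutant is rescued by the other branch (W = 1); the double
#'   is synthetically sick, epsilon = -0.5.
#' * `"shared"`: one reaction catalysed by the g1/g2 complex plus a reporter
#'   step. The uniform single cap gives W_xy = W_x = W_y = 0.5, hence
#'   epsilon = W - W^2 = +0.25.
#' * `"twocarbon"`: a glucose-analog and a low-yield ethanol-analog source.
#'   The downstream pathway pair (g1, g2) is loaded on both carbons (stable
#'   positive epistasis); the alternative-carbon pathway pair (g3, g4)
#'   carries zero flux on glucose (epsilon = 0) and becomes load-bearing on
#'   the alternative carbon (epsilon = +0.25) — a designed condition-specific
#'   (dynamic) interaction.
#'
#' @param name one of `"serial"`, `"parallel"`, `"shared"`, `"twocarbon"`
#'   (case-insensitive; a `"FIXTURE_"` prefix is accepted).
#' @return A list with `model` (a [metabolic_model()]) and `manifest`, the
#'   expected-results record: reference exchange/uptake, wild-type growth,
#'   and a tibble of designed pairs with expected fitnesses, epsilon and
#'   sign per condition.
#' @export
make_fixture <- function(name) {
  key <- tolower(sub("^FIXTURE_", "", toupper(name)))
  switch(
    key,
    serial = {
      model <- metabolic_model(
        metabolites = c("A", "B", "C"),
        reactions = c("EX_A", "R1", "R2", "BIOMASS"),
        S = matrix(c(
          -1, -1, 0, 0,
          0, 1, -1, 0,
          0, 0, 1, -1
        ), nrow = 3, byrow = TRUE),
        lb = c(-10, 0, 0, 0), ub = c(0, 1000, 1000, 1000),
        objective = "BIOMASS",
        gene_to_reactions = list(g1 = "R1", g2 = "R2")
      )
      list(model = model, manifest = list(
        reference_exchange = "EX_A", reference_uptake = 10, wt_growth = 10,
        pairs = tibble(
          condition = "reference", gene_a = "g1", gene_b = "g2",
          W_x = 0.5, W_y = 0.5, W_xy = 0.5, epsilon = 0.25, sign = 1
        )
      ))
    },
    parallel = {
      model <- metabolic_model(
        metabolites = c("A", "B"),
        reactions = c("EX_A", "R1", "R2", "BIOMASS"),
        S = matrix(c(
          -1, -1, -1, 0,
          0, 1, 1, -1
        ), nrow = 2, byrow = TRUE),
        lb = c(-10, 0, 0, 0), ub = c(0, 1000, 1000, 1000),
        objective = "BIOMASS",
        gene_to_reactions = list(g1 = "R1", g2 = "R2")
      )
      list(model = model, manifest = list(
        reference_exchange = "EX_A", reference_uptake = 10, wt_growth = 10,
        geometric_branch_flux = c(R1 = 5, R2 = 5),
        pairs = tibble(
          condition = "reference", gene_a = "g1", gene_b = "g2",
          W_x = 1, W_y = 1, W_xy = 0.5, epsilon = -0.5, sign = -1
        )
      ))
    },
    shared = {
      model <- metabolic_model(
        metabolites = c("A", "B", "C"),
        reactions = c("EX_A", "R1", "R2", "BIOMASS"),
        S = matrix(c(
          -1, -1, 0, 0,
          0, 1, -1, 0,
          0, 0, 1, -1
        ), nrow = 3, byrow = TRUE),
        lb = c(-10, 0, 0, 0), ub = c(0, 1000, 1000, 1000),
        objective = "BIOMASS",
        gene_to_reactions = list(g1 = "R1", g2 = "R1")
      )
      list(model = model, manifest = list(
        reference_exchange = "EX_A", reference_uptake = 10, wt_growth = 10,
        pairs = tibble(
          condition = "reference", gene_a = "g1", gene_b = "g2",
          W_x = 0.5, W_y = 0.5, W_xy = 0.5, epsilon = 0.25, sign = 1
        )
      ))
    },
    twocarbon = {
      # R_EX converts 2 E -> 1 X: the alternative carbon is low-yield (0.5)
      model <- metabolic_model(
        metabolites = c("G", "E", "X", "M", "N", "B"),
        reactions = c("EX_GLC", "EX_ETH", "R_GM", "R_EX", "R_XM",
                      "R_MN", "R_NB", "BIOMASS"),
        S = matrix(c(
          # EX_GLC EX_ETH R_GM R_EX R_XM R_MN R_NB BIOMASS
          -1, 0, -1, 0, 0, 0, 0, 0, # G
          0, -1, 0, -2, 0, 0, 0, 0, # E
          0, 0, 0, 1, -1, 0, 0, 0, # X
          0, 0, 1, 0, 1, -1, 0, 0, # M
          0, 0, 0, 0, 0, 1, -1, 0, # N
          0, 0, 0, 0, 0, 0, 1, -1 # B
        ), nrow = 6, byrow = TRUE),
        lb = c(-10, 0, 0, 0, 0, 0, 0, 0),
        ub = c(0, 0, 1000, 1000, 1000, 1000, 1000, 1000),
        objective = "BIOMASS",
        gene_to_reactions = list(g1 = "R_MN", g2 = "R_NB",
                                 g3 = "R_EX", g4 = "R_XM")
      )
      list(model = model, manifest = list(
        reference_exchange = "EX_GLC", reference_uptake = 10, wt_growth = 10,
        alt_exchange = "EX_ETH", alt_yield = 0.5,
        pairs = dplyr::bind_rows(
          tibble(condition = "reference", gene_a = "g1", gene_b = "g2",
                 W_x = 0.5, W_y = 0.5, W_xy = 0.5, epsilon = 0.25, sign = 1),
          tibble(condition = "reference", gene_a = "g3", gene_b = "g4",
                 W_x = 1, W_y = 1, W_xy = 1, epsilon = 0, sign = 0),
          tibble(condition = "alt_carbon", gene_a = "g1", gene_b = "g2",
                 W_x = 0.5, W_y = 0.5, W_xy = 0.5, epsilon = 0.25, sign = 1),
          tibble(condition = "alt_carbon", gene_a = "g3", gene_b = "g4",
                 W_x = 0.5, W_y = 0.5, W_xy = 0.5, epsilon = 0.25, sign = 1)
        )
      ))
    },
    abort(paste0("unknown fixture name: ", name))
  )
}

#' Generate a random toy network from serial/parallel motifs
#'
#' Composes seeded random pathway motifs into one network sharing a biomass
#' drain that consumes one unit of every motif's product, so each motif is an
#' obligate bottleneck. Serial motifs plant a positive within-pathway
#' epistasis pair; parallel motifs plant a negative redundant-branch pair.
#' The designed sign of every planted pair is recorded alongside the model,
#' which is what the pipeline-recovery checks compare against.
#'
#' @param n_motifs number of motifs (default 10).
#' @param motif `"mixed"` (default), `"serial"` or `"parallel"`.
#' @param uptake_caps integer range motif uptake caps are drawn from.
#' @param seed integer seed; the same seed reproduces the same network.
#' @return A list with `model` and `designed_pairs`
#'   (tibble: `gene_a`, `gene_b`, `motif`, `motif_type`, `expected_sign`).
#' @export
make_random_network <- function(n_motifs = 10, motif = c("mixed", "serial", "parallel"),
                                uptake_caps = 5:15, seed = 1) {
  motif <- match.arg(motif)
  stopifnot(n_motifs >= 1)
  with_seed(seed, {
    types <- switch(motif,
      mixed = sample(c("serial", "parallel"), n_motifs, replace = TRUE),
      rep(motif, n_motifs)
    )
    caps <- sample(uptake_caps, n_motifs, replace = TRUE)

    mets <- character(0)
    rxn_ids <- character(0)
    stoich <- list() # per reaction: named coef vector
    lb <- numeric(0)
    ub <- numeric(0)
    g2r <- list()
    designed <- vector("list", n_motifs)

    add_rxn <- function(id, coefs, lo, hi) {
      rxn_ids <<- c(rxn_ids, id)
      stoich[[id]] <<- coefs
      lb <<- c(lb, lo)
      ub <<- c(ub, hi)
    }

    for (i in seq_len(n_motifs)) {
      a <- sprintf("A%02d", i)
      b <- sprintf("B%02d", i)
      ga <- sprintf("g%02da", i)
      gb <- sprintf("g%02db", i)
      if (types[i] == "serial") {
        cc <- sprintf("C%02d", i)
        mets <- c(mets, a, cc, b)
        add_rxn(sprintf("EX%02d", i), setNames(-1, a), -caps[i], 0)
        add_rxn(sprintf("R%02da", i), setNames(c(-1, 1), c(a, cc)), 0, 1000)
        add_rxn(sprintf("R%02db", i), setNames(c(-1, 1), c(cc, b)), 0, 1000)
        g2r[[ga]] <- sprintf("R%02da", i)
        g2r[[gb]] <- sprintf("R%02db", i)
        expected <- 1
      } else {
        mets <- c(mets, a, b)
        add_rxn(sprintf("EX%02d", i), setNames(-1, a), -caps[i], 0)
        add_rxn(sprintf("R%02da", i), setNames(c(-1, 1), c(a, b)), 0, 1000)
        add_rxn(sprintf("R%02db", i), setNames(c(-1, 1), c(a, b)), 0, 1000)
        g2r[[ga]] <- sprintf("R%02da", i)
        g2r[[gb]] <- sprintf("R%02db", i)
        expected <- -1
      }
      designed[[i]] <- tibble(
        gene_a = min(ga, gb), gene_b = max(ga, gb),
        motif = i, motif_type = types[i], expected_sign = expected
      )
    }
    bm <- setNames(rep(-1, n_motifs), sprintf("B%02d", seq_len(n_motifs)))
    add_rxn("BIOMASS", bm, 0, 1000)

    S <- matrix(0, length(mets), length(rxn_ids),
                dimnames = list(mets, rxn_ids))
    for (id in rxn_ids) S[names(stoich[[id]]), id] <- stoich[[id]]
    model <- metabolic_model(mets, rxn_ids, S, lb, ub, "BIOMASS", g2r)

    g <- solve_fba(model)
    if (g$status != "optimal" || g$objective_value <= 0) {
      abort(sprintf(
        "generated network infeasible (seed %d, %d motifs): wild-type growth %s",
        seed, n_motifs,
        if (g$status == "optimal") format(g$objective_value) else g$status))
    }
    list(model = model, designed_pairs = dplyr::bind_rows(designed))
  })
}

#' Generate a synthetic evolutionary-rate table with planted co-evolution
#'
#' Background gene rates (dN/dS-like, dimensionless, non-negative) are drawn
#' uniformly on (0, 1); each planted co-evolving pair shares a common base
#' rate plus independent Gaussian jitter of standard deviation `noise_sd`.
#'
#' @param genes character vector of gene ids.
#' @param coevolving_pairs tibble/data frame with columns `gene_a`, `gene_b`
#'   (subset of `genes`); may be empty.
#' @param noise_sd jitter standard deviation (>= 0; 0 makes planted pairs
#'   share identical rates).
#' @param seed integer seed.
#' @return A tibble with columns `gene`, `rate`.
#' @export
make_rates <- function(genes, coevolving_pairs = NULL, noise_sd = 0.01, seed = 1) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  genes <- as.character(genes)
  with_seed(seed, {
    rate <- setNames(runif(length(genes)), genes)
    if (!is.null(coevolving_pairs) && nrow(coevolving_pairs) > 0L) {
      bad <- setdiff(c(coevolving_pairs$gene_a, coevolving_pairs$gene_b), genes)
      if (length(bad) > 0L) {
        abort(paste0("planted pair gene(s) not in gene list: ",
                     paste(unique(bad), collapse = ", ")))
      }
      for (j in seq_len(nrow(coevolving_pairs))) {
        base <- runif(1)
        rate[coevolving_pairs$gene_a[j]] <- max(0, base + rnorm(1, 0, noise_sd))
        rate[coevolving_pairs$gene_b[j]] <- max(0, base + rnorm(1, 0, noise_sd))
      }
    }
    tibble(gene = genes, rate = unname(rate))
  })
}
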
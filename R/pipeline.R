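# End-to-end pipeline: reference -> conditions -> fitness screens ->
# epistasis -> differential -> similarity -> stability -> class networks ->
# optional co-evolution; flat TSV/JSON artifacts plus a run manifest.

write_stage <- function(x, dir, file) {
  path <- file.path(dir, file)
  readr::write_tsv(x, path, na = "NA")
  path
}

#' Run the full epistasis-dynamics pipeline
#'
#' Executes every stage in order on one model and one condition
#' configuration, writing per-stage TSVs, a summary JSON and a run manifest
#' into `out_dir`. Any stage error aborts with the stage name; outputs of
#' completed stages are left in place.
#'
#' @param model a `metabolic_model`, or a path to a toy JSON / SBML file.
#' @param config condition configuration for [build_condition_set()] (list or
#'   YAML path).
#' @param out_dir output directory (created if needed).
#' @param epsilon_threshold interaction threshold on `|epsilon|`
#'   (default 0.01).
#' @param d_epsilon_threshold differential threshold (default 0.01).
#' @param fraction mutation restriction fraction (default 0.5).
#' @param gene_subset optional character vector restricting the screen to the
#'   pairs among these genes (desk-scale runs on big models).
#' @param rates optional rate table (tibble or TSV path) switching on the
#'   co-evolution stage.
#' @param seed integer seed used for the resampling stage.
#' @param n_resamples resamples for the co-evolution test (default 10000).
#' @param cache_dir optional fitness-cache directory (see
#'   [fitness_screen()]).
#' @return Invisibly, a list with all in-memory stage results and the output
#'   paths.
#' @export
run_pipeline <- function(model, config, out_dir,
                         epsilon_threshold = 0.01,
                         d_epsilon_threshold = 0.01,
                         fraction = 0.5,
                         gene_subset = NULL,
                         rates = NULL,
                         seed = 1,
                         n_resamples = 10000,
                         cache_dir = NULL) {
  t0 <- Sys.time()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "load_model"
  result <- tryCatch({
    if (is.character(model)) {
      model <- if (grepl("\\.json$", model, ignore.case = TRUE)) {
        read_toy_model(model)
      } else {
        read_sbml_model(model)
      }
    }

    stage <- "conditions"
    cs <- build_condition_set(model, config)
    all_conds <- c(list(reference = cs$reference), cs$conditions)

    stage <- "fitness_screens"
    pairs <- if (is.null(gene_subset)) {
      gene_pairs(model)
    } else {
      gene_pairs(intersect(gene_subset, model_genes(model)))
    }
    screens <- lapply(all_conds, fitness_screen, pairs = pairs,
                      fraction = fraction, cache_dir = cache_dir)
    for (nm in names(screens)) {
      write_stage(screens[[nm]], out_dir, paste0("fitness_", nm, ".tsv"))
    }

    stage <- "epistasis"
    records <- lapply(screens, condition_epistasis,
                      threshold = epsilon_threshold)
    for (nm in names(records)) {
      write_stage(records[[nm]], out_dir, paste0("epistasis_", nm, ".tsv"))
    }

    stage <- "differential"
    perturbed <- setdiff(names(records), "reference")
    diffs <- lapply(records[perturbed], differential_epistasis,
                    records_ref = records$reference,
                    d_threshold = d_epsilon_threshold)
    signs <- dplyr::bind_rows(lapply(diffs, sign_summary))
    if (length(diffs) > 0L) {
      write_stage(dplyr::bind_rows(diffs), out_dir, "differential.tsv")
      write_stage(signs, out_dir, "sign_summary.tsv")
    }

    stage <- "similarity"
    sim <- if (length(perturbed) >= 2L) {
      similarity_matrix(records[perturbed])
    } else {
      NULL
    }
    if (!is.null(sim)) write_stage(sim, out_dir, "similarity.tsv")

    stage <- "stability"
    stab <- NULL
    fractions <- NULL
    if (length(perturbed) >= 2L) {
      stab <- epistasis_stability(records[perturbed])
      fractions <- stability_fractions(stab, records[perturbed])
      write_stage(stab, out_dir, "stability.tsv")
      write_stage(fractions, out_dir, "stability_fractions.tsv")
    }

    stage <- "networks"
    nets <- list()
    if (!is.null(stab)) {
      for (cls in c("stable", "dynamic")) {
        g <- build_epistasis_graph(stab, cls)
        if (igraph::gsize(g) > 0L && igraph::gorder(g) >= 2L) {
          nets[[cls]] <- dplyr::mutate(network_stats(g), class = cls,
                                       .before = 1)
          write_stage(
            tibble::as_tibble(igraph::as_data_frame(g, what = "edges")),
            out_dir, paste0("network_edges_", cls, ".tsv"))
          igraph::write_graph(
            g, file.path(out_dir, paste0("network_", cls, ".graphml")),
            format = "graphml")
        }
      }
      if (length(nets) > 0L) {
        write_stage(dplyr::bind_rows(nets), out_dir, "network_stats.tsv")
      }
    }

    stage <- "coevolution"
    coevo <- NULL
    if (!is.null(rates)) {
      if (is.character(rates)) rates <- read_rate_table(rates)
      epi_pairs <- dplyr::bind_rows(records[perturbed]) |>
        dplyr::filter(.data$passes) |>
        dplyr::distinct(.data$gene_a, .data$gene_b)
      if (nrow(epi_pairs) > 0L) {
        coevo <- pair_rate_test(epi_pairs, rates, n_resamples = n_resamples,
                                seed = seed, universe = model_genes(model))
      }
    }

    summary <- list(
      conditions = names(all_conds),
      growth_fraction = cs$growth_fraction,
      wildtype_growth = vapply(all_conds, function(x) x$wildtype_growth,
                               numeric(1)),
      sign_summary = signs,
      stability_class_fractions = if (!is.null(stab)) {
        ever <- stab[stab$n_conditions > 0L, ]
        as.list(table(ever$class) / nrow(ever))
      } else NULL,
      coevolution_p = if (!is.null(coevo)) coevo$p else NULL
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")

    manifest <- list(
      model_hash = model_hash(model),
      n_genes = length(model_genes(model)),
      n_reactions = length(model$reactions),
      epsilon_threshold = epsilon_threshold,
      d_epsilon_threshold = d_epsilon_threshold,
      fraction = fraction,
      seed = seed,
      gene_subset = gene_subset,
      lp_solves = lp_solve_count(),
      r_version = R.version.string,
      wall_time_s = as.numeric(Sys.time() - t0, units = "secs")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")

    list(model = model, condition_set = cs, screens = screens,
         records = records, differential = diffs, sign_summary = signs,
         similarity = sim, stability = stab,
         stability_fractions = fractions, network_stats = nets,
         coevolution = coevo, out_dir = out_dir)
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
  invisible(result)
}
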
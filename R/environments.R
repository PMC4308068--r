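# Growth environments: the abundant-glucose reference and nutrient-limited
# perturbations calibrated to a matched growth rate.
#
# Two modes. fixed_fraction (the iso-growth design): the limiting nutrient's
# uptake bound is calibrated by an LP so wild-type growth equals
# growth_fraction x reference growth (default 0.20), then frozen. max_growth:
# uptake is opened to the allowed maximum and growth is capped at the
# reference growth. Only the limiting nutrient's exchange bound differs
# between conditions; every other exchange bound is inherited from the
# reference medium.

new_condition <- function(name, model, limiting_exchange, mode, uptake_bound,
                          wildtype_growth, wildtype_flux, reference_growth) {
  structure(
    list(
      name = name,
      model = model,
      limiting_exchange = limiting_exchange,
      mode = mode,
      uptake_bound = uptake_bound,
      wildtype_growth = wildtype_growth,
      wildtype_flux = wildtype_flux,
      reference_growth = reference_growth
    ),
    class = "fba_condition"
  )
}

#' @export
print.fba_condition <- function(x, ...) {
  cat(sprintf(
    "<fba_condition> %s: %s on %s, uptake %.4g, wild-type growth %.6g (reference %.6g)\n",
    x$name, x$mode, x$limiting_exchange, x$uptake_bound, x$wildtype_growth,
    x$reference_growth))
  invisible(x)
}

#' Build the reference (abundant-glucose) environment
#'
#' Opens the reference carbon exchange to the configured abundant uptake,
#' runs FBA, and stores the geometric-FBA wild-type flux vector that all
#' mutants in this condition are restricted against.
#'
#' @param model a `metabolic_model`.
#' @param glucose_exchange exchange reaction id of the reference carbon.
#' @param glucose_uptake abundant uptake magnitude (positive scalar).
#' @param name condition label (default `"reference"`).
#' @return An `fba_condition`.
#' @export
build_reference <- function(model, glucose_exchange, glucose_uptake,
                            name = "reference") {
  if (!glucose_exchange %in% exchange_reactions(model)) {
    abort(paste0(glucose_exchange, " is not an exchange reaction of the model"))
  }
  m <- model
  m$lb[glucose_exchange] <- -abs(glucose_uptake)
  res <- solve_fba(m)
  if (res$status != "optimal" || res$objective_value <= TAU_FEAS) {
    abort("zero growth in the reference condition: model or medium misconfigured")
  }
  wt <- geometric_fba(m)
  new_condition(name, m, glucose_exchange, "reference",
                abs(glucose_uptake), res$objective_value, wt,
                res$objective_value)
}

#' Build a nutrient-limited condition at matched growth
#'
#' Derives a perturbed environment from the reference: the reference carbon
#' exchange is closed (unless `close_reference = FALSE`, e.g. for a
#' phosphate-style limitation where glucose stays abundant) and the new
#' limiting nutrient is opened. In `fixed_fraction` mode the uptake bound is
#' set to the minimum that supports exactly `growth_fraction` times the
#' reference growth and then frozen; in `max_growth` mode uptake is opened to
#' `max_uptake` and growth capped at the reference growth.
#'
#' @param model the base `metabolic_model` (same one the reference was built
#'   from).
#' @param reference the reference `fba_condition`.
#' @param limiting_exchange exchange reaction id of the limiting nutrient.
#' @param mode `"fixed_fraction"` or `"max_growth"`.
#' @param growth_fraction target growth as a fraction of reference growth
#'   (default 0.20; used in `fixed_fraction` mode).
#' @param name condition label (defaults to the exchange id).
#' @param close_reference close the reference carbon exchange (default
#'   `TRUE`).
#' @param max_uptake maximum allowed uptake magnitude for the limiting
#'   nutrient; defaults to the reference condition's abundant uptake.
#' @return An `fba_condition`.
#' @export
build_condition <- function(model, reference, limiting_exchange,
                            mode = c("fixed_fraction", "max_growth"),
                            growth_fraction = 0.2,
                            name = limiting_exchange,
                            close_reference = TRUE,
                            max_uptake = reference$uptake_bound) {
  mode <- match.arg(mode)
  if (!limiting_exchange %in% exchange_reactions(model)) {
    abort(paste0(limiting_exchange, " is not an exchange reaction of the model"))
  }
  m <- reference$model # inherit the full reference medium
  if (close_reference && limiting_exchange != reference$limiting_exchange) {
    m$lb[reference$limiting_exchange] <- 0
  }
  m$lb[limiting_exchange] <- -abs(max_uptake)

  if (mode == "fixed_fraction") {
    target <- growth_fraction * reference$wildtype_growth
    uptake <- min_uptake_at_growth(m, limiting_exchange, target)
    m$lb[limiting_exchange] <- -uptake
    res <- solve_fba(m)
    if (res$status != "optimal") {
      abort("calibrated condition model is infeasible")
    }
    wt <- geometric_fba(m)
    new_condition(name, m, limiting_exchange, mode, uptake,
                  res$objective_value, wt, reference$wildtype_growth)
  } else {
    m$ub[model$objective] <- min(m$ub[model$objective],
                                 reference$wildtype_growth)
    res <- solve_fba(m)
    if (res$status != "optimal" || res$objective_value <= TAU_FEAS) {
      abort("nutrient cannot support growth in max_growth mode")
    }
    wt <- geometric_fba(m)
    new_condition(name, m, limiting_exchange, mode, abs(max_uptake),
                  res$objective_value, wt, reference$wildtype_growth)
  }
}

#' Build a full condition set from a configuration
#'
#' The configuration mirrors the conditions YAML:
#' `list(reference = list(exchange =, uptake =), growth_fraction = 0.2,
#' conditions = list(list(name =, exchange =, mode =, close_reference =), ...))`.
#' A path to a YAML file with that structure is also accepted.
#'
#' @param model a `metabolic_model`.
#' @param config a list as above, or a path to a YAML file.
#' @return A `condition_set`: list with `reference`, `conditions` (named
#'   list of `fba_condition`), and `growth_fraction`.
#' @export
build_condition_set <- function(model, config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  gf <- config$growth_fraction %||% 0.2
  reference <- build_reference(model, config$reference$exchange,
                               config$reference$uptake)
  conds <- list()
  for (cc in config$conditions) {
    nm <- cc$name %||% cc$exchange
    if (nm %in% names(conds)) abort(paste0("duplicate condition name: ", nm))
    conds[[nm]] <- build_condition(
      model, reference, cc$exchange,
      mode = cc$mode %||% "fixed_fraction",
      growth_fraction = gf,
      name = nm,
      close_reference = cc$close_reference %||% TRUE
    )
  }
  structure(list(reference = reference, conditions = conds,
                 growth_fraction = gf),
            class = "condition_set")
}

#' @export
print.condition_set <- function(x, ...) {
  cat(sprintf("<condition_set> reference + %d perturbed conditions (growth fraction %.3g)\n",
              length(x$conditions), x$growth_fraction))
  invisible(x)
}

#' Wrap a model's current medium as a condition
#'
#' Treats the model's current exchange bounds as the environment: runs FBA
#' and geometric FBA and returns the resulting `fba_condition`. Useful for
#' generated networks whose uptake caps are already part of the model.
#'
#' @param model a `metabolic_model`.
#' @param name condition label.
#' @return An `fba_condition` (its own growth is also the reference growth).
#' @export
condition_from_model <- function(model, name = "reference") {
  res <- solve_fba(model)
  if (res$status != "optimal" || res$objective_value <= TAU_FEAS) {
    abort("model has no positive growth under its current bounds")
  }
  ex <- exchange_reactions(model)
  open <- ex[model$lb[ex] < 0]
  wt <- geometric_fba(model)
  new_condition(name, model, if (length(open) > 0L) open[1] else ex[1],
                "reference", if (length(open) > 0L) -model$lb[open[1]] else 0,
                res$objective_value, wt, res$objective_value)
}

#' Essential genes of a condition
#'
#' A gene is essential if its full knockout (all associated reactions bounded
#' to `[0, 0]`) drops FBA growth below `tau` times the reference growth in
#' the calibrated condition model. Note that essentiality uses the knockout,
#' not the 50%-restriction mutant.
#'
#' @param condition an `fba_condition`.
#' @param tau essentiality cutoff as a fraction of reference growth
#'   (default `1e-6`).
#' @return Sorted character vector of essential gene ids.
#' @export
condition_essentials <- function(condition, tau = 1e-6) {
  m <- condition$model
  cutoff <- tau * condition$reference_growth
  ess <- character(0)
  for (g in model_genes(m)) {
    km <- m
    rxns <- m$gene_to_reactions[[g]]
    km$lb[rxns] <- 0
    km$ub[rxns] <- 0
    res <- solve_fba(km)
    growth <- if (res$status == "optimal") res$objective_value else 0
    if (growth < cutoff) ess <- c(ess, g)
  }
  sort(ess)
}
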
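# Shared fixture conditions, computed once per test session.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name) {
  key <- paste0("fixture_", name)
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- make_fixture(name)
  .fx_cache[[key]]
}

# reference condition of a single-carbon fixture (uptake 10 on EX_A)
fx_condition <- function(name) {
  key <- paste0("cond_", name)
  if (is.null(.fx_cache[[key]])) {
    f <- fx(name)
    .fx_cache[[key]] <- build_reference(f$model, f$manifest$reference_exchange,
                                        f$manifest$reference_uptake)
  }
  .fx_cache[[key]]
}

# the two-carbon fixture's reference + both calibrated conditions
twocarbon_setup <- function() {
  if (is.null(.fx_cache$tc)) {
    f <- fx("twocarbon")
    ref <- build_reference(f$model, "EX_GLC", 10)
    glc_low <- build_condition(f$model, ref, "EX_GLC", "fixed_fraction",
                               growth_fraction = 0.2, name = "glucose_low")
    alt <- build_condition(f$model, ref, "EX_ETH", "fixed_fraction",
                           growth_fraction = 0.2, name = "alt_carbon")
    .fx_cache$tc <- list(fixture = f, reference = ref,
                         glucose_low = glc_low, alt_carbon = alt)
  }
  .fx_cache$tc
}

# epistasis records for the two-carbon run (reference + 2 conditions)
twocarbon_records <- function(threshold = 0.01) {
  key <- paste0("tc_records_", threshold)
  if (is.null(.fx_cache[[key]])) {
    tc <- twocarbon_setup()
    conds <- list(reference = tc$reference, glucose_low = tc$glucose_low,
                  alt_carbon = tc$alt_carbon)
    screens <- lapply(conds, fitness_screen)
    .fx_cache[[key]] <- list(
      screens = screens,
      records = lapply(screens, condition_epistasis, threshold = threshold)
    )
  }
  .fx_cache[[key]]
}

# hand-built epistasis records over an explicit pair universe:
# passing = named sign vector keyed "a|b"
toy_records <- function(universe, passing, condition = "x") {
  key <- paste(universe$gene_a, universe$gene_b, sep = "|")
  eps <- ifelse(key %in% names(passing), 0.2 * unname(passing[key]), 0.001)
  tibble::tibble(
    condition = condition,
    gene_a = universe$gene_a,
    gene_b = universe$gene_b,
    W_x = 1, W_y = 1, W_xy = 1 + eps,
    epsilon = eps,
    passes = abs(eps) >= 0.01,
    sign = sign(eps)
  )
}
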
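# FBA, flux variability analysis, geometric FBA and nutrient-minimisation.
#
# All solves share one bounded-LP wrapper (solve_lp). Geometric FBA follows
# the iterative range-shrinking scheme: flux variability on the optimal face
# within the current box, an L1 minimisation towards the range midpoints via
# split variables, then shrinking each reaction's box to the interval spanned
# by the L1 solution and the midpoint (at least halving every width), until
# the widest range is below tau_geo. Reactions are processed in lexicographic
# id order so the result does not depend on column order.

obj_vector <- function(model) {
  as.numeric(model$reactions == model$objective)
}

check_flux_vector <- function(model, v) {
  res <- max(abs(model$S %*% v))
  ok_bounds <- all(v >= model$lb - 1e-7) && all(v <= model$ub + 1e-7)
  if (res > 1e-6 || !ok_bounds) {
    abort(sprintf("flux vector violates feasibility (max |Sv| = %.3g)", res))
  }
  invisible(v)
}

#' Flux balance analysis
#'
#' Maximises flux through the model's objective (biomass) reaction subject to
#' steady state (`S v = 0`) and the flux bounds.
#'
#' @param model a `metabolic_model`.
#' @return An object of class `fba_result`: list with `status`
#'   (`"optimal"` or `"infeasible"`), `objective_value` and `fluxes`
#'   (named numeric over all reactions; `NULL` unless optimal).
#' @export
solve_fba <- function(model) {
  res <- solve_lp(obj_vector(model),
                  A_eq = model$S, b_eq = rep(0, length(model$metabolites)),
                  lb = model$lb, ub = model$ub, maximize = TRUE)
  if (res$status == "failed") {
    abort("LP solver failed on the FBA problem (iteration limit); not returning zero")
  }
  fluxes <- NULL
  if (res$status == "optimal") {
    fluxes <- setNames(res$x, model$reactions)
  }
  structure(
    list(status = res$status,
         objective_value = if (res$status == "optimal") res$objective else NA_real_,
         fluxes = fluxes),
    class = "fba_result"
  )
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result>", x$status)
  if (x$status == "optimal") cat(sprintf(", objective = %.6g", x$objective_value))
  cat("\n")
  invisible(x)
}

# FVA restricted to a box, holding the objective at >= opt - tau_feas.
# Only reactions in `which_rxns` are re-solved; others keep their box.
fva_box <- function(model, box_lb, box_ub, opt, which_rxns) {
  n <- length(model$reactions)
  cobj <- obj_vector(model)
  A_le <- matrix(-cobj, nrow = 1)
  b_le <- -(opt - TAU_FEAS)
  mn <- box_lb
  mx <- box_ub
  for (i in which_rxns) {
    ei <- as.numeric(seq_len(n) == i)
    lo <- solve_lp(ei, A_eq = model$S, b_eq = rep(0, nrow(model$S)),
                   A_le = A_le, b_le = b_le, lb = box_lb, ub = box_ub,
                   maximize = FALSE)
    hi <- solve_lp(ei, A_eq = model$S, b_eq = rep(0, nrow(model$S)),
                   A_le = A_le, b_le = b_le, lb = box_lb, ub = box_ub,
                   maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      abort(paste0("flux variability infeasible for reaction ",
                   model$reactions[i]))
    }
    mn[i] <- lo$objective
    mx[i] <- hi$objective
  }
  # numerical guard: keep min <= max
  sw <- mn > mx
  if (any(sw)) {
    mid <- (mn[sw] + mx[sw]) / 2
    mn[sw] <- mid
    mx[sw] <- mid
  }
  list(min = mn, max = mx)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux attainable while the objective is
#' held at at least `objective_fraction` times its optimum.
#'
#' @param model a `metabolic_model`.
#' @param objective_fraction scalar in `[0, 1]`.
#' @return A tibble with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, objective_fraction = 1) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  base <- solve_fba(model)
  if (base$status != "optimal") {
    abort("flux variability requires an optimal base FBA solution")
  }
  target <- objective_fraction * base$objective_value
  r <- fva_box(model, unname(model$lb), unname(model$ub), target,
               seq_along(model$reactions))
  tibble(reaction = model$reactions, min = unname(r$min), max = unname(r$max))
}

#' Geometric FBA: a deterministic representative optimal flux vector
#'
#' Selects one flux vector from the set of alternate FBA optima: the
#' L1-central point of the optimal face, computed by iterating flux
#' variability within a shrinking box and minimising the L1 distance to the
#' range midpoints. The result is optimal for the growth objective, unique,
#' reproducible across runs, and invariant to reaction column order; it is
#' the wild-type reference that flux-restriction mutants are measured
#' against.
#'
#' @param model a `metabolic_model`.
#' @param tol convergence tolerance on the widest flux range (default
#'   `1e-6`).
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   widest remaining range.
#' @return Named numeric vector of fluxes (one per reaction).
#' @export
geometric_fba <- function(model, tol = TAU_GEO, max_iter = 50L) {
  base <- solve_fba(model)
  if (base$status != "optimal") abort("geometric FBA requires an optimal FBA solution")
  opt <- base$objective_value

  # canonical (lexicographic) internal order for order-invariance
  ord <- order(model$reactions, method = "radix")
  cmodel <- model
  cmodel$reactions <- model$reactions[ord]
  cmodel$S <- model$S[, ord, drop = FALSE]
  cmodel$lb <- model$lb[ord]
  cmodel$ub <- model$ub[ord]
  cmodel$objective <- model$objective

  n <- length(cmodel$reactions)
  cobj <- obj_vector(cmodel)
  box_lb <- unname(cmodel$lb)
  box_ub <- unname(cmodel$ub)
  active <- seq_len(n)
  v_star <- NULL

  for (iter in seq_len(max_iter)) {
    r <- fva_box(cmodel, box_lb, box_ub, opt, active)
    box_lb <- r$min
    box_ub <- r$max
    width <- box_ub - box_lb
    if (max(width) < tol && !is.null(v_star)) break
    mid <- (box_lb + box_ub) / 2
    active <- which(width >= tol)

    # L1 minimisation to the midpoint with split variables s_i >= |v_i - mid_i|
    # over the wide reactions only (narrow ones are already pinned).
    k <- length(active)
    if (k == 0L) {
      # everything pinned: recover the unique point with one feasibility solve
      sol <- solve_lp(cobj, A_eq = cmodel$S, b_eq = rep(0, nrow(cmodel$S)),
                      lb = box_lb, ub = box_ub, maximize = TRUE)
      v_star <- sol$x
      break
    }
    nv <- n + k
    ext_obj <- c(rep(0, n), rep(1, k))
    A_eq <- cbind(cmodel$S, matrix(0, nrow(cmodel$S), k))
    b_eq <- rep(0, nrow(cmodel$S))
    # objective >= opt - tau  ->  -c'v <= -(opt - tau)
    A_le <- matrix(0, 1 + 2 * k, nv)
    b_le <- numeric(1 + 2 * k)
    A_le[1, seq_len(n)] <- -cobj
    b_le[1] <- -(opt - TAU_FEAS)
    for (j in seq_len(k)) {
      i <- active[j]
      # v_i - s_j <= mid_i   and   -v_i - s_j <= -mid_i
      A_le[1 + 2 * j - 1, i] <- 1
      A_le[1 + 2 * j - 1, n + j] <- -1
      b_le[1 + 2 * j - 1] <- mid[i]
      A_le[1 + 2 * j, i] <- -1
      A_le[1 + 2 * j, n + j] <- -1
      b_le[1 + 2 * j] <- -mid[i]
    }
    smax <- pmax(mid[active] - box_lb[active], box_ub[active] - mid[active])
    sol <- solve_lp(ext_obj, A_eq = A_eq, b_eq = b_eq,
                    A_le = A_le, b_le = b_le,
                    lb = c(box_lb, rep(0, k)), ub = c(box_ub, smax + tol),
                    maximize = FALSE)
    if (sol$status != "optimal") {
      abort("geometric FBA: L1 centring LP did not solve")
    }
    v_star <- sol$x[seq_len(n)]
    # shrink each active reaction's box to [min(v*, mid), max(v*, mid)]
    box_lb[active] <- pmin(v_star[active], mid[active])
    box_ub[active] <- pmax(v_star[active], mid[active])
    if (max(box_ub - box_lb) < tol) break
    if (iter == max_iter) {
      abort(sprintf(
        "geometric FBA did not converge in %d iterations (widest range %.3g)",
        max_iter, max(box_ub - box_lb)))
    }
  }

  v <- setNames(v_star, cmodel$reactions)[model$reactions]
  # snap solver noise to zero so wild-type-zero reactions pin cleanly
  v[abs(v) < 1e-9] <- 0
  check_flux_vector(model, v)
  v
}

#' Minimal nutrient uptake at a fixed growth rate
#'
#' Solves the LP minimising the uptake magnitude through `nutrient_exchange`
#' subject to steady state, bounds, and the growth rate held *equal* to
#' `growth_target`. This is the calibration step that puts every perturbed
#' environment on the same growth rate.
#'
#' @param model a `metabolic_model` (the nutrient's exchange should already
#'   be open to the maximum allowed uptake).
#' @param nutrient_exchange exchange reaction id of the limiting nutrient.
#' @param growth_target required growth rate (equality constraint).
#' @return Minimal uptake magnitude (non-negative scalar).
#' @export
min_uptake_at_growth <- function(model, nutrient_exchange, growth_target) {
  if (!nutrient_exchange %in% model$reactions) {
    abort(paste0("unknown exchange reaction: ", nutrient_exchange))
  }
  n <- length(model$reactions)
  i_ex <- which(model$reactions == nutrient_exchange)
  A_eq <- rbind(model$S, obj_vector(model))
  b_eq <- c(rep(0, length(model$metabolites)), growth_target)
  # uptake magnitude = -v_ex (uptake is negative flux); minimise it
  cvec <- as.numeric(seq_len(n) == i_ex) * -1
  res <- solve_lp(cvec, A_eq = A_eq, b_eq = b_eq,
                  lb = model$lb, ub = model$ub, maximize = FALSE)
  if (res$status != "optimal") {
    cap <- solve_fba(model)
    reach <- if (cap$status == "optimal") cap$objective_value else 0
    abort(sprintf(
      "growth target unreachable on this nutrient (target %.6g, achievable maximum %.6g)",
      growth_target, reach))
  }
  max(0, res$objective)
}
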
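test_that("FBA solves the toy fixtures to their known capacities", {
  expect_equal(solve_fba(fx("serial")$model)$objective_value, 10,
               tolerance = 1e-10)
  # closing all uptake gives zero growth
  m <- fx("serial")$model
  m$lb[exchange_reactions(m)] <- 0
  expect_equal(solve_fba(m)$objective_value, 0, tolerance = 1e-10)
  # parallel fixture with both branches capped at 2.5 each
  p <- fx("parallel")$model
  p$ub[c("R1", "R2")] <- 2.5
  expect_equal(solve_fba(p)$objective_value, 5, tolerance = 1e-10)
})

test_that("FBA objective matches the brute-force vertex-enumeration oracle", {
  for (nm in c("serial", "parallel", "shared", "twocarbon")) {
    m <- fx(nm)$model
    expect_equal(solve_fba(m)$objective_value, oracle_fba_objective(m),
                 tolerance = 1e-8, label = nm)
  }
  # small random networks (<= 12 reactions) against the same oracle
  for (seed in 1:3) {
    rn <- make_random_network(n_motifs = 3, seed = seed)
    m <- rn$model
    expect_lte(length(m$reactions), 12)
    expect_equal(solve_fba(m)$objective_value, oracle_fba_objective(m),
                 tolerance = 1e-8, label = paste("seed", seed))
  }
})

test_that("flux variability brackets alternate optima correctly", {
  fv <- flux_variability(fx("parallel")$model, 1)
  expect_equal(fv$min[fv$reaction == "R1"], 0, tolerance = 1e-8)
  expect_equal(fv$max[fv$reaction == "R1"], 10, tolerance = 1e-8)
  expect_equal(fv$min[fv$reaction == "R2"], 0, tolerance = 1e-8)
  expect_equal(fv$max[fv$reaction == "R2"], 10, tolerance = 1e-8)

  # unique optimum: every reaction pinned
  fs <- flux_variability(fx("serial")$model, 1)
  internal <- fs[fs$reaction != "EX_A", ]
  expect_equal(internal$min, rep(10, 3), tolerance = 1e-8)
  expect_equal(internal$max, rep(10, 3), tolerance = 1e-8)

  # fraction 0 releases the objective: ranges are bounds cut by feasibility
  f0 <- flux_variability(fx("serial")$model, 0)
  expect_equal(f0$min[f0$reaction == "R1"], 0, tolerance = 1e-8)
  expect_equal(f0$max[f0$reaction == "R1"], 10, tolerance = 1e-8)
  expect_true(all(f0$min <= f0$max + 1e-12))
})

test_that("geometric FBA picks the central optimum deterministically", {
  v <- geometric_fba(fx("parallel")$model)
  expect_equal(unname(v["R1"]), 5, tolerance = 1e-8)
  expect_equal(unname(v["R2"]), 5, tolerance = 1e-8)
  # repeated runs are bit-identical
  expect_identical(v, geometric_fba(fx("parallel")$model))
  # unique optimum: geometric FBA is a no-op relative to plain FBA
  s <- fx("serial")$model
  expect_equal(geometric_fba(s), solve_fba(s)$fluxes, tolerance = 1e-9)
})

test_that("geometric FBA is invariant to reaction column order", {
  p <- fx("parallel")$model
  perm <- c(3, 1, 4, 2)
  pm <- metabolic_model(
    p$metabolites, p$reactions[perm], p$S[, perm],
    p$lb[perm], p$ub[perm], p$objective, p$gene_to_reactions
  )
  v <- geometric_fba(p)
  vp <- geometric_fba(pm)
  expect_equal(vp[names(v)], v, tolerance = 1e-12)
})

test_that("returned flux vectors satisfy steady state and bounds", {
  for (nm in c("serial", "parallel", "shared", "twocarbon")) {
    m <- fx(nm)$model
    v <- geometric_fba(m)
    expect_lt(max(abs(m$S %*% v)), 1e-7)
    expect_true(all(v >= m$lb - 1e-7 & v <= m$ub + 1e-7))
  }
})

test_that("minimal uptake at fixed growth is exact and monotone", {
  s <- fx("serial")$model
  expect_equal(min_uptake_at_growth(s, "EX_A", 2), 2, tolerance = 1e-10)
  expect_equal(min_uptake_at_growth(s, "EX_A", 0), 0, tolerance = 1e-10)
  expect_error(min_uptake_at_growth(s, "EX_A", 20), "unreachable")
  # monotone non-decreasing in the growth target
  targets <- c(0, 1, 2.5, 5, 7.5, 10)
  ups <- vapply(targets, function(tg) min_uptake_at_growth(s, "EX_A", tg),
                numeric(1))
  expect_true(all(diff(ups) >= -1e-9))
  # low-yield conversion needs proportionally more uptake
  tc <- fx("twocarbon")$model
  tc$lb["EX_GLC"] <- 0
  tc$lb["EX_ETH"] <- -10
  expect_equal(min_uptake_at_growth(tc, "EX_ETH", 2), 4, tolerance = 1e-10)
})

test_that("the LP wrapper reports status faithfully", {
  # infeasible equality
  r <- solve_lp(c(1, 0), A_eq = rbind(c(1, 1)), b_eq = 5,
                lb = c(0, 0), ub = c(1, 1))
  expect_equal(r$status, "infeasible")
  # fixed variables are eliminated and restored
  r2 <- solve_lp(c(1, 1), A_eq = rbind(c(1, 1)), b_eq = 3,
                 lb = c(2, 0), ub = c(2, 5), maximize = FALSE)
  expect_equal(r2$status, "optimal")
  expect_equal(r2$x, c(2, 1))
  # maximisation
  r3 <- solve_lp(c(1, 2), A_le = rbind(c(1, 1)), b_le = 4,
                 lb = c(0, 0), ub = c(3, 3), maximize = TRUE)
  expect_equal(r3$objective, 7) # x = (1, 3)
})
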
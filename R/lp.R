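# Bounded linear programming via a dense two-phase simplex with Bland's rule.
#
# The solver is deliberately self-contained: it must be deterministic (Bland's
# anti-cycling pivot gives finite, reproducible termination, which geometric
# FBA relies on) and robust to the heavily degenerate LPs that stoichiometric
# models produce. Problem sizes here are small (tens to a few hundred
# variables), where a dense tableau is perfectly adequate.
#
# solve_lp() handles general box bounds lb <= v <= ub by shifting variables
# (y = v - lb >= 0) and adding upper-bound rows; variables with lb == ub are
# eliminated before the solve.

.lp_env <- new.env(parent = emptyenv())
.lp_env$count <- 0L

#' Number of LP solves performed so far
#'
#' A process-wide counter of simplex solves, useful for verifying cache hits
#' and for progress reporting on large screens.
#'
#' @param reset if `TRUE`, reset the counter to zero (returns the old value).
#' @return Integer count of LP solves since load (or since last reset).
#' @export
lp_solve_count <- function(reset = FALSE) {
  n <- .lp_env$count
  if (reset) .lp_env$count <- 0L
  n
}

# Two-phase tableau simplex for
#   min c'x  s.t.  A1 x <= b1, A3 x = b3, x >= 0
# with Bland's rule (entering: lowest eligible index; leaving: minimum ratio,
# ties broken by lowest basis index). Returns list(status, objective, x).
simplex_core <- function(cvec, A1 = NULL, b1 = NULL, A3 = NULL, b3 = NULL,
                         tol = 1e-9) {
  n <- length(cvec)
  m1 <- if (is.null(A1)) 0L else nrow(A1)
  m3 <- if (is.null(A3)) 0L else nrow(A3)
  m <- m1 + m3
  if (m == 0L) abort("simplex_core: no constraints")

  A <- matrix(0, m, n + m1)
  b <- numeric(m)
  if (m1 > 0L) {
    A[seq_len(m1), seq_len(n)] <- A1
    A[cbind(seq_len(m1), n + seq_len(m1))] <- 1 # slack
    b[seq_len(m1)] <- b1
  }
  if (m3 > 0L) {
    A[m1 + seq_len(m3), seq_len(n)] <- A3
    b[m1 + seq_len(m3)] <- b3
  }
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  # rows whose slack can serve as the initial basic variable
  slack_ok <- c(!neg[seq_len(m1)], rep(FALSE, m3))
  need_art <- which(!slack_ok)
  n_art <- length(need_art)
  n_tot <- n + m1 + n_art
  if (n_art > 0L) {
    Art <- matrix(0, m, n_art)
    Art[cbind(need_art, seq_len(n_art))] <- 1
    A <- cbind(A, Art)
  }
  basis <- integer(m)
  basis[slack_ok] <- n + which(slack_ok)
  basis[need_art] <- n + m1 + seq_len(n_art)

  # tableau: m rows of [A | b], plus cost row appended during each phase
  TB <- cbind(A, b)

  pivot <- function(TB, r, j) {
    TB[r, ] <- TB[r, ] / TB[r, j]
    other <- setdiff(seq_len(nrow(TB)), r)
    TB[other, ] <- TB[other, ] - outer(TB[other, j], TB[r, ])
    # exact zeros in the pivot column guard against drift
    TB[other, j] <- 0
    TB
  }

  run_phase <- function(TB, basis, cost, allowed) {
    # reduced-cost row carried as the last tableau row and pivoted with it
    costrow <- c(cost, 0)
    for (i in seq_len(m)) {
      cb <- cost[basis[i]]
      if (cb != 0) costrow <- costrow - cb * TB[i, ]
    }
    TBx <- rbind(TB, costrow)
    crow <- m + 1L
    max_pivots <- 2000L + 50L * n_tot
    for (it in seq_len(max_pivots)) {
      red <- TBx[crow, seq_len(n_tot)]
      cand <- which(allowed & red < -tol)
      if (length(cand) == 0L) {
        return(list(TB = TBx[seq_len(m), , drop = FALSE], basis = basis,
                    objective = -TBx[crow, n_tot + 1], status = "optimal"))
      }
      j <- cand[1L] # Bland: smallest eligible index
      col <- TBx[seq_len(m), j]
      rows <- which(col > tol)
      if (length(rows) == 0L) {
        return(list(TB = TBx[seq_len(m), , drop = FALSE], basis = basis,
                    objective = NA_real_, status = "unbounded"))
      }
      ratio <- TBx[rows, n_tot + 1] / col[rows]
      rmin <- min(ratio)
      tie <- rows[ratio <= rmin + tol]
      r <- tie[which.min(basis[tie])] # Bland tie-break
      TBx <- pivot(TBx, r, j)
      basis[r] <- j
    }
    list(TB = TBx[seq_len(m), , drop = FALSE], basis = basis,
         objective = NA_real_, status = "failed")
  }

  art_cols <- if (n_art > 0L) n + m1 + seq_len(n_art) else integer(0)

  if (n_art > 0L) {
    cost1 <- c(rep(0, n + m1), rep(1, n_art))
    allowed1 <- rep(TRUE, n_tot)
    ph1 <- run_phase(TB, basis, cost1, allowed1)
    if (ph1$status == "failed") {
      return(list(status = "failed", objective = NA_real_, x = NULL))
    }
    if (ph1$objective > 1e-7) {
      return(list(status = "infeasible", objective = NA_real_, x = NULL))
    }
    TB <- ph1$TB
    basis <- ph1$basis
    # drive any degenerate artificial out of the basis
    for (i in which(basis %in% art_cols)) {
      row <- TB[i, seq_len(n + m1)]
      j <- which(abs(row) > tol)
      if (length(j) > 0L) {
        TB <- pivot(TB, i, j[1L])
        basis[i] <- j[1L]
      }
      # else: redundant row; harmless to leave (all-zero coefficients)
    }
  }

  cost2 <- c(cvec, rep(0, m1), rep(0, n_art))
  allowed2 <- c(rep(TRUE, n + m1), rep(FALSE, n_art))
  ph2 <- run_phase(TB, basis, cost2, allowed2)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }
  x_full <- numeric(n_tot)
  x_full[ph2$basis] <- ph2$TB[seq_len(m), n_tot + 1]
  list(status = "optimal", objective = sum(cvec * x_full[seq_len(n)]),
       x = x_full[seq_len(n)])
}

#' Solve a bounded linear program
#'
#' Minimise (or maximise) `obj' v` subject to `A_eq v = b_eq`,
#' `A_le v <= b_le` and `lb <= v <= ub`. All bounds must be finite; the flux
#' polytopes handled here are bounded by construction and an unbounded
#' formulation is treated as a caller error.
#'
#' @param obj numeric objective coefficients, one per variable.
#' @param A_eq,b_eq equality constraints (matrix may be `NULL`).
#' @param A_le,b_le inequality (`<=`) constraints (may be `NULL`).
#' @param lb,ub finite variable bounds.
#' @param maximize maximise instead of minimise.
#' @return list with `status` (`"optimal"`, `"infeasible"` or `"unbounded"`),
#'   `objective`, and `x` (solution on the original variable scale; `NULL`
#'   unless optimal).
#' @export
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     lb, ub, maximize = FALSE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    abort("solve_lp requires finite variable bounds")
  }
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }

  fixed <- (ub - lb) <= 1e-12
  free <- which(!fixed)
  shift_all <- lb # fixed variables sit at lb == ub

  if (length(free) == 0L) {
    ok <- TRUE
    if (!is.null(A_eq)) ok <- ok && all(abs(A_eq %*% shift_all - b_eq) <= 1e-7)
    if (!is.null(A_le)) ok <- ok && all(A_le %*% shift_all - b_le <= 1e-7)
    if (!ok) return(list(status = "infeasible", objective = NA_real_, x = NULL))
    return(list(status = "optimal", objective = sum(obj * shift_all),
                x = shift_all))
  }

  cf <- if (maximize) -obj[free] else obj[free]

  A3 <- NULL; b3 <- NULL
  if (!is.null(A_eq)) {
    A3 <- A_eq[, free, drop = FALSE]
    b3 <- b_eq - as.numeric(A_eq %*% shift_all)
  }
  A1 <- NULL; b1 <- NULL
  if (!is.null(A_le)) {
    A1 <- A_le[, free, drop = FALSE]
    b1 <- b_le - as.numeric(A_le %*% shift_all)
  }
  # upper bounds on shifted variables: y_i <= ub_i - lb_i
  nf <- length(free)
  Aub <- diag(nf)
  width <- ub[free] - lb[free]
  A1 <- if (is.null(A1)) Aub else rbind(A1, Aub)
  b1 <- c(b1, width)

  .lp_env$count <- .lp_env$count + 1L
  res <- simplex_core(cf, A1 = A1, b1 = b1, A3 = A3, b3 = b3)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, x = NULL))
  }
  x <- shift_all
  x[free] <- lb[free] + res$x
  list(status = "optimal", objective = sum(obj * x), x = x)
}
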
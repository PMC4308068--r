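# Independent oracles, deliberately implemented by different means than the
# package code they check.

# Brute-force FBA oracle: exhaustive vertex enumeration of the flux polytope
# {S v = 0, lb <= v <= ub}. A vertex has n - rank(S) reactions pinned at a
# bound; every pinning pattern is enumerated, the remaining square-ish linear
# system solved, and feasibility checked. Exact on small integer toys.
oracle_fba_objective <- function(model, tol = 1e-8) {
  S <- unname(model$S)
  n <- ncol(S)
  lb <- unname(model$lb)
  ub <- unname(model$ub)
  cvec <- as.numeric(model$reactions == model$objective)
  r <- qr(S)$rank
  k <- n - r
  best <- -Inf

  check_vertex <- function(v) {
    if (any(v < lb - tol) || any(v > ub + tol)) return(invisible(NULL))
    if (max(abs(S %*% v)) > 1e-7) return(invisible(NULL))
    val <- sum(cvec * v)
    if (val > best) best <<- val
    invisible(NULL)
  }

  if (k == 0) {
    v <- rep(0, n)
    check_vertex(v)
    return(if (is.finite(best)) best else NA_real_)
  }

  fix_sets <- utils::combn(n, k)
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  for (ci in seq_len(ncol(fix_sets))) {
    fx <- fix_sets[, ci]
    free <- setdiff(seq_len(n), fx)
    A <- S[, free, drop = FALSE]
    qa <- qr(A)
    if (qa$rank < length(free)) next # solution not unique: not a basic point
    for (pi in seq_len(nrow(patterns))) {
      vfix <- ifelse(patterns[pi, ], ub[fx], lb[fx])
      b <- -S[, fx, drop = FALSE] %*% vfix
      vfree <- tryCatch(qr.coef(qa, b), error = function(e) NULL)
      if (is.null(vfree) || any(is.na(vfree))) next
      if (max(abs(A %*% vfree - b)) > 1e-7) next
      v <- numeric(n)
      v[fx] <- vfix
      v[free] <- vfree
      check_vertex(v)
    }
  }
  if (is.finite(best)) best else NA_real_
}

# All-pairs BFS network oracle on an adjacency list.
oracle_network_stats <- function(graph) {
  n <- igraph::gorder(graph)
  adj <- igraph::as_adj_list(graph)
  adj <- lapply(adj, as.integer)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      for (w in adj[[u]]) {
        if (!is.finite(dist[w])) {
          dist[w] <- dist[u] + 1
          queue <- c(queue, w)
        }
      }
    }
    D[s, ] <- dist
  }
  off <- D[upper.tri(D)]
  avg_path <- mean(off[is.finite(off)])

  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  clust <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    d <- length(nb)
    if (d < 2) return(0)
    links <- sum(A[nb, nb]) / 2
    links / (d * (d - 1) / 2)
  }, numeric(1))

  clo <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- d[is.finite(d) & d > 0]
    if (length(reach) == 0) 0 else length(reach) / sum(reach)
  }, numeric(1))

  list(avg_path_length = avg_path, avg_clustering = mean(clust),
       avg_closeness = mean(clo))
}

# Exact two-sided binomial p at p0 = 0.5 by direct summation: the total
# probability of outcomes no more likely than the observed one.
oracle_binom_two_sided <- function(k, n) {
  probs <- vapply(0:n, function(i) choose(n, i) * 0.5^n, numeric(1))
  sum(probs[probs <= probs[k + 1] + 1e-12])
}

# Hypergeometric upper-tail by direct summation.
oracle_hyper_tail <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}

# Spearman rho with average ranks, from first principles.
oracle_spearman_rho <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}
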
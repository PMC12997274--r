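# Independent oracles used across test files.

# all permutations of 1..n (n small)
perms_of <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- if (n == 1) matrix(1L, 1, 1) else {
      sub <- perms_of(n - 1)
      do.call(rbind, lapply(seq_len(n), function(k) {
        rest <- setdiff(seq_len(n), k)
        cbind(k, matrix(rest[sub], nrow(sub)))
      }))
    }
    cache[[key]] <<- p
    p
  }
})

# exhaustive minimum assignment cost: rows fully matched into columns
brute_assignment_cost <- function(cost) {
  if (nrow(cost) > ncol(cost)) cost <- t(cost)
  n <- nrow(cost); m <- ncol(cost)
  pm <- perms_of(m)[, seq_len(n), drop = FALSE]
  # row i pairs with column pm[p, i] for each permutation p
  idx <- cbind(rep(seq_len(n), times = nrow(pm)), as.vector(t(pm)))
  vals <- matrix(cost[idx], nrow(pm), n, byrow = TRUE)
  min(rowSums(vals))
}

# exhaustive graph-automorphism orbits of carbons: backtracking over
# colour- and adjacency-preserving permutations (heavy atoms <= ~12)
brute_carbon_orbits <- function(mol) {
  n <- nrow(mol$atoms)
  rings <- perceive_rings(mol)
  ords <- ifelse(rings$aromatic_bond, 4, mol$bonds$order)
  adj <- matrix(0, n, n)
  if (nrow(mol$bonds)) {
    adj[cbind(mol$bonds$i, mol$bonds$j)] <- ords
    adj[cbind(mol$bonds$j, mol$bonds$i)] <- ords
  }
  col <- paste(mol$atoms$element, mol$atoms$nH)
  same <- outer(col, col, "==")
  linked <- logical(n)
  orbit_mate <- diag(TRUE, n)
  assign_next <- function(perm, depth) {
    if (depth > n) {
      orbit_mate[cbind(seq_len(n), perm)] <<- TRUE
      return(invisible())
    }
    for (cand in which(same[depth, ])) {
      if (cand %in% perm[seq_len(depth - 1)]) next
      ok <- TRUE
      for (prev in seq_len(depth - 1)) {
        if (adj[depth, prev] != adj[cand, perm[prev]]) { ok <- FALSE; break }
      }
      if (ok) { perm[depth] <- cand; assign_next(perm, depth + 1) }
    }
  }
  assign_next(integer(n), 1)
  # orbits = connected components of the "mapped to" relation
  g <- igraph::graph_from_adjacency_matrix(orbit_mate, mode = "max")
  memb <- igraph::components(g)$membership
  carbons <- which(mol$atoms$element == "C")
  cls <- split(carbons, memb[carbons])
  cls <- unname(cls[order(vapply(cls, min, integer(1)))])
  lapply(cls, as.integer)
}

# exact pinball loss
pinball <- function(y, yhat, tau) {
  tau * pmax(y - yhat, 0) + (1 - tau) * pmax(yhat - y, 0)
}

# density-based oracle for the error score: piecewise-constant density from
# the quantile knots, trapezoid-integrated over [med - e, med + e]
trapezoid_error_score <- function(vec, taus, y, npts = 1e4) {
  v <- sort(vec); taus <- as.numeric(taus)
  keep <- c(v[-length(v)] != v[-1], TRUE)
  vv <- v[keep]; tt <- taus[keep]
  wlo <- vv[2] - vv[1]; whi <- vv[length(vv)] - vv[length(vv) - 1]
  knots_x <- c(vv[1] - wlo, vv, vv[length(vv)] + whi)
  knots_t <- c(0, tt, 1)
  dens <- function(x) {
    i <- findInterval(x, knots_x)
    out <- numeric(length(x))
    ok <- i >= 1 & i < length(knots_x)
    out[ok] <- (knots_t[i[ok] + 1] - knots_t[i[ok]]) /
               (knots_x[i[ok] + 1] - knots_x[i[ok]])
    out
  }
  med <- v[which.min(abs(taus - 0.5))]
  e <- abs(med - y)
  if (e == 0) return(0)
  xs <- seq(med - e, med + e, length.out = npts)
  sum((dens(xs[-1]) + dens(xs[-npts])) / 2 * diff(xs))
}

# one shared desk-scale training pair (penalty on / off), built lazily so
# fast test files do not pay for it
.desk_env <- new.env(parent = emptyenv())
desk_runs <- function() {
  if (is.null(.desk_env$runs)) {
    seed <- 101
    corpus <- desk_corpus(seed)
    run1 <- desk_train(seed, mono_weight = 1, corpus = corpus)
    run0 <- desk_train(seed, mono_weight = 0, corpus = corpus)
    .desk_env$runs <- list(on = run1, off = run0, seed = seed)
  }
  .desk_env$runs
}
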
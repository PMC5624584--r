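# Independent brute-force oracle for the sub-game solver, written as plain
# loops over the payoff definition.  It shares nothing with the package's
# vectorized state/payoff machinery.

oracle_payoff <- function(p, joined, edges, tsc, par) {
  ls <- 0
  if (p %in% joined) {
    nb <- c(edges$to[edges$from == p], edges$from[edges$to == p])
    ls <- sum(tsc[intersect(nb, setdiff(joined, p))])
  }
  nj <- length(joined)
  de <- 0
  if (nj >= 2) {
    inside <- edges$from %in% joined & edges$to %in% joined
    de <- sum(edges$weight[inside]) / choose(nj, 2)
  }
  par$alpha * tsc[[p]] + par$beta * ls + par$gamma * de - par$delta * (nj - 1)
}

# enumerate every join/leave assignment (seed fixed to join), return the
# joined sets that survive the unilateral-deviation check
oracle_equilibria <- function(members, seed, edges, tsc, par) {
  free <- setdiff(members, seed)
  if (length(free) == 0L) return(list(seed))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(free)))
  out <- list()
  for (r in seq_len(nrow(grid))) {
    joined <- c(seed, free[unlist(grid[r, ])])
    is_eq <- TRUE
    for (p in free) {
      dev <- if (p %in% joined) setdiff(joined, p) else c(joined, p)
      if (oracle_payoff(p, dev, edges, tsc, par) >
          oracle_payoff(p, joined, edges, tsc, par) + 1e-12) {
        is_eq <- FALSE
        break
      }
    }
    if (is_eq) out[[length(out) + 1L]] <- sort(joined, method = "radix")
  }
  out
}

# the published selection rule: highest mean |t| over joined genes, then the
# larger set, then the lexicographically smallest tuple
oracle_best <- function(equilibria, tsc) {
  if (length(equilibria) == 0L) return(NULL)
  mt <- vapply(equilibria, function(j) mean(abs(tsc[j])), numeric(1))
  sz <- lengths(equilibria)
  key <- vapply(equilibria, paste, character(1), collapse = "\r")
  equilibria[[order(-mt, -sz, key, method = "radix")[1]]]
}

# random sub-game around seed "s" and one anchor, with n_two extra two-step
# players, random extra edges and weights, and random t-scores
random_subgame <- function(n_two, p_extra = 0.4, weighted = TRUE) {
  two <- if (n_two > 0) sprintf("t%02d", seq_len(n_two)) else character(0)
  members <- c("s", "a", two)
  from <- "s"; to <- "a"
  for (v in two) { from <- c(from, "a"); to <- c(to, v) }  # anchor adjacency
  pairs <- if (length(members) >= 2) utils::combn(members, 2) else NULL
  for (j in seq_len(ncol(pairs))) {
    x <- pairs[1, j]; y <- pairs[2, j]
    already <- any((from == x & to == y) | (from == y & to == x))
    if (!already && stats::runif(1) < p_extra) {
      from <- c(from, x); to <- c(to, y)
    }
  }
  w <- if (weighted) round(stats::runif(length(from), 0.2, 1), 3) else
    rep(1, length(from))
  edges <- data.frame(from = from, to = to, weight = w,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = members)
  tsc <- stats::setNames(round(stats::rnorm(length(members), 0, 3), 3),
                         members)
  list(subgame = structure(list(seed = "s", anchor = "a",
                                members = members, graph = g),
                           class = "gta_subgame"),
       edges = edges, tscore = tsc, members = members)
}

# small deterministic expression profile whose per-class Gaussian fits are
# N(2,1) for cases and N(0,1) for controls on gene "gA"
toy_profile <- function() {
  vals <- rbind(gA = c(1, 2, 3, -1, 0, 1),
                gB = c(5, 6, 7, 5, 6, 7))
  colnames(vals) <- paste0("s", 1:6)
  expression_profile(vals, stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                                           colnames(vals)))
}
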
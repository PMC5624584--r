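# Sub-game solving.  A candidate subnetwork is one game per retained
# one-step neighbour (the anchor); each sub-game contains the seed, the
# anchor, and the anchor's adjacent retained two-step nodes, with edges
# induced on those members.  Payoffs during deviation checks are computed
# on the sub-game's induced graph, which is what keeps the enumerated
# state space small.

#' Decompose a candidate subnetwork into sub-games
#'
#' One sub-game per retained one-step neighbour; each two-step node joins
#' the sub-game of every anchor it is adjacent to (it may appear in
#' several).
#'
#' @param candidate a pruned and capped `gta_candidate`.
#' @param max_subgame_players maximum number of free players (all members
#'   except the seed) a sub-game may have before enumeration is refused.
#' @return list of `gta_subgame` objects, one per anchor, in
#'   lexicographic anchor order.
#' @export
decompose <- function(candidate, max_subgame_players = 21) {
  g <- candidate$graph
  members <- c(candidate$seed, candidate$one_step, candidate$two_step)
  lapply(candidate$one_step, function(anchor) {
    two <- intersect(.nbrs_in(g, anchor, members), candidate$two_step)
    mem <- c(candidate$seed, anchor, sort(two, method = "radix"))
    if (length(mem) - 1L > max_subgame_players)
      stop("sub-game for anchor ", anchor, " has ", length(mem) - 1L,
           " free players (cap ", max_subgame_players,
           "); lower the neighbor caps")
    sub <- igraph::induced_subgraph(g, mem)
    structure(list(seed = candidate$seed, anchor = anchor, members = mem,
                   graph = sub),
              class = "gta_subgame")
  })
}

subgame_edges <- function(subgame) {
  el <- igraph::as_edgelist(subgame$graph, names = TRUE)
  w <- igraph::E(subgame$graph)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  data.frame(from = el[, 1], to = el[, 2], weight = w,
             stringsAsFactors = FALSE)
}

#' Enumerate all strategy states of a sub-game
#'
#' The seed always joins; the free players (every other member, sorted
#' lexicographically) each choose join (1) or leave (0).  States are
#' generated in binary-counter order with the first sorted free player as
#' the least significant bit, giving `2^free` rows.
#'
#' @param subgame a `gta_subgame`.
#' @param max_subgame_players refusal cap on the number of free players.
#' @return 0/1 matrix, one row per state, columns named by player with the
#'   seed first.
#' @export
enumerate_states <- function(subgame, max_subgame_players = 21) {
  free <- sort(setdiff(subgame$members, subgame$seed), method = "radix")
  nf <- length(free)
  if (nf > max_subgame_players)
    stop("sub-game has ", nf, " free players, enumeration cap is ",
         max_subgame_players)
  n_states <- 2L^nf
  S <- matrix(1L, nrow = n_states, ncol = nf + 1L,
              dimnames = list(NULL, c(subgame$seed, free)))
  if (nf > 0L) {
    k <- 0:(n_states - 1L)
    for (b in seq_len(nf))
      S[, b + 1L] <- bitwAnd(bitwShiftR(k, b - 1L), 1L)
  }
  S
}

# payoff matrix (states x players) for a sub-game, fully vectorized:
#   PF_i = alpha t_i + beta LS_i + gamma DE - delta (n_join - 1)
# with LS_i = s_i * sum_j A_ij s_j t_j and DE the weighted density of the
# joined induced subgraph.
subgame_payoffs <- function(S, subgame, tscore, params) {
  players <- colnames(S)
  t <- tscore[players]
  has_w <- "weight" %in% igraph::edge_attr_names(subgame$graph)
  W <- igraph::as_adjacency_matrix(subgame$graph,
                                   attr = if (has_w) "weight" else NULL,
                                   sparse = FALSE)
  W <- W[players, players, drop = FALSE]
  A <- (W > 0) * 1
  St <- sweep(S, 2, t, `*`)                       # s_j * t_j per state
  LS <- (St %*% A) * S
  nj <- rowSums(S)
  ew <- rowSums((S %*% W) * S) / 2                # joined edge weight sum
  de <- ifelse(nj >= 2, ew / choose(nj, 2), 0)
  sweep(params$beta * LS, 2, params$alpha * t, `+`) +
    params$gamma * de - params$delta * (nj - 1)
}

# for every state row and free player, the row index of the state with
# only that player's bit flipped
.flip_index <- function(n_free) {
  k <- 0:(2L^n_free - 1L)
  vapply(seq_len(n_free), function(b) bitwXor(k, bitwShiftL(1L, b - 1L)) + 1L,
         integer(length(k)))
}

#' Test whether a state is a pure-strategy Nash equilibrium
#'
#' True iff no free player can strictly increase its own payoff by
#' unilaterally flipping its strategy (payoffs recomputed on the sub-game's
#' induced graph); the seed never deviates.
#'
#' @param state 0/1 vector named by player (seed = 1).
#' @param subgame a `gta_subgame`.
#' @param tscore named t-score vector.
#' @param params a [gta_params()].
#' @return logical scalar.
#' @export
is_equilibrium <- function(state, subgame, tscore, params = gta_params()) {
  players <- names(state)
  edges <- subgame_edges(subgame)
  joined <- players[state == 1L]
  free <- setdiff(players, subgame$seed)
  for (p in free) {
    dev <- if (p %in% joined) setdiff(joined, p) else c(joined, p)
    if (payoff(p, dev, edges, tscore, params) >
        payoff(p, joined, edges, tscore, params) + 1e-12)
      return(FALSE)
  }
  TRUE
}

#' Solve a sub-game by exhaustive equilibrium search
#'
#' Enumerates all states, finds every pure-strategy Nash equilibrium, and
#' among them returns the one with the highest average absolute t-score
#' over its joined genes; ties go to the larger joined set, then the
#' lexicographically smallest joined tuple.  If no pure equilibrium exists
#' the state maximizing the total payoff is returned, flagged with
#' `fallback = TRUE`.
#'
#' @inheritParams is_equilibrium
#' @param subgame a `gta_subgame`.
#' @param max_subgame_players enumeration cap.
#' @return list with `joined` (character), `state` (named 0/1 vector),
#'   `payoffs` (named numeric, the selected state's per-player payoffs),
#'   `n_equilibria`, and `fallback`.
#' @export
solve_subgame <- function(subgame, tscore, params = gta_params(),
                          max_subgame_players = 21) {
  S <- enumerate_states(subgame, max_subgame_players)
  P <- subgame_payoffs(S, subgame, tscore, params)
  nf <- ncol(S) - 1L
  if (nf == 0L) {
    eq <- 1L
  } else {
    flips <- .flip_index(nf)
    ok <- rep(TRUE, nrow(S))
    for (b in seq_len(nf)) {
      col <- b + 1L
      ok <- ok & (P[, col] >= P[flips[, b], col] - 1e-12)
    }
    eq <- which(ok)
  }
  fallback <- length(eq) == 0L
  cand <- if (fallback) which.max(rowSums(P)) else eq

  abs_t <- abs(tscore[colnames(S)])
  nj <- rowSums(S[cand, , drop = FALSE])
  mean_t <- as.vector((S[cand, , drop = FALSE] %*% abs_t) / nj)
  joined_key <- vapply(cand, function(i)
    paste(sort(colnames(S)[S[i, ] == 1L], method = "radix"), collapse = "\r"),
    character(1))
  best <- cand[order(-mean_t, -nj, joined_key, method = "radix")][1]

  state <- S[best, ]
  list(joined = sort(colnames(S)[state == 1L], method = "radix"),
       state = state,
       payoffs = stats::setNames(P[best, ], colnames(S)),
       n_equilibria = if (fallback) 0L else length(eq),
       fallback = fallback)
}

#' Merge solved sub-games into a subnetwork marker
#'
#' A gene joins the marker if it joins in at least one sub-game (union
#' rule); edges are the candidate's edges induced on the joined set; the
#' marker score is the mean absolute t-score of the joined genes.
#'
#' @param candidate the capped `gta_candidate` the sub-games came from.
#' @param solved list of [solve_subgame()] results, one per sub-game.
#' @param tscore named t-score vector.
#' @return an object of class `gta_marker`: seed, `joined` genes, induced
#'   `edges`, `score`, per-gene table `genes` (role, t-score, in-marker
#'   degree, final payoff) and a `fallback` flag.
#' @export
merge_subgames <- function(candidate, solved, tscore) {
  joined <- sort(unique(c(candidate$seed,
                          unlist(lapply(solved, `[[`, "joined")))),
                 method = "radix")
  sub <- igraph::induced_subgraph(candidate$graph, joined)
  el <- igraph::as_edgelist(sub, names = TRUE)
  w <- igraph::E(sub)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  edges <- data.frame(from = el[, 1], to = el[, 2], weight = w,
                      stringsAsFactors = FALSE)
  role <- ifelse(joined == candidate$seed, "seed",
                 ifelse(joined %in% candidate$one_step, "one-step",
                        "two-step"))
  # final payoff of a duplicated player: its payoff in the sub-game where it
  # joins with the largest value (positive evidence wins, as in the merge)
  pay <- stats::setNames(rep(NA_real_, length(joined)), joined)
  for (s in solved)
    for (gn in intersect(names(s$payoffs), joined)) {
      v <- s$payoffs[[gn]]
      if (is.na(pay[[gn]]) || v > pay[[gn]]) pay[gn] <- v
    }
  deg <- igraph::degree(sub)[joined]
  genes <- data.frame(gene = joined, role = role,
                      tscore = as.numeric(tscore[joined]),
                      degree = as.integer(deg),
                      payoff = as.numeric(pay),
                      stringsAsFactors = FALSE)
  structure(list(seed = candidate$seed, joined = joined, edges = edges,
                 score = mean(abs(tscore[joined])), genes = genes,
                 fallback = any(vapply(solved, `[[`, logical(1), "fallback"))),
            class = "gta_marker")
}

#' @export
print.gta_marker <- function(x, ...) {
  cat("Subnetwork marker '", x$seed, "': ", length(x$joined),
      " genes, ", nrow(x$edges), " edges, score (mean |t|) ",
      format(x$score, digits = 4), "\n", sep = "")
  invisible(x)
}
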
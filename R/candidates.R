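# Candidate subnetworks: seed + retained one-step and two-step neighbors,
# with the working-graph edges induced on the member set.  Stored as a plain
# list; `graph` is the induced igraph, kept so in-candidate degrees and edge
# counts never need the full network again.

.candidate <- function(seed, one_step, two_step, network) {
  members <- c(seed, one_step, two_step)
  g <- igraph::induced_subgraph(network, members)
  structure(list(seed = seed,
                 one_step = sort(one_step, method = "radix"),
                 two_step = sort(two_step, method = "radix"),
                 graph = g),
            class = "gta_candidate")
}

candidate_edges <- function(candidate) {
  el <- igraph::as_edgelist(candidate$graph, names = TRUE)
  w <- igraph::E(candidate$graph)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  data.frame(from = el[, 1], to = el[, 2], weight = w,
             stringsAsFactors = FALSE)
}

#' @export
print.gta_candidate <- function(x, ...) {
  cat("Candidate subnetwork: seed ", x$seed, ", ",
      length(x$one_step), " one-step + ", length(x$two_step),
      " two-step neighbors, ", igraph::ecount(x$graph), " edges\n", sep = "")
  invisible(x)
}

#' Rank seed genes
#'
#' Genes whose degree is at least the mean degree of the working graph,
#' sorted by decreasing absolute t-score (or signed t-score when
#' `rank_signed`), ties broken lexicographically.
#'
#' @param network working graph (igraph), every node scored.
#' @param tscore named t-score vector covering all network nodes.
#' @param rank_signed rank by signed t instead of |t|.
#' @return character vector of eligible seeds in rank order.
#' @export
rank_seeds <- function(network, tscore, rank_signed = FALSE) {
  nodes <- igraph::V(network)$name
  missing <- setdiff(nodes, names(tscore))
  if (length(missing)) stop("unscored network node(s): ",
                            paste(utils::head(missing, 5), collapse = ", "))
  deg <- igraph::degree(network)
  eligible <- nodes[deg[nodes] >= mean(deg)]
  if (length(eligible) == 0L)
    stop("no gene reaches the mean network degree; ",
         "try a smaller network or different data")
  key <- if (rank_signed) tscore[eligible] else abs(tscore[eligible])
  eligible[order(-key, eligible, method = "radix")]
}

#' Extract the unpruned candidate subnetwork around a seed
#'
#' All nodes at shortest-path distance at most two from the seed: the
#' one-step tier is the seed's direct neighbours, the two-step tier the
#' nodes at distance exactly two; edges are those of the working graph
#' induced on the member set.
#'
#' @param network working graph (igraph).
#' @param seed seed gene identifier.
#' @return a `gta_candidate`.
#' @export
extract_candidate <- function(network, seed) {
  if (!seed %in% igraph::V(network)$name)
    stop("seed not in working graph: ", seed)
  one <- igraph::V(network)$name[
    igraph::neighbors(network, seed)]
  two_ball <- igraph::V(network)$name[
    igraph::neighborhood(network, order = 2, nodes = seed)[[1]]]
  two <- setdiff(two_ball, c(seed, one))
  .candidate(seed, one, two, network)
}

#' Local clustering coefficient of a node over a given neighbour set
#'
#' Number of edges among the neighbours divided by the number of possible
#' pairs; 0 when fewer than two neighbours.  Edge weights are ignored.
#'
#' @param graph igraph whose edges define adjacency.
#' @param neighbor_set character vector of the node's current neighbours.
#' @return a number in [0, 1].
#' @export
local_clustering_coefficient <- function(graph, neighbor_set) {
  k <- length(neighbor_set)
  if (k < 2L) return(0)
  sub <- igraph::induced_subgraph(graph, neighbor_set)
  igraph::ecount(sub) / choose(k, 2)
}

# neighbours of `node` within the candidate graph restricted to `members`
.nbrs_in <- function(graph, node, members) {
  nb <- igraph::V(graph)$name[igraph::neighbors(graph, node)]
  intersect(nb, members)
}

#' Prune a candidate's neighbour tier by the clustering-coefficient rule
#'
#' Tier nodes are visited once in increasing order of in-candidate degree
#' (ties lexicographic); each is tentatively removed and the removal kept
#' exactly when it strictly increases the reference clustering value.  For
#' the one-step tier the reference is the seed's local clustering
#' coefficient over its remaining one-step neighbours; a removal that would
#' empty the tier is rejected, so at least one (the highest-degree)
#' one-step neighbour always survives.  For the two-step tier, nodes left
#' without any retained one-step neighbour are removed unconditionally
#' first; each remaining node is then re-tested against the reference
#' value selected by `two_step_rule`.  Under the default `"seed"`
#' reference a two-step removal cannot change the seed's clustering
#' coefficient, so the conditional pass accepts nothing and the tier is
#' thinned by the orphan rule alone.
#'
#' @param candidate a `gta_candidate`.
#' @param tier `"one_step"` or `"two_step"`; for `"two_step"` the one-step
#'   tier must already be pruned.
#' @param two_step_rule reference clustering value for the two-step pass:
#'   `"seed"` (default) re-evaluates the seed's own local clustering
#'   coefficient, which no two-step removal can alter, so the pass reduces
#'   to the unconditional orphan rule; `"anchor"` uses the clustering
#'   coefficient of the node's anchor; `"extended"` uses the density of
#'   the seed's full one-plus-two-step neighbourhood.
#' @return the pruned `gta_candidate`.
#' @export
prune_neighbors <- function(candidate, tier = c("one_step", "two_step"),
                            two_step_rule = c("seed", "anchor", "extended")) {
  tier <- match.arg(tier)
  two_step_rule <- match.arg(two_step_rule)
  g <- candidate$graph
  seed <- candidate$seed

  if (tier == "one_step") {
    kept <- candidate$one_step
    deg <- igraph::degree(g)[kept]
    order_nodes <- kept[order(deg, kept, method = "radix")]
    lcc <- local_clustering_coefficient(g, kept)
    for (v in order_nodes) {
      if (length(kept) == 1L) break
      trial <- setdiff(kept, v)
      lcc_trial <- local_clustering_coefficient(g, trial)
      if (lcc_trial > lcc) {
        kept <- trial
        lcc <- lcc_trial
      }
    }
    return(.candidate(seed, kept, candidate$two_step,
                      .restrict(candidate)))
  }

  one <- candidate$one_step
  members <- c(seed, one, candidate$two_step)
  # orphan rule: two-step nodes with no surviving one-step anchor go first
  kept <- Filter(function(v) length(intersect(.nbrs_in(g, v, members), one)) > 0,
                 candidate$two_step)
  kept <- as.character(kept)
  deg <- igraph::degree(g)[kept]
  order_nodes <- kept[order(deg, kept, method = "radix")]
  for (v in order_nodes) {
    current <- c(seed, one, kept)
    trial_members <- setdiff(current, v)
    if (two_step_rule == "seed") {
      # the seed's first neighbours and the edges among them do not involve
      # two-step nodes, so ref == trial always: no conditional removal
      ref <- local_clustering_coefficient(g, intersect(one, current))
      trial <- local_clustering_coefficient(g, intersect(one, trial_members))
    } else if (two_step_rule == "anchor") {
      anchor <- sort(intersect(.nbrs_in(g, v, current), one),
                     method = "radix")[1]
      ref <- local_clustering_coefficient(g, .nbrs_in(g, anchor, current))
      trial <- local_clustering_coefficient(
        g, .nbrs_in(g, anchor, trial_members))
    } else {
      ref <- local_clustering_coefficient(g, setdiff(current, seed))
      trial <- local_clustering_coefficient(g, setdiff(trial_members, seed))
    }
    if (trial > ref) kept <- setdiff(kept, v)
  }
  .candidate(seed, one, kept, .restrict(candidate))
}

# the candidate graph doubles as the "network" when re-inducing a smaller
# member set
.restrict <- function(candidate) candidate$graph

#' Cap the neighbour tiers of a pruned candidate
#'
#' If the one-step tier exceeds `max_one_step`, the top nodes by the filter
#' method are kept (`"tscore"`: largest |t|; `"degree"`: largest
#' in-candidate degree; ties lexicographic).  Two-step nodes orphaned by
#' one-step capping are removed, then each retained anchor keeps at most
#' its `max_two_step` top-ranked adjacent two-step nodes; a two-step node
#' survives if some anchor retains it.
#'
#' @param candidate a pruned `gta_candidate`.
#' @param max_one_step,max_two_step integers in 1..19.
#' @param filter_method `"tscore"` or `"degree"`.
#' @param tscore named t-score vector (required for `"tscore"`).
#' @return the capped `gta_candidate`.
#' @export
apply_caps <- function(candidate, max_one_step = 4, max_two_step = 3,
                       filter_method = c("tscore", "degree"),
                       tscore = NULL) {
  filter_method <- match.arg(filter_method)
  for (cap in c(max_one_step, max_two_step))
    if (cap < 1 || cap > 19) stop("neighbor caps must be in 1..19, got ", cap)
  g <- candidate$graph
  keyfun <- function(nodes) {
    if (filter_method == "tscore") {
      if (is.null(tscore)) stop("tscore vector required for filter_method='tscore'")
      abs(tscore[nodes])
    } else igraph::degree(g)[nodes]
  }
  top_k <- function(nodes, k) {
    if (length(nodes) <= k) return(nodes)
    nodes[order(-keyfun(nodes), nodes, method = "radix")][seq_len(k)]
  }

  one <- top_k(candidate$one_step, max_one_step)
  members <- c(candidate$seed, one, candidate$two_step)
  two <- Filter(function(v) length(intersect(.nbrs_in(g, v, members), one)) > 0,
                candidate$two_step)
  two <- as.character(two)
  retained <- character(0)
  for (a in one) {
    adj <- intersect(.nbrs_in(g, a, members), two)
    retained <- union(retained, top_k(adj, max_two_step))
  }
  .candidate(candidate$seed, one, sort(retained, method = "radix"),
             .restrict(candidate))
}
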
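# seed ranking, two-step extraction, LCC pruning, caps

graph_from_pairs <- function(...) {
  el <- matrix(c(...), ncol = 2, byrow = TRUE)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- 1
  g
}

# the canonical worked game: seed with 4 one-step neighbours, each anchoring 3
# exclusive two-step nodes (12 in total)
canonical_game_graph <- function() {
  pairs <- c()
  anchors <- paste0("a", 1:4)
  for (i in 1:4) {
    pairs <- c(pairs, "seed", anchors[i])
    for (j in 1:3)
      pairs <- c(pairs, anchors[i], sprintf("b%d%d", i, j))
  }
  graph_from_pairs(pairs)
}

test_that("seeds need at least mean degree and sort by decreasing |t|", {
  g <- graph_from_pairs("A", "B", "B", "C")  # degrees 1,2,1; mean 4/3
  tsc <- c(A = 5, B = 1, C = -2)
  expect_equal(rank_seeds(g, tsc), "B")
  ring <- graph_from_pairs("A", "B", "B", "C", "C", "D", "D", "A")
  tsc2 <- c(A = -3.1, B = 2.0, C = 0.5, D = 2.0)
  expect_equal(rank_seeds(ring, tsc2), c("A", "B", "D", "C"))
  expect_equal(rank_seeds(ring, tsc2, rank_signed = TRUE),
               c("B", "D", "C", "A"))
  expect_error(rank_seeds(ring, tsc2[1:3]), "unscored")
})

test_that("candidates contain exactly the distance <= 2 ball", {
  star <- graph_from_pairs("S", "L1", "S", "L2", "S", "L3", "S", "L4")
  cand <- extract_candidate(star, "S")
  expect_setequal(cand$one_step, paste0("L", 1:4))
  expect_length(cand$two_step, 0)

  cand2 <- extract_candidate(canonical_game_graph(), "seed")
  expect_length(cand2$one_step, 4)
  expect_length(cand2$two_step, 12)

  path <- graph_from_pairs("S", "A", "A", "B", "B", "C")
  cand3 <- extract_candidate(path, "S")
  expect_false("C" %in% c(cand3$one_step, cand3$two_step))  # distance 3
  expect_error(extract_candidate(path, "nope"), "not in")
})

test_that("local clustering coefficient counts realized neighbour pairs", {
  g <- graph_from_pairs("S", "A", "S", "B", "S", "C",
                        "A", "B", "B", "C", "A", "C")
  expect_equal(local_clustering_coefficient(g, c("A", "B", "C")), 1)
  star <- graph_from_pairs("S", "A", "S", "B", "S", "C")
  expect_equal(local_clustering_coefficient(star, c("A", "B", "C")), 0)
  g2 <- graph_from_pairs("S", "A", "S", "B", "S", "C", "A", "B")
  expect_equal(local_clustering_coefficient(g2, c("A", "B", "C")), 1 / 3)
  expect_equal(local_clustering_coefficient(g2, "A"), 0)  # < 2 neighbours
})

test_that("one-step pruning removes exactly the nodes that raise seed LCC", {
  # seed S with neighbours A,B,C; only A-B among them: LCC 1/3; dropping C
  # (lowest in-candidate degree) raises it to 1; dropping more would hit 0
  g <- graph_from_pairs("S", "A", "S", "B", "S", "C", "A", "B")
  cand <- prune_neighbors(extract_candidate(g, "S"), "one_step")
  expect_setequal(cand$one_step, c("A", "B"))

  # clique: LCC already 1, nothing pruned
  kl <- graph_from_pairs("S", "A", "S", "B", "S", "C",
                         "A", "B", "B", "C", "A", "C")
  cand2 <- prune_neighbors(extract_candidate(kl, "S"), "one_step")
  expect_setequal(cand2$one_step, c("A", "B", "C"))

  # star: every LCC is 0, no strict increase possible, nothing pruned
  star <- graph_from_pairs("S", "A", "S", "B", "S", "C")
  cand3 <- prune_neighbors(extract_candidate(star, "S"), "one_step")
  expect_setequal(cand3$one_step, c("A", "B", "C"))
  expect_gte(length(cand3$one_step), 1)
})

test_that("two-step pruning drops orphans first, then applies the LCC rule", {
  # C is pruned from the one-step tier (as above); X was anchored only at C
  g <- graph_from_pairs("S", "A", "S", "B", "S", "C", "A", "B", "C", "X")
  cand <- prune_neighbors(extract_candidate(g, "S"), "one_step")
  expect_setequal(cand$one_step, c("A", "B"))
  cand <- prune_neighbors(cand, "two_step")
  expect_false("X" %in% cand$two_step)
})

test_that("seed LCC never decreases across the one-step pruning pass", {
  set.seed(5)
  for (i in 1:15) {
    g <- igraph::sample_gnp(25, 0.15)
    igraph::V(g)$name <- sprintf("n%02d", 1:25)
    igraph::E(g)$weight <- 1
    seeds <- igraph::V(g)$name[igraph::degree(g) >= 2]
    if (length(seeds) == 0) next
    s <- seeds[1]
    cand <- extract_candidate(g, s)
    before <- local_clustering_coefficient(cand$graph, cand$one_step)
    after_cand <- prune_neighbors(cand, "one_step")
    after <- local_clustering_coefficient(after_cand$graph,
                                          after_cand$one_step)
    expect_gte(after, before)
    expect_gte(length(after_cand$one_step), 1)
  }
})

test_that("candidate membership ignores edge-list order", {
  rows <- c("S\tA", "S\tB", "A\tB", "B\tC", "C\tD", "A\tC")
  f1 <- tempfile(); writeLines(rows, f1)
  f2 <- tempfile(); writeLines(rev(rows), f2)
  c1 <- extract_candidate(read_network(f1), "S")
  c2 <- extract_candidate(read_network(f2), "S")
  expect_identical(c1$one_step, c2$one_step)
  expect_identical(c1$two_step, c2$two_step)
})

test_that("caps keep the top nodes by the filter method", {
  # seed with 6 one-step neighbours, no pruning possible (star)
  pairs <- unlist(lapply(1:6, function(i) c("S", paste0("n", i))))
  g <- graph_from_pairs(pairs)
  cand <- extract_candidate(g, "S")
  tsc <- setNames(c(0, 6:1), c("S", paste0("n", 1:6)))
  capped <- apply_caps(cand, max_one_step = 4, max_two_step = 3,
                       filter_method = "tscore", tscore = tsc)
  expect_setequal(capped$one_step, paste0("n", 1:4))

  expect_error(apply_caps(cand, 0, 3, "tscore", tsc), "1..19")
  expect_error(apply_caps(cand, 4, 20, "tscore", tsc), "1..19")

  within <- apply_caps(cand, 19, 19, "tscore", tsc)
  expect_setequal(within$one_step, cand$one_step)  # no-op inside caps
})

test_that("two-step caps are per anchor and orphans are removed", {
  cand <- extract_candidate(canonical_game_graph(), "seed")
  tsc <- setNames(seq_along(c("seed", cand$one_step, cand$two_step)),
                  c("seed", cand$one_step, cand$two_step))
  capped <- apply_caps(cand, max_one_step = 2, max_two_step = 2,
                       filter_method = "tscore", tscore = tsc)
  expect_length(capped$one_step, 2)
  g <- capped$graph
  members <- c("seed", capped$one_step, capped$two_step)
  for (v in capped$two_step) {
    nb <- igraph::V(g)$name[igraph::neighbors(g, v)]
    expect_gte(length(intersect(nb, capped$one_step)), 1)
  }
  # each surviving anchor keeps at most 2 two-step nodes here (exclusive)
  expect_lte(length(capped$two_step), 2 * 2)

  bydeg <- apply_caps(cand, max_one_step = 2, max_two_step = 3,
                      filter_method = "degree")
  expect_length(bydeg$one_step, 2)
})

test_that("alternative two-step pruning references prune weakly attached nodes", {
  # triangle S-A-B with a pendant two-step X on A: the default seed
  # reference keeps X (seed LCC is unaffected), while the anchor and
  # extended references both drop it
  g <- graph_from_pairs("S", "A", "S", "B", "A", "B", "A", "X")
  cand <- prune_neighbors(extract_candidate(g, "S"), "one_step")
  expect_setequal(cand$one_step, c("A", "B"))
  by_seed <- prune_neighbors(cand, "two_step", "seed")
  expect_true("X" %in% by_seed$two_step)
  by_anchor <- prune_neighbors(cand, "two_step", "anchor")
  expect_false("X" %in% by_anchor$two_step)
  by_ext <- prune_neighbors(cand, "two_step", "extended")
  expect_false("X" %in% by_ext$two_step)
})
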
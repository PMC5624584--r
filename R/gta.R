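#' Find discriminative subnetwork markers by game-theoretic search
#'
#' Runs the full marker-discovery pipeline on an interaction network and a
#' two-phenotype expression profile.  The working gene universe is the
#' intersection of network nodes and profile genes (nodes without
#' expression cannot play).  Every gene is scored by the Welch t-statistic
#' of its log-likelihood-ratio vector; genes with at least the mean network
#' degree become seeds, in decreasing |t| order.  Around each seed a
#' candidate subnetwork of all genes within two steps is extracted, pruned
#' to raise the seed's local clustering coefficient, capped, decomposed
#' into per-anchor sub-games, solved by exhaustive pure-strategy Nash
#' equilibrium search, and merged into one marker.  Markers with identical
#' joined sets collapse to the higher-ranked seed's marker; the final list
#' is sorted by marker score (mean |t| of joined genes) and truncated to
#' `n_results`.
#'
#' @param network an undirected igraph (e.g. from [read_network()]).
#' @param profile an [expression_profile()] (e.g. from [read_expression()]).
#' @param params payoff constants, a [gta_params()].
#' @param max_one_step,max_two_step neighbour caps, integers in 1..19.
#' @param n_results number of markers to return.
#' @param filter_method `"tscore"` or `"degree"`: how a tier over its cap
#'   is thinned.
#' @param two_step_rule reference clustering value of the two-step pruning
#'   pass; see [prune_neighbors()].
#' @param rank_signed rank seeds by signed t instead of |t|.
#' @param max_subgame_players refusal cap on free players per sub-game.
#' @param verbose print per-stage progress messages.
#' @return an object of class `gta`: list with `markers` (list of
#'   `gta_marker`), `scores` (`gene_scores`), `summary` (stage counts),
#'   `config`, and `call`.  Deterministic: identical inputs give identical
#'   output.
#' @seealso [summary.gta()], [plot.gta()], [write_markers()]
#' @examples
#' sim <- simulate_gta_data(n_genes = 60, module_size = 8, seed = 1)
#' fit <- gta(sim$network, sim$profile, n_results = 5)
#' fit
#' summary(fit)
#' @export
gta <- function(network, profile, params = gta_params(),
                max_one_step = 4, max_two_step = 3, n_results = 50,
                filter_method = c("tscore", "degree"), rank_signed = FALSE,
                two_step_rule = c("seed", "anchor", "extended"),
                max_subgame_players = 21, verbose = FALSE) {
  filter_method <- match.arg(filter_method)
  two_step_rule <- match.arg(two_step_rule)
  stopifnot(inherits(profile, "expression_profile"), n_results >= 1)
  say <- if (verbose) message else function(...) invisible(NULL)

  universe <- intersect(igraph::V(network)$name, rownames(profile$values))
  if (length(universe) == 0L)
    stop("no shared gene identifiers between network and expression profile; ",
         "the same nomenclature must be used in both")
  n_dropped_nodes <- igraph::vcount(network) - length(universe)
  work <- igraph::induced_subgraph(network, universe)
  if (!"weight" %in% igraph::edge_attr_names(work))
    igraph::E(work)$weight <- 1
  say("working graph: ", length(universe), " genes (",
      n_dropped_nodes, " unscoreable nodes removed), ",
      igraph::ecount(work), " edges")

  prof <- expression_profile(
    profile$values[intersect(rownames(profile$values), universe), ,
                   drop = FALSE],
    stats::setNames(profile$labels, colnames(profile$values)))
  scores <- score_genes(prof)

  seeds <- rank_seeds(work, scores$tscore, rank_signed = rank_signed)
  say(length(seeds), " eligible seeds")

  markers <- list()
  seen <- character(0)
  n_dup <- 0L
  for (seed in seeds) {
    cand <- extract_candidate(work, seed)
    cand <- prune_neighbors(cand, "one_step")
    cand <- prune_neighbors(cand, "two_step", two_step_rule)
    cand <- apply_caps(cand, max_one_step, max_two_step, filter_method,
                       tscore = scores$tscore)
    games <- decompose(cand, max_subgame_players)
    solved <- lapply(games, solve_subgame, tscore = scores$tscore,
                     params = params,
                     max_subgame_players = max_subgame_players)
    mk <- merge_subgames(cand, solved, scores$tscore)
    key <- paste(mk$joined, collapse = "\r")
    if (key %in% seen) {
      n_dup <- n_dup + 1L
      next
    }
    seen <- c(seen, key)
    markers[[length(markers) + 1L]] <- mk
  }
  say(length(markers), " distinct markers (", n_dup, " duplicates dropped)")

  sc <- vapply(markers, `[[`, numeric(1), "score")
  sd_names <- vapply(markers, `[[`, character(1), "seed")
  markers <- markers[order(-sc, sd_names, method = "radix")]
  out <- markers[seq_len(min(n_results, length(markers)))]

  structure(list(
    markers = out,
    scores = scores,
    summary = list(n_genes_network = igraph::vcount(network),
                   n_genes_profile = nrow(profile$values),
                   n_genes_working = length(universe),
                   n_nodes_dropped = n_dropped_nodes,
                   n_seeds_eligible = length(seeds),
                   n_seeds_processed = length(seeds),
                   n_duplicates_dropped = n_dup,
                   n_markers_found = length(markers),
                   n_markers_returned = length(out),
                   n_fallback = sum(vapply(out, `[[`, logical(1), "fallback"))),
    config = list(params = params, max_one_step = max_one_step,
                  max_two_step = max_two_step, n_results = n_results,
                  filter_method = filter_method, rank_signed = rank_signed,
                  two_step_rule = two_step_rule,
                  max_subgame_players = max_subgame_players),
    call = match.call()),
    class = "gta")
}

#' @export
print.gta <- function(x, ...) {
  cat("Game-theoretic subnetwork marker search\n")
  cat("  working genes: ", x$summary$n_genes_working,
      ", eligible seeds: ", x$summary$n_seeds_eligible, "\n", sep = "")
  cat("  markers returned: ", x$summary$n_markers_returned,
      " (of ", x$summary$n_markers_found, " distinct)\n", sep = "")
  if (length(x$markers)) {
    cat("  top marker: ")
    print(x$markers[[1]])
  }
  invisible(x)
}

#' Summarize a marker search
#'
#' @param object a `gta` fit.
#' @param ... unused.
#' @return data frame with one row per marker: rank, seed, number of genes
#'   and edges, score (mean |t| of joined genes), and member list.
#' @export
summary.gta <- function(object, ...) {
  m <- object$markers
  data.frame(
    rank = seq_along(m),
    seed = vapply(m, `[[`, character(1), "seed"),
    n_genes = vapply(m, function(z) length(z$joined), integer(1)),
    n_edges = vapply(m, function(z) nrow(z$edges), integer(1)),
    score = vapply(m, `[[`, numeric(1), "score"),
    genes = vapply(m, function(z) paste(z$joined, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE)
}

#' @export
as.data.frame.gta <- function(x, ...) summary.gta(x)

#' Plot a subnetwork marker
#'
#' Draws the induced graph of the `which`-th marker; the seed, one-step
#' and two-step members get distinct colours.
#'
#' @param x a `gta` fit.
#' @param which marker rank to plot.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.gta <- function(x, which = 1, ...) {
  if (length(x$markers) == 0L) stop("no markers to plot")
  mk <- x$markers[[which]]
  g <- igraph::graph_from_data_frame(mk$edges, directed = FALSE,
                                     vertices = mk$joined)
  cols <- c(seed = "tomato", `one-step` = "skyblue", `two-step` = "palegreen")
  role <- mk$genes$role[match(igraph::V(g)$name, mk$genes$gene)]
  igraph::plot.igraph(g, vertex.color = cols[role],
                      main = paste0("Marker '", mk$seed, "' (mean |t| = ",
                                    format(mk$score, digits = 3), ")"), ...)
  invisible(x)
}

#' Write markers to disk
#'
#' One SIF file per marker (its induced edges, relation `pp`), a summary
#' TSV (rank, marker name = seed gene, member gene, role, optionally
#' t-score and in-marker degree), and a JSON run summary with the
#' configuration and stage counts.  An empty marker list still writes the
#' summary files.
#'
#' @param fit a `gta` object, or a plain list of `gta_marker`s.
#' @param out_dir output directory, created if needed.
#' @param show_tscores,show_degrees include the optional columns.
#' @return character vector of written file paths, invisibly.
#' @export
write_markers <- function(fit, out_dir, show_tscores = TRUE,
                          show_degrees = TRUE) {
  markers <- if (inherits(fit, "gta")) fit$markers else fit
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  rows <- list()
  for (i in seq_along(markers)) {
    mk <- markers[[i]]
    sif <- file.path(out_dir,
                     sprintf("marker_%03d_%s.sif", i, mk$seed))
    if (nrow(mk$edges) > 0) {
      writeLines(paste(mk$edges$from, "pp", mk$edges$to, sep = "\t"), sif)
    } else {
      writeLines(mk$seed, sif)
    }
    paths <- c(paths, sif)
    df <- data.frame(rank = i, marker = mk$seed, gene = mk$genes$gene,
                     role = mk$genes$role, stringsAsFactors = FALSE)
    if (show_tscores) df$tscore <- mk$genes$tscore
    if (show_degrees) df$degree <- mk$genes$degree
    rows[[i]] <- df
  }
  summary_tsv <- file.path(out_dir, "markers_summary.tsv")
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rank = integer(0), marker = character(0),
               gene = character(0), role = character(0))
  utils::write.table(tab, summary_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, summary_tsv)

  run <- list(n_markers = length(markers),
              show_tscores = show_tscores, show_degrees = show_degrees)
  if (inherits(fit, "gta")) {
    cfg <- fit$config
    cfg$params <- unclass(cfg$params)
    run$config <- cfg
    run$counts <- fit$summary
    if (fit$summary$n_markers_returned < fit$config$n_results)
      run$shortfall <- paste0(fit$config$n_results, " markers requested, ",
                              fit$summary$n_markers_returned, " found")
  }
  summary_json <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(run, summary_json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, summary_json)
  invisible(paths)
}
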
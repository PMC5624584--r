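#' Simulate a network and expression profile with a planted module
#'
#' Generates the data structure the marker search assumes: an
#' Erdos-Renyi background interaction graph in which a small module is
#' rewired to a higher edge probability (and forced connected by a random
#' spanning tree over the module), together with Gaussian expression in
#' which only the planted genes shift their case-class mean.  Background
#' genes are Normal(0, sd) in both classes; planted genes are
#' Normal(effect, sd) in cases and Normal(0, sd) in controls.
#'
#' @param n_genes total number of genes (network nodes).
#' @param p_background background edge probability.
#' @param module_size number of planted genes.
#' @param p_module edge probability within the planted module
#'   (>= `p_background`).
#' @param n_case,n_control samples per class (each >= 3).
#' @param effect mean expression shift of planted genes in the case class,
#'   in noise-sd units when `noise_sd = 1`.
#' @param noise_sd within-class expression standard deviation.
#' @param log_normal if TRUE, expression values are exponentiated
#'   (log-normal data) to probe robustness to the Gaussian assumption.
#' @param seed RNG seed; with a fixed seed generation is reproducible.
#' @return list with `network` (igraph, all edge weights 1), `profile`
#'   (an [expression_profile()]), and `planted` (character vector of
#'   planted gene names).
#' @export
simulate_gta_data <- function(n_genes = 200, p_background = 0.02,
                              module_size = 10, p_module = 0.6,
                              n_case = 20, n_control = 20,
                              effect = 2, noise_sd = 1,
                              log_normal = FALSE, seed = 1) {
  stopifnot(module_size <= n_genes, n_case >= 3, n_control >= 3,
            p_module >= p_background, p_background > 0, p_background < 1)
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  planted <- genes[seq_len(module_size)]

  pairs <- utils::combn(genes, 2)
  both_planted <- pairs[1, ] %in% planted & pairs[2, ] %in% planted
  p_edge <- ifelse(both_planted, p_module, p_background)
  keep <- stats::runif(ncol(pairs)) < p_edge
  from <- pairs[1, keep]; to <- pairs[2, keep]

  # connectivity of the planted module: add a random spanning tree
  if (module_size >= 2) {
    perm <- sample(planted)
    for (i in 2:module_size) {
      a <- perm[i]; b <- perm[sample.int(i - 1L, 1L)]
      from <- c(from, min(a, b)); to <- c(to, max(a, b))
    }
  }
  net <- igraph::simplify(igraph::graph_from_data_frame(
    data.frame(from = from, to = to), directed = FALSE, vertices = genes))
  igraph::E(net)$weight <- 1
  if (module_size >= 2 &&
      !igraph::is_connected(igraph::induced_subgraph(net, planted)))
    stop("internal error: planted module disconnected after enforcement")

  m <- n_case + n_control
  samples <- sprintf("s%03d", seq_len(m))
  labels <- stats::setNames(rep(c(1L, 2L), c(n_case, n_control)), samples)
  vals <- matrix(stats::rnorm(n_genes * m, 0, noise_sd), n_genes, m,
                 dimnames = list(genes, samples))
  vals[planted, labels == 1L] <- vals[planted, labels == 1L] + effect
  if (log_normal) vals <- exp(vals)

  list(network = net,
       profile = expression_profile(vals, labels),
       planted = planted)
}

#' Write a simulated data set to disk
#'
#' Emits the network TSV edge list, expression matrix TSV, labels TSV and
#' the planted-gene truth list, in the formats [read_network()] and
#' [read_expression()] load.
#'
#' @param sim result of [simulate_gta_data()].
#' @param out_dir output directory, created if needed.
#' @return named character vector of the four file paths, invisibly.
#' @export
write_gta_sim <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(out_dir, "network.tsv"),
             expression = file.path(out_dir, "expression.tsv"),
             labels = file.path(out_dir, "labels.tsv"),
             truth = file.path(out_dir, "planted_genes.txt"))
  write_network(sim$network, paths[["network"]])
  write_expression(sim$profile, paths[["expression"]], paths[["labels"]])
  writeLines(sim$planted, paths[["truth"]])
  invisible(paths)
}

#' Jaccard index of two gene sets
#'
#' @param a,b character vectors.
#' @return |a intersect b| / |a union b|.
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}
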
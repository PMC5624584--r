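#' Payoff parameters
#'
#' Weighting constants of the payoff function: `alpha` scales a player's own
#' expression evidence (t-score of its LLR vector), `beta` the local
#' neighbourhood score, `gamma` the density of the joined subgraph, and
#' `delta` the per-member size penalty.  The defaults are the published
#' calibration of the algorithm.
#'
#' @param alpha,beta,gamma,delta non-negative reals.
#' @return a list of class `gta_params`.
#' @export
gta_params <- function(alpha = 1.24, beta = 1, gamma = 1, delta = 2) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma),
            is.numeric(delta))
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta),
            class = "gta_params")
}

# sd floor: constant genes would otherwise yield a degenerate Gaussian and
# infinite LLR values
.SD_FLOOR <- 1e-6

#' Fit per-phenotype Gaussian densities for one gene
#'
#' Sample mean and unbiased (n-1) standard deviation of the gene's
#' expression in each phenotype class; the standard deviation is floored at
#' 1e-6 so that constant genes still define a proper density.
#'
#' @param profile an [expression_profile()].
#' @param gene gene identifier.
#' @return list with elements `class1` and `class2`, each `c(mean, sd)`.
#' @export
fit_class_densities <- function(profile, gene) {
  if (!gene %in% rownames(profile$values))
    stop("gene not in expression profile: ", gene)
  x <- profile$values[gene, ]
  fit1 <- function(v) c(mean = mean(v), sd = max(stats::sd(v), .SD_FLOOR))
  list(class1 = fit1(x[profile$labels == 1L]),
       class2 = fit1(x[profile$labels == 2L]))
}

#' Per-sample log-likelihood ratio of one gene
#'
#' For each labeled sample j, the natural log of the ratio of the fitted
#' phenotype-1 Gaussian density to the phenotype-2 density evaluated at the
#' gene's expression in that sample:
#' \eqn{LLR_i(x_{ij}) = \log[f_{i1}(x_{ij}) / f_{i2}(x_{ij})]}.
#'
#' @inheritParams fit_class_densities
#' @return numeric vector of length `m` (number of labeled samples), in
#'   sample order.
#' @export
compute_llr <- function(profile, gene) {
  fits <- fit_class_densities(profile, gene)
  x <- profile$values[gene, ]
  stats::dnorm(x, fits$class1["mean"], fits$class1["sd"], log = TRUE) -
    stats::dnorm(x, fits$class2["mean"], fits$class2["sd"], log = TRUE)
}

#' Welch t-statistic of an LLR vector between the two phenotype classes
#'
#' Unpaired two-sample t assuming unequal variances, class 1 (case) minus
#' class 2 (control) in the numerator.  When both class variances vanish
#' the statistic is 0 for equal means; a variance floor keeps the value
#' finite when the means differ.
#'
#' @param llr numeric vector indexed like `labels`.
#' @param labels integer vector of 1/2 phenotype labels.
#' @return a single finite number.
#' @export
tscore_llr <- function(llr, labels) {
  if (length(llr) != length(labels))
    stop("llr vector and labels differ in length")
  x1 <- llr[labels == 1L]; x2 <- llr[labels == 2L]
  m1 <- mean(x1); m2 <- mean(x2)
  v1 <- stats::var(x1); v2 <- stats::var(x2)
  if (v1 < 1e-12 && v2 < 1e-12 && isTRUE(all.equal(m1, m2))) return(0)
  se <- sqrt(max(v1 / length(x1) + v2 / length(x2), 1e-24))
  (m1 - m2) / se
}

#' Score every gene of a profile
#'
#' Computes the LLR vector and its Welch t-score for each gene.
#'
#' @param profile an [expression_profile()].
#' @return list of class `gene_scores` with `llr` (gene x sample matrix) and
#'   `tscore` (named numeric vector).
#' @export
score_genes <- function(profile) {
  genes <- rownames(profile$values)
  llr <- t(vapply(genes, function(g) compute_llr(profile, g),
                  numeric(ncol(profile$values))))
  dimnames(llr) <- dimnames(profile$values)
  tsc <- apply(llr, 1, tscore_llr, labels = profile$labels)
  structure(list(llr = llr, tscore = tsc, labels = profile$labels),
            class = "gene_scores")
}

#' Local score of a gene under a strategy state
#'
#' Sum of the t-scores of the gene's neighbours that currently join the
#' subnetwork; a gene playing the leaving strategy has no neighbour in the
#' subnetwork, so its local score is 0.
#'
#' @param gene gene identifier.
#' @param joined_neighbors identifiers of the gene's neighbours with
#'   joining strategy.
#' @param tscore named numeric vector of per-gene t-scores.
#' @param strategy `"join"` or `"leave"`.
#' @return a single number.
#' @export
local_score <- function(gene, joined_neighbors, tscore,
                        strategy = c("join", "leave")) {
  strategy <- match.arg(strategy)
  if (strategy == "leave") return(0)
  if (length(joined_neighbors) == 0L) return(0)
  missing <- setdiff(joined_neighbors, names(tscore))
  if (length(missing)) stop("unscored neighbor(s): ",
                            paste(missing, collapse = ", "))
  sum(tscore[joined_neighbors])
}

#' Density of the joined subgraph
#'
#' Sum of the weights of edges with both endpoints joined, divided by the
#' number of possible pairs \eqn{\binom{|V_{join}|}{2}}; 0 when fewer than
#' two nodes join.  The value is shared by all players of the state.
#'
#' @param joined character vector of joined node identifiers.
#' @param edges data frame with columns `from`, `to`, `weight`.
#' @return a single number.
#' @export
subnetwork_density <- function(joined, edges) {
  n <- length(joined)
  if (n < 2L) return(0)
  inside <- edges$from %in% joined & edges$to %in% joined
  sum(edges$weight[inside]) / choose(n, 2)
}

#' Gain of a player in a strategy state
#'
#' \eqn{GF = \alpha\, t\text{-}score(LLR_i) + \beta\, LS_i + \gamma\, DE(G_{join})}.
#' The own t-score and the shared density term apply under either strategy;
#' only the local score depends on the player's own choice.
#'
#' @param gene player identifier.
#' @param joined joined node set of the state.
#' @param edges induced edge set of the game (data frame `from,to,weight`).
#' @param tscore named t-score vector covering all players.
#' @param params a [gta_params()].
#' @return a single number.
#' @export
gain <- function(gene, joined, edges, tscore, params = gta_params()) {
  if (!gene %in% names(tscore)) stop("unscored gene: ", gene)
  strat <- if (gene %in% joined) "join" else "leave"
  nb <- unique(c(edges$to[edges$from == gene], edges$from[edges$to == gene]))
  ls <- local_score(gene, intersect(nb, setdiff(joined, gene)), tscore, strat)
  params$alpha * tscore[[gene]] + params$beta * ls +
    params$gamma * subnetwork_density(joined, edges)
}

#' Loss of a player in a strategy state
#'
#' \eqn{LF = \delta\,(|V_{join}| - 1)}: a size penalty shared by every
#' player regardless of its own strategy.  The seed always joins, so the
#' joined count is at least 1.
#'
#' @param joined_count number of joined players (>= 1).
#' @param params a [gta_params()].
#' @return a single number.
#' @export
loss <- function(joined_count, params = gta_params()) {
  if (joined_count < 1L)
    stop("joined_count must be >= 1 (the seed always joins)")
  params$delta * (joined_count - 1)
}

#' Payoff of a player in a strategy state
#'
#' Gain minus loss for this player under this state.
#'
#' @inheritParams gain
#' @return a single number.
#' @export
payoff <- function(gene, joined, edges, tscore, params = gta_params()) {
  gain(gene, joined, edges, tscore, params) -
    loss(length(joined), params)
}
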
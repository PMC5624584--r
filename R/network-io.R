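#' Read an interaction network from a SIF or TSV edge list
#'
#' Loads an undirected, optionally edge-weighted interaction network.
#' Two dialects are supported: Cytoscape-style SIF (`A <relation> B [B2 ...]`,
#' relation ignored) and a 2/3-column TSV edge list (`A B [weight]`, optional
#' header, `#` comment lines skipped, a single-token row declaring an
#' isolated node).  Duplicate edges are collapsed keeping
#' the maximum weight, self-loops are dropped (with a message reporting the
#' count), and unweighted input yields weight 1 on every edge.
#'
#' @param path path to the network file.
#' @param dialect `"tsv"` (default) or `"sif"`.
#' @return an undirected [igraph::igraph] with vertex attribute `name` and
#'   edge attribute `weight`; attributes `n_self_loops_dropped` and
#'   `n_duplicates_collapsed` record the load summary.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB\t0.5", "B\tA\t0.7", "B\tC"), f)
#' g <- read_network(f)
#' igraph::E(g)$weight  # 0.7 (max of duplicates) and 1 (unweighted default)
#' @export
read_network <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0L) stop("network file is empty: ", path)

  from <- character(0); to <- character(0); w <- numeric(0)
  iso <- character(0)
  first_data_row <- TRUE
  for (i in rows) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (dialect == "sif") {
      if (length(tok) < 3L)
        stop("malformed SIF row at line ", i, ": expected 'A <relation> B'")
      a <- tok[1]; bs <- tok[-(1:2)]
      from <- c(from, rep(a, length(bs))); to <- c(to, bs)
      w <- c(w, rep(1, length(bs)))
    } else {
      if (length(tok) == 1L) {  # isolated node declaration
        iso <- c(iso, tok)
        first_data_row <- FALSE
        next
      }
      if (length(tok) > 3L)
        stop("malformed TSV row at line ", i, ": expected 'A B [weight]'")
      if (first_data_row && length(tok) == 3L && is.na(suppressWarnings(as.numeric(tok[3])))) {
        first_data_row <- FALSE
        next  # header row
      }
      first_data_row <- FALSE
      wt <- if (length(tok) == 3L) suppressWarnings(as.numeric(tok[3])) else 1
      if (is.na(wt)) stop("malformed weight at line ", i, ": '", tok[3], "'")
      if (wt <= 0) stop("non-positive edge weight at line ", i, ": ", wt)
      from <- c(from, tok[1]); to <- c(to, tok[2]); w <- c(w, wt)
    }
  }

  self <- from == to
  n_self <- sum(self)
  if (n_self > 0) {
    message("read_network: dropped ", n_self, " self-loop(s)")
    from <- from[!self]; to <- to[!self]; w <- w[!self]
  }
  nodes <- sort(unique(c(from, to, iso)), method = "radix")
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  n_before <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(weight = "max"))
  g$n_self_loops_dropped <- n_self
  g$n_duplicates_collapsed <- n_before - igraph::ecount(g)
  g
}

#' Write an interaction network as a TSV edge list
#'
#' Inverse of [read_network()] for the TSV dialect: one `from to weight` row
#' per stored edge, endpoints in sorted order within each row, rows sorted.
#'
#' @param network an undirected igraph with `weight` edge attribute.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  w <- igraph::E(network)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  ord <- order(a, b, method = "radix")
  iso <- igraph::V(network)$name[igraph::degree(network) == 0]
  writeLines(c(paste(a[ord], b[ord],
                     format(w[ord], digits = 17, trim = TRUE), sep = "\t"),
               sort(iso, method = "radix")), path)
  invisible(path)
}
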
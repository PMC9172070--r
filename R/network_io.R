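#' Gene interaction networks
#'
#' A `gene_network` is an undirected graph on gene symbols used as the global
#' template network for local-entropy scoring. It is stored as a node vector,
#' a two-column edge table and a precomputed adjacency list (neighbors sorted
#' lexicographically, so downstream weight vectors are reproducibly indexed).
#' Invariants enforced by every constructor path: no self-loops, no duplicate
#' edges, and no isolated nodes (every node has degree >= 1).
#'
#' Identifier mapping (protein to gene symbol, orthology) is out of scope:
#' inputs are assumed to be pre-mapped to the same gene symbols used by the
#' expression matrix.
#'
#' @param edges two-column character matrix or data.frame of edge endpoints.
#' @param confidence_threshold confidence level at/above which the source
#'   edges were retained, on the unit scale.
#' @return an object of class `gene_network` with elements `nodes` (sorted
#'   character vector), `edges` (data.frame with columns `from`, `to`,
#'   `from < to` lexicographically), `adj` (named list of sorted neighbor
#'   vectors) and `confidence_threshold`.
#' @export
gene_network <- function(edges, confidence_threshold = NA_real_) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  mode(edges) <- "character"
  dimnames(edges) <- NULL
  keep <- edges[, 1] != edges[, 2]            # drop self-loops
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) > 0) {
    swap <- edges[, 1] > edges[, 2]           # canonical order within edge
    edges[swap, ] <- edges[swap, 2:1]
    edges <- unique(edges)
  }
  nodes <- sort(unique(as.vector(edges)))
  adj <- .adjacency_list(nodes, edges)
  structure(
    list(nodes = nodes,
         edges = data.frame(from = edges[, 1], to = edges[, 2],
                            stringsAsFactors = FALSE, row.names = NULL),
         adj = adj,
         confidence_threshold = confidence_threshold),
    class = "gene_network")
}

.adjacency_list <- function(nodes, edges) {
  adj <- lapply(
    split(c(edges[, 2], edges[, 1]), factor(c(edges[, 1], edges[, 2]), levels = nodes)),
    function(x) sort(unique(x)))
  adj[nodes]
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges", length(x$nodes), nrow(x$edges)))
  if (!is.na(x$confidence_threshold))
    cat(sprintf(" (confidence >= %.3g)", x$confidence_threshold))
  cat("\n")
  invisible(x)
}

#' Load a PPI edge list and build the global template network
#'
#' Reads a STRING-style edge list (`protein1 protein2 [combined_score]`,
#' whitespace-, tab- or comma-delimited, optional header, gzip-transparent),
#' keeps edges whose confidence score is at least `threshold`, drops
#' self-loops, deduplicates edges order-insensitively and removes isolated
#' nodes. STRING distributes `combined_score` on a 0-1000 integer scale;
#' `score_scale = "string-1000"` divides scores by 1000 so that a confidence
#' level of 0.800 corresponds to a stored score of 800.
#'
#' @param path path to the edge-list file (plain or gzipped).
#' @param score_column name of the score column when the file has a header,
#'   or `NULL` to use the third column when present.
#' @param threshold minimum confidence on the unit scale in `[0, 1]`; edges
#'   below it are discarded. Files without a score column admit every edge.
#' @param score_scale `"unit"` if scores are already in `[0, 1]`,
#'   `"string-1000"` for the STRING 0-1000 integer scale.
#' @return a [gene_network].
#' @examples
#' f <- tempfile()
#' writeLines(c("A B 0.9", "B C 0.5", "D D 0.99"), f)
#' net <- load_edge_list(f, threshold = 0.8)
#' net$nodes   # "A" "B"
#' @export
load_edge_list <- function(path, score_column = NULL, threshold = 0,
                           score_scale = c("unit", "string-1000")) {
  score_scale <- match.arg(score_scale)
  if (!file.exists(path)) stop("edge list file not found: ", path)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1] on the unit scale, got: ", threshold)

  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(lines_keep) == 0) stop("edge list is empty: ", path)

  split_row <- function(x) strsplit(trimws(x), "[,\t ]+")[[1]]
  first <- split_row(lines[lines_keep[1]])
  has_header <- length(first) >= 2 && is.na(suppressWarnings(as.numeric(first[min(3, length(first))]))) &&
    (!is.null(score_column) || grepl("protein|gene|node|score", paste(first, collapse = " "),
                                     ignore.case = TRUE))
  score_idx <- 3L
  if (has_header) {
    if (!is.null(score_column)) {
      score_idx <- match(score_column, first)
      if (is.na(score_idx)) stop("score column '", score_column, "' not in header")
    }
    lines_keep <- lines_keep[-1]
  }

  n <- length(lines_keep)
  a <- character(n); b <- character(n); s <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ln <- lines_keep[i]
    f <- split_row(lines[ln])
    if (length(f) < 2)
      stop("malformed edge-list row at line ", ln, ": ", lines[ln])
    a[i] <- f[1]; b[i] <- f[2]
    if (length(f) >= score_idx) {
      v <- suppressWarnings(as.numeric(f[score_idx]))
      if (is.na(v))
        stop("malformed score at line ", ln, ": ", lines[ln])
      s[i] <- v
    }
  }
  if (score_scale == "string-1000") s <- s / 1000
  if (any(!is.na(s) & (s < 0 | s > 1)))
    stop("scores outside [0, 1] after rescaling; check score_scale")
  keep <- is.na(s) | s >= threshold
  if (!any(keep))
    stop("no edges pass the confidence threshold ", threshold)
  gene_network(cbind(a[keep], b[keep]), confidence_threshold = threshold)
}

#' Restrict a network to a gene set
#'
#' Induced subgraph on the intersection of the network's nodes and `genes`,
#' followed by re-pruning of nodes left isolated. Used to map an expression
#' matrix onto the global template network.
#'
#' @param net a [gene_network].
#' @param genes character vector of gene symbols to keep.
#' @return a [gene_network] on the retained genes.
#' @export
restrict_to_genes <- function(net, genes) {
  stopifnot(inherits(net, "gene_network"))
  if (length(genes) == 0) stop("'genes' must be nonempty")
  common <- intersect(net$nodes, genes)
  if (length(common) == 0)
    stop(sprintf("no overlap between %d network genes and %d query genes",
                 length(net$nodes), length(genes)))
  e <- net$edges
  keep <- e$from %in% common & e$to %in% common
  if (!any(keep))
    stop(sprintf(
      "restriction to %d genes leaves no edges (all %d shared genes isolated)",
      length(genes), length(common)))
  gene_network(as.matrix(e[keep, , drop = FALSE]),
               confidence_threshold = net$confidence_threshold)
}

#' First-order local neighborhood of a gene
#'
#' The local network of a center gene is the set of its first-order neighbors
#' in the template network. Neighbors are returned in lexicographic order so
#' the correlation-weight vector indexing is deterministic.
#'
#' @param net a [gene_network].
#' @param gene center gene symbol.
#' @return an object of class `local_neighborhood`: list with `center`,
#'   `neighbors` (sorted character vector) and `M` (neighbor count, equal to
#'   the center's degree).
#' @export
neighborhood <- function(net, gene) {
  stopifnot(inherits(net, "gene_network"))
  if (!gene %in% net$nodes) stop("gene not in network: ", gene)
  nb <- net$adj[[gene]]
  structure(list(center = gene, neighbors = nb, M = length(nb)),
            class = "local_neighborhood")
}

#' Export a network as SIF
#'
#' Writes `nodeA<TAB>pp<TAB>nodeB` lines readable by Cytoscape.
#'
#' @param net a [gene_network].
#' @param path output file path.
#' @param interaction interaction type label (default `"pp"`).
#' @return `path`, invisibly.
#' @export
export_sif <- function(net, path, interaction = "pp") {
  stopifnot(inherits(net, "gene_network"))
  writeLines(paste(net$edges$from, interaction, net$edges$to, sep = "\t"), path)
  invisible(path)
}

#' Export a network as GraphML with optional attributes
#'
#' @param net a [gene_network].
#' @param path output file path.
#' @param node_attr optional named numeric vector of per-node attributes
#'   (names are gene symbols); written as node attribute `score`.
#' @param edge_attr optional numeric vector, one value per edge row of
#'   `net$edges`; written as edge attribute `weight`.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path, node_attr = NULL, edge_attr = NULL) {
  stopifnot(inherits(net, "gene_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  if (!is.null(node_attr))
    igraph::V(g)$score <- unname(node_attr[net$nodes])
  if (!is.null(edge_attr))
    igraph::E(g)$weight <- edge_attr
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
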
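# Spearman co-expression networks and the multi-query intersection screen.
#
# "Guilt by association": genes whose expression profiles are rank-correlated
# across many cultivation conditions tend to share function. Edges connect
# gene pairs whose Spearman correlation exceeds a cutoff (0.5 by default, a
# stringent threshold for compendia of >150 conditions); the screen then
# intersects the neighbourhoods of several query genes to find candidates
# coupled to all of them.

#' Spearman rank correlation between two vectors
#'
#' Average (fractional) ranks are used for ties, the standard convention.
#' Constant vectors have undefined rank correlation and are rejected.
#'
#' @param x,y numeric vectors of equal length >= 2, neither constant.
#' @return Correlation in `[-1, 1]`; symmetric in its arguments and
#'   invariant under strictly monotone transforms of either.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
spearman_rho <- function(x, y) {
  check_that(is.numeric(x) && is.numeric(y), "inputs must be numeric")
  check_that(length(x) == length(y),
             "length mismatch: %d vs %d", length(x), length(y))
  check_that(length(x) >= 2L, "need at least 2 observations")
  check_that(!anyNA(x) && !anyNA(y), "missing values are not allowed")
  if (min(x) == max(x)) stop("`x` is constant; rank correlation undefined",
                             call. = FALSE)
  if (min(y) == max(y)) stop("`y` is constant; rank correlation undefined",
                             call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Build a Spearman co-expression network
#'
#' An edge joins genes `a` and `b` iff their Spearman correlation is
#' strictly greater than `cutoff` (the threshold is described as "above"
#' the cutoff, so ties at the cutoff are excluded; negative correlations
#' never form edges). With `query_restriction`, only pairs with at least one
#' member in the restriction are evaluated -- screen mode, which avoids the
#' all-pairs cost when only query neighbourhoods are consumed. The edge set
#' restricted to query-incident pairs is identical in both modes.
#'
#' @param matrix numeric expression matrix, genes x conditions, with unique
#'   rownames/colnames, >= 5 conditions, no missing values.
#' @param cutoff correlation threshold in `[0, 1)`.
#' @param query_restriction optional character vector of gene IDs.
#' @return A `coex_network`: list with `nodes`, `edges` (data.frame
#'   `gene_a`, `gene_b`, `rho`; each unordered pair once, `gene_a` <
#'   `gene_b`), `cutoff`, and `queries` (`NULL` for a full network).
#' @export
build_network <- function(matrix, cutoff = 0.5, query_restriction = NULL) {
  validate_expression_matrix(matrix)
  check_that(is_scalar_number(cutoff) && cutoff >= 0 && cutoff < 1,
             "`cutoff` must lie in [0, 1)")
  genes <- rownames(matrix)
  constant <- apply(matrix, 1L, function(r) min(r) == max(r))
  if (any(constant)) {
    stop("constant expression profiles (rank correlation undefined): ",
         paste(genes[constant], collapse = ", "), call. = FALSE)
  }

  if (is.null(query_restriction)) {
    rho <- stats::cor(t(matrix), method = "spearman")
    hit <- which(upper.tri(rho) & rho > cutoff, arr.ind = TRUE)
    edges <- data.frame(gene_a = genes[hit[, 1]], gene_b = genes[hit[, 2]],
                        rho = rho[hit], stringsAsFactors = FALSE)
  } else {
    missing <- setdiff(query_restriction, genes)
    check_that(length(missing) == 0L, "query genes not in matrix: %s",
               paste(missing, collapse = ", "))
    rho <- stats::cor(t(matrix[query_restriction, , drop = FALSE]),
                      t(matrix), method = "spearman")
    hit <- which(rho > cutoff, arr.ind = TRUE)
    a <- query_restriction[hit[, 1]]
    b <- genes[hit[, 2]]
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    lo <- pmin(a, b); hi <- pmax(a, b)
    edges <- data.frame(gene_a = lo, gene_b = hi,
                        rho = rho[hit][keep], stringsAsFactors = FALSE)
    edges <- edges[!duplicated(edges[c("gene_a", "gene_b")]), , drop = FALSE]
  }
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = genes, edges = edges, cutoff = cutoff,
                 queries = query_restriction),
            class = "coex_network")
}

#' @export
print.coex_network <- function(x, ...) {
  mode <- if (is.null(x$queries)) "full" else
    sprintf("screen (%d queries)", length(x$queries))
  cat(sprintf("Co-expression network (%s): %d genes, %d edges above rho = %g\n",
              mode, length(x$nodes), nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Neighbour set of a gene in a co-expression network
#'
#' @param network a `coex_network` from [build_network()].
#' @param query a gene ID present in the network (and, for a screen-mode
#'   network, among its evaluated queries -- other neighbourhoods are
#'   incomplete by construction).
#' @return Character vector of neighbouring gene IDs, excluding `query`.
#' @export
query_subnetwork <- function(network, query) {
  check_that(inherits(network, "coex_network"), "`network` must be a coex_network")
  check_that(is.character(query) && length(query) == 1L,
             "`query` must be a single gene ID")
  if (!query %in% network$nodes) {
    stop("gene not in network: ", query, call. = FALSE)
  }
  if (!is.null(network$queries) && !query %in% network$queries) {
    stop("gene ", query, " was not among the evaluated queries; ",
         "its neighbourhood is incomplete in screen mode", call. = FALSE)
  }
  e <- network$edges
  sort(unique(c(e$gene_b[e$gene_a == query], e$gene_a[e$gene_b == query])))
}

#' Multi-query subnetwork intersection screen
#'
#' Computes each query's co-expression neighbourhood and intersects them:
#' the result is the set of genes co-expressed with every query, the query
#' genes themselves excluded. Adding queries can only shrink the
#' intersection.
#'
#' @param network a `coex_network`.
#' @param queries character vector of >= 1 gene IDs in the network.
#' @return A `screen_result`: list with `query_genes`,
#'   `per_query_neighbors` (named list), `intersection` (character) and
#'   `intersection_size`.
#' @export
intersect_subnetworks <- function(network, queries) {
  check_that(is.character(queries) && length(queries) >= 1L,
             "at least one query gene is required")
  neighbors <- lapply(queries, function(q) query_subnetwork(network, q))
  names(neighbors) <- queries
  inter <- Reduce(intersect, neighbors)
  inter <- sort(setdiff(inter, queries))
  structure(list(query_genes = queries, per_query_neighbors = neighbors,
                 intersection = inter, intersection_size = length(inter)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Screen over %d queries: %d genes co-expressed with all queries\n",
              length(x$query_genes), x$intersection_size))
  invisible(x)
}

#' Convert a co-expression network to an igraph object
#'
#' Nodes are all genes (including isolated ones); edge attribute `rho`
#' carries the correlation.
#'
#' @param network a `coex_network`.
#' @return An [igraph::graph][igraph] object.
#' @export
as_igraph <- function(network) {
  check_that(inherits(network, "coex_network"), "`network` must be a coex_network")
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = data.frame(name = network$nodes))
}

#' Export a network as edge-list TSV and GraphML
#'
#' @param network a `coex_network`.
#' @param tsv_path,graphml_path output paths; either may be `NULL` to skip.
#' @return Invisibly, the network.
#' @export
write_network <- function(network, tsv_path = NULL, graphml_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(network$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(network), graphml_path, format = "graphml")
  }
  invisible(network)
}

#' Tabulate a screen result per gene
#'
#' @param result a `screen_result`.
#' @return data.frame with columns `gene`, `n_queries_supporting` and
#'   `member_of_intersection`, sorted by support then gene.
#' @export
screen_result_table <- function(result) {
  check_that(inherits(result, "screen_result"), "`result` must be a screen_result")
  support <- table(unlist(result$per_query_neighbors))
  genes <- setdiff(names(support), result$query_genes)
  df <- data.frame(gene = genes,
                   n_queries_supporting = as.integer(support[genes]),
                   stringsAsFactors = FALSE)
  df$member_of_intersection <- df$gene %in% result$intersection
  df <- df[order(-df$n_queries_supporting, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}
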
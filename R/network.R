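#' Load a directed gene-gene edge list
#'
#' Reads (or accepts) a table with `source` and `target` columns and an
#' optional `effect` column (activation/inhibition/unspecified) and
#' optional `category` column. Self-loops are dropped and duplicate
#' directed pairs collapsed (keeping the first effect), with counts
#' reported via messages. Node attributes such as the methylation direction
#' of the gene's probes can be joined; genes carrying both hypo- and
#' hypermethylated probes are labeled `"mixed"`.
#'
#' @param edges file path of a TSV edge list, or a data.frame.
#' @param node_attributes optional data.frame with columns `gene` and
#'   `direction` (possibly several rows per gene).
#' @param categories optional character vector; when the table has a
#'   `category` column, only these categories are kept.
#' @return object of class `directed_network`: `edges` (data.frame),
#'   `nodes` (data.frame with name and direction), and the igraph `graph`.
#' @export
load_edge_list <- function(edges, node_attributes = NULL, categories = NULL) {
  if (is.character(edges)) {
    df <- read.delim(edges, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(edges, stringsAsFactors = FALSE)
  }
  if (!all(c("source", "target") %in% names(df)))
    stop("edge list needs 'source' and 'target' columns")
  bad <- which(is.na(df$source) | is.na(df$target) |
                 !nzchar(df$source) | !nzchar(df$target))
  if (length(bad))
    stop("malformed edge rows (missing endpoint) at line(s): ",
         paste(head(bad + 1, 5), collapse = ", "))
  if (!is.null(categories) && "category" %in% names(df))
    df <- df[df$category %in% categories, , drop = FALSE]
  if (!"effect" %in% names(df)) df$effect <- "unspecified"

  loops <- df$source == df$target
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    df <- df[!loops, , drop = FALSE]
  }
  key <- paste(df$source, df$target, sep = "\r")
  if (anyDuplicated(key)) {
    message(sum(duplicated(key)), " duplicate edge(s) collapsed")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no edges remain after filtering")
  df <- df[, c("source", "target", "effect")]
  rownames(df) <- NULL

  g <- igraph::graph_from_data_frame(df, directed = TRUE)
  nodes <- data.frame(name = igraph::V(g)$name, direction = NA_character_,
                      stringsAsFactors = FALSE)
  if (!is.null(node_attributes)) {
    if (!all(c("gene", "direction") %in% names(node_attributes)))
      stop("node_attributes needs 'gene' and 'direction' columns")
    dirs <- tapply(node_attributes$direction, node_attributes$gene,
                   function(d) if (length(unique(d)) > 1) "mixed" else d[1])
    nodes$direction <- as.character(dirs[nodes$name])
  }
  structure(list(edges = df, nodes = nodes, graph = g),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("directed_network: %d genes, %d directed interactions\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Strongly connected components
#'
#' Partition of the nodes into maximal sets with mutual directed
#' reachability.
#'
#' @param net a [load_edge_list()] network.
#' @return named integer vector: component membership per node.
#' @export
strongly_connected_components <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  igraph::components(net$graph, mode = "strong")$membership
}

#' Extract the nontrivial strongly connected component
#'
#' Returns the induced subnetwork of the unique SCC with at least two
#' nodes. If several nontrivial components exist, the largest is returned
#' with a warning (ties broken by the lexicographically smallest member);
#' with none, `NULL` is returned with a message.
#'
#' @param net a [load_edge_list()] network.
#' @return a `directed_network` of the component, or `NULL`.
#' @export
extract_scc <- function(net) {
  memb <- strongly_connected_components(net)
  sizes <- table(memb)
  nontrivial <- names(sizes)[sizes >= 2]
  if (length(nontrivial) == 0) {
    message("no nontrivial strongly connected component")
    return(NULL)
  }
  if (length(nontrivial) > 1) {
    warning(length(nontrivial), " nontrivial components found; ",
            "returning the largest")
    best_size <- max(sizes[nontrivial])
    cands <- nontrivial[sizes[nontrivial] == best_size]
    smallest_member <- vapply(cands, function(cmp)
      min(names(memb)[memb == as.integer(cmp)]), "")
    pick <- cands[order(smallest_member)[1]]
  } else pick <- nontrivial
  keep <- names(memb)[memb == as.integer(pick)]
  sub <- net$edges[net$edges$source %in% keep & net$edges$target %in% keep, ,
                   drop = FALSE]
  out <- load_edge_list(sub)
  out$nodes$direction <- net$nodes$direction[match(out$nodes$name,
                                                  net$nodes$name)]
  out
}

#' Node-level topology metrics
#'
#' NetworkAnalyzer-style metrics: in- and out-degree by directed edge
#' counting; betweenness centrality on the directed graph (Brandes),
#' normalized by `(N-1)(N-2)`; clustering coefficient and neighborhood
#' connectivity on the undirected projection (`CC(v) = 2 e(N(v)) /
#' (k_v (k_v - 1))`, zero when `k_v < 2`; neighborhood connectivity is the
#' mean undirected degree of the neighbors).
#'
#' @param net a [load_edge_list()] network.
#' @return data.frame with gene, in_degree, out_degree, betweenness,
#'   clustering_coefficient, neighborhood_connectivity.
#' @export
topology_metrics <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  g <- net$graph
  nn <- igraph::vcount(g)
  btw <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  if (nn > 2) btw <- btw / ((nn - 1) * (nn - 2))
  gu <- igraph::as_undirected(g, mode = "collapse")
  cc <- igraph::transitivity(gu, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  deg_u <- igraph::degree(gu)
  adj <- igraph::as_adjacency_matrix(gu, sparse = FALSE) > 0
  nc <- vapply(seq_len(nn), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) == 0) 0 else mean(deg_u[nb])
  }, 0)
  data.frame(gene = igraph::V(g)$name,
             in_degree = igraph::degree(g, mode = "in"),
             out_degree = igraph::degree(g, mode = "out"),
             betweenness = unname(btw),
             clustering_coefficient = cc,
             neighborhood_connectivity = nc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank hub genes
#'
#' Orders genes by total degree (in + out), breaking ties by betweenness
#' and then lexicographically, so the ranking is deterministic.
#'
#' @param metrics a [topology_metrics()] data.frame.
#' @return the same data.frame, ordered, with a `rank` column.
#' @export
rank_hub_genes <- function(metrics) {
  total <- metrics$in_degree + metrics$out_degree
  out <- metrics[order(-total, -metrics$betweenness, metrics$gene), ,
                 drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
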
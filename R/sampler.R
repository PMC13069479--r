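#' Collect the hop-expanded neighbourhood of an anchor gene
#'
#' Breadth-first expansion over the co-expression network: direct neighbours
#' first (hop 1), then neighbours-of-neighbours, stopping at the first hop
#' where the cumulative neighbour count reaches `target`, or when the
#' anchor's connected component is exhausted.
#'
#' @param net a `coexpression_network`.
#' @param anchor gene identifier present in the network.
#' @param target required neighbour count (99 under the default 100-node
#'   subgraph capacity).
#' @param adj optional precomputed adjacency list (from repeated calls).
#' @return list with `neighbors` (anchor excluded, in collection order:
#'   by hop, then by edge insertion order), `hop_reached`, and `exhausted`
#'   (`TRUE` when the component ran out before `target` was met).
#' @export
collect_neighborhood <- function(net, anchor, target = 99L, adj = NULL) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!anchor %in% net$gene_ids) stop("anchor gene not in network: ", anchor)
  if (is.null(adj)) adj <- gcen_adjacency(net)
  seen <- c(anchor)
  collected <- character()
  frontier <- anchor
  hop <- 0L
  while (length(collected) < target) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!nxt %in% seen]
    if (!length(nxt)) break # component exhausted
    hop <- hop + 1L
    seen <- c(seen, nxt)
    collected <- c(collected, nxt)
    frontier <- nxt
  }
  list(neighbors = collected, hop_reached = hop,
       exhausted = length(collected) < target)
}

# induced subgraph object: anchor first, neighbours in sorted-id order
make_subgraph <- function(net, anchor, neighbors, hop_reached, mode) {
  node_ids <- c(anchor, sort(setdiff(neighbors, anchor)))
  in_set <- net$edges$a %in% node_ids & net$edges$b %in% node_ids
  edges <- net$edges[in_set, , drop = FALSE]
  rownames(edges) <- NULL
  sg <- list(anchor = anchor, node_ids = node_ids, edges = edges,
             is_tf = stats::setNames(
               net$is_tf[match(node_ids, net$gene_ids)], node_ids),
             hop_reached = hop_reached, mode = mode)
  class(sg) <- "tf_subgraph"
  sg
}

#' @export
print.tf_subgraph <- function(x, ...) {
  cat(sprintf("tf_subgraph: anchor %s, %d nodes, %d edges (hop %d, %s)\n",
              x$anchor, length(x$node_ids), nrow(x$edges), x$hop_reached,
              x$mode))
  invisible(x)
}

#' Sample one fixed-capacity training subgraph for a TF
#'
#' Expands the anchor's neighbourhood until at least `size - 1` neighbours
#' are collected, then takes a single uniform random draw of `size - 1`
#' neighbours from the collected set if it is larger. When the anchor's
#' component holds fewer genes, the whole component is used (smaller
#' subgraphs are emitted rather than discarded). Isolated anchors return
#' `NULL` with a message.
#'
#' @param net a `coexpression_network`.
#' @param anchor TF gene id.
#' @param size subgraph capacity (anchor included), default 100.
#' @param adj optional precomputed adjacency list.
#' @return a `tf_subgraph` with at most `size` nodes, or `NULL`.
#' @export
sample_training_subgraph <- function(net, anchor, size = 100L, adj = NULL) {
  nb <- collect_neighborhood(net, anchor, target = size - 1L, adj = adj)
  if (!length(nb$neighbors)) {
    message("anchor ", anchor, " is isolated in the GCEN; subgraph skipped")
    return(NULL)
  }
  chosen <- nb$neighbors
  if (length(chosen) > size - 1L)
    chosen <- sample(chosen, size - 1L)
  make_subgraph(net, anchor, chosen, nb$hop_reached, mode = "train")
}

#' Enumerate deterministic inference subgraphs covering all TF neighbours
#'
#' At inference every collected neighbour of every TF must be scored, so the
#' neighbourhood is traversed exhaustively and deterministically: neighbours
#' are taken in collection order and cut into consecutive chunks of at most
#' `size - 1`, each chunk prepended with the anchor TF. Genes recurring
#' across subgraphs are intentional (context-specific instances).
#'
#' @param net a `coexpression_network`.
#' @param tfs character vector of TF gene ids (ids absent from the network
#'   are skipped with a message).
#' @param size per-subgraph capacity, default 100.
#' @param target neighbourhood expansion target; defaults to `size - 1`.
#' @return list of `tf_subgraph` objects (possibly several per TF).
#' @export
enumerate_inference_subgraphs <- function(net, tfs, size = 100L,
                                          target = NULL) {
  if (is.null(target)) target <- size - 1L
  adj <- gcen_adjacency(net)
  out <- list()
  for (tf in tfs) {
    if (!tf %in% net$gene_ids) {
      message("TF ", tf, " not in network; skipped")
      next
    }
    nb <- collect_neighborhood(net, tf, target = target, adj = adj)
    if (!length(nb$neighbors)) next
    chunks <- split(nb$neighbors,
                    ceiling(seq_along(nb$neighbors) / (size - 1L)))
    for (ch in chunks)
      out[[length(out) + 1L]] <-
        make_subgraph(net, tf, ch, nb$hop_reached, mode = "infer")
  }
  out
}
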
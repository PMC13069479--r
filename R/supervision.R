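#' Construct a ground-truth regulatory network
#'
#' Merges one or more directed (regulator, target) edge sources by union.
#' Self-loops and duplicate ordered pairs are removed; when a TF list is
#' supplied, edges whose regulator is not a TF are rejected.
#'
#' @param ... data.frames with `regulator` and `target` columns (e.g. from
#'   [read_edge_list()]); a `source` tag column is added per input when
#'   absent.
#' @param tf_ids optional character vector restricting allowed regulators.
#' @return a `ground_truth_network`: data.frame of unique directed edges
#'   with columns `regulator`, `target`, `source`.
#' @export
ground_truth_network <- function(..., tf_ids = NULL) {
  srcs <- list(...)
  if (!length(srcs)) stop("at least one edge source is required")
  pieces <- lapply(seq_along(srcs), function(i) {
    df <- srcs[[i]]
    stopifnot(all(c("regulator", "target") %in% names(df)))
    data.frame(regulator = as.character(df$regulator),
               target = as.character(df$target),
               source = if ("source" %in% names(df))
                 as.character(df$source) else paste0("source", i),
               stringsAsFactors = FALSE)
  })
  gt <- do.call(rbind, pieces)
  gt <- gt[gt$regulator != gt$target, , drop = FALSE]
  gt <- gt[!duplicated(gt[c("regulator", "target")]), , drop = FALSE]
  if (!is.null(tf_ids)) {
    bad <- setdiff(unique(gt$regulator), tf_ids)
    if (length(bad))
      stop("regulators not in the TF list: ", paste(bad, collapse = ", "))
  }
  rownames(gt) <- NULL
  class(gt) <- c("ground_truth_network", "data.frame")
  gt
}

gt_keys <- function(gt) paste(gt$regulator, gt$target, sep = "|")

#' Label a subgraph with ground-truth regulatory edges
#'
#' Positives are the directed ground-truth edges whose both endpoints lie in
#' the subgraph. Subgraphs containing no positive are uninformative for
#' training and are discarded (returns `NULL` with a message).
#'
#' @param sg a `tf_subgraph`.
#' @param gt a [ground_truth_network()].
#' @return a `labeled_subgraph` (list with `subgraph`, `positives`,
#'   `negatives` initialised empty, `feature_block = NULL`), or `NULL`.
#' @export
label_subgraph <- function(sg, gt) {
  stopifnot(inherits(sg, "tf_subgraph"))
  keep <- gt$regulator %in% sg$node_ids & gt$target %in% sg$node_ids
  pos <- gt[keep, c("regulator", "target"), drop = FALSE]
  rownames(pos) <- NULL
  if (!nrow(pos)) {
    message("subgraph anchored at ", sg$anchor,
            " has no ground-truth edges; discarded")
    return(NULL)
  }
  ls <- list(subgraph = sg, positives = pos,
             negatives = pos[0, , drop = FALSE], feature_block = NULL)
  class(ls) <- "labeled_subgraph"
  ls
}

#' Sample balanced negative pairs for a labeled subgraph
#'
#' Draws `|positives|` ordered node pairs uniformly without replacement from
#' the subgraph's non-ground-truth pairs (direction matters; the exclusion
#' uses the full ground-truth network, not just the subgraph's positives).
#' Intended to be called afresh each epoch (dynamic negative sampling).
#'
#' @param ls a `labeled_subgraph`.
#' @param gt the [ground_truth_network()] used for exclusion.
#' @return `ls` with its `negatives` replaced; if fewer candidates exist
#'   than positives, all are taken and the shortfall is messaged.
#' @export
sample_negatives <- function(ls, gt) {
  nodes <- ls$subgraph$node_ids
  n <- length(nodes)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  idx <- idx[idx$i != idx$j, , drop = FALSE]
  keys <- paste(nodes[idx$i], nodes[idx$j], sep = "|")
  cand <- which(!keys %in% gt_keys(gt))
  need <- nrow(ls$positives)
  if (length(cand) < need) {
    message("only ", length(cand), " candidate negatives for ", need,
            " positives in subgraph ", ls$subgraph$anchor)
    take <- cand
  } else {
    take <- sample(cand, need)
  }
  ls$negatives <- data.frame(regulator = nodes[idx$i[take]],
                             target = nodes[idx$j[take]],
                             stringsAsFactors = FALSE)
  ls
}

#' Assemble the model input features of a subgraph
#'
#' Each cell (column) is z-scored across the subgraph's genes only -- mean 0
#' and population standard deviation 1 within the column -- so recurring
#' genes become context-specific instances and gene identity cannot be
#' memorised. Columns that are constant across the subgraph's genes become
#' all zeros. A final 0/1 column carries the TF flag. Edge features are the
#' subgraph's signed global co-expression weights and travel on the
#' subgraph itself.
#'
#' @param sg a `tf_subgraph`.
#' @param expr the full [expression_matrix()]; every subgraph gene must be
#'   present.
#' @return numeric matrix, `length(sg$node_ids)` rows by `n_cells + 1`
#'   columns, rows named by gene.
#' @export
assemble_features <- function(sg, expr) {
  miss <- setdiff(sg$node_ids, expr$gene_ids)
  if (length(miss))
    stop("genes missing from expression matrix: ",
         paste(miss, collapse = ", "))
  m <- expr$values[sg$node_ids, , drop = FALSE]
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(m^2) - mu^2)
  sd_pop[sd_pop < 1e-12] <- Inf # constant column -> all zeros
  z <- sweep(sweep(m, 2L, mu, "-"), 2L, sd_pop, "/")
  fb <- cbind(z, tf_flag = as.numeric(sg$is_tf[sg$node_ids]))
  rownames(fb) <- sg$node_ids
  fb
}
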
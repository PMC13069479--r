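#' Predict per-subgraph edge probabilities with a trained model
#'
#' Enumerates deterministic high-coverage inference subgraphs for each TF,
#' runs the model in evaluation mode (latents at their means, so the pass
#' is deterministic), and emits every ordered pair whose predicted
#' probability exceeds the retention threshold.
#'
#' @param model a trained `grn_model`.
#' @param net the `coexpression_network` of the dataset.
#' @param tfs TF gene identifiers to anchor inference.
#' @param expr the [expression_matrix()].
#' @param retention_threshold minimum probability to keep a prediction;
#'   defaults to the model configuration.
#' @return data.frame of edge predictions: `source`, `target`, `prob`,
#'   `subgraph` (index), `tf_initiated` (source is a TF).
#' @export
predict_subgraphs <- function(model, net, tfs, expr,
                              retention_threshold = NULL) {
  stopifnot(inherits(model, "grn_model"))
  if (is.null(retention_threshold))
    retention_threshold <- model$cfg$retention_threshold
  sgs <- enumerate_inference_subgraphs(net, tfs, size = model$cfg$subgraph_size)
  out <- vector("list", length(sgs))
  for (k in seq_along(sgs)) {
    sg <- sgs[[k]]
    feats <- assemble_features(sg, expr)
    arr <- subgraph_arrays(sg)
    fw <- model_forward(model, feats, arr, training = FALSE)
    p <- fw$prob_masked
    keep <- which(!is.na(p) & p > retention_threshold, arr.ind = TRUE)
    if (!nrow(keep)) next
    out[[k]] <- data.frame(
      source = sg$node_ids[keep[, 1L]],
      target = sg$node_ids[keep[, 2L]],
      prob = p[keep],
      subgraph = k,
      tf_initiated = arr$is_tf[keep[, 1L]],
      stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(source = character(), target = character(),
                      prob = numeric(), subgraph = integer(),
                      tf_initiated = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Aggregate per-subgraph predictions into a global GRN
#'
#' Each contributing prediction is weighted by `tf_weight` when its source
#' is a TF (TF-initiated edges are prioritised); per edge, the weighted
#' probabilities are summed, divided by the number of contributing
#' subgraphs, and the resulting raw scores are min-max normalised to
#' `[0, 1]`. When all raw scores are equal (including a single edge) every
#' score maps to 1.
#'
#' @param predictions data.frame from [predict_subgraphs()].
#' @param tf_weight multiplier for TF-initiated contributions.
#' @param tf_only keep only TF-initiated edges (the regulatory core).
#' @return a `global_grn` data.frame: `source`, `target`, `score`,
#'   `n_subgraphs`, sorted by decreasing score.
#' @export
aggregate_predictions <- function(predictions, tf_weight = 2,
                                  tf_only = TRUE) {
  empty <- data.frame(source = character(), target = character(),
                      score = numeric(), n_subgraphs = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("global_grn", "data.frame")
  if (!nrow(predictions)) return(empty)
  if (tf_only) predictions <- predictions[predictions$tf_initiated, ,
                                          drop = FALSE]
  if (!nrow(predictions)) return(empty)
  w <- ifelse(predictions$tf_initiated, tf_weight, 1)
  key <- paste(predictions$source, predictions$target, sep = "|")
  contrib <- predictions$prob * w
  sums <- tapply(contrib, key, sum)
  counts <- tapply(contrib, key, length)
  raw <- as.numeric(sums) / as.numeric(counts)
  keys <- names(sums)
  rng <- range(raw)
  score <- if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1])
           else rep(1, length(raw))
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(
    source = vapply(parts, `[`, character(1), 1L),
    target = vapply(parts, `[`, character(1), 2L),
    score = score,
    n_subgraphs = as.integer(counts),
    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("global_grn", "data.frame")
  out
}

#' End-to-end network inference from expression data
#'
#' Builds the co-expression network, predicts per-subgraph edge
#' probabilities with the trained model, and aggregates them into a
#' ranked global network.
#'
#' @param model a trained `grn_model`.
#' @param expr an [expression_matrix()] with TF flags set (or supply
#'   `tfs`).
#' @param tfs TF identifiers; defaults to the flagged genes of `expr`.
#' @param net optional prebuilt `coexpression_network`.
#' @param tf_only restrict output to TF-initiated edges.
#' @return a `global_grn` data.frame.
#' @export
infer_grn <- function(model, expr, tfs = NULL, net = NULL, tf_only = TRUE) {
  if (is.null(tfs)) tfs <- expr$gene_ids[expr$is_tf]
  if (!length(tfs)) stop("no TFs supplied or flagged")
  if (is.null(net)) net <- build_gcen(expr, model$cfg$gcen_threshold)
  preds <- predict_subgraphs(model, net, tfs, expr)
  aggregate_predictions(preds, tf_weight = model$cfg$tf_weight,
                        tf_only = tf_only)
}

#' Write a global GRN as a ranked TSV edge list
#'
#' @param grn a `global_grn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grn <- function(grn, path) {
  utils::write.table(grn, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
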
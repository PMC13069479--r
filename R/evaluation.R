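# Evaluation: clean negative pools, bootstrapped sampled metrics,
# full-matrix ranking metrics, and early precision.

edge_keys <- function(x) {
  if (is.character(x)) return(x)
  paste(x[[1L]], x[[2L]], sep = "|")
}

#' Area under the ROC curve (midrank convention)
#'
#' Equivalent to the normalised Mann-Whitney U statistic with ties
#' counted at half weight, so constant scores give 0.5.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative labels")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the precision at each recalled positive,
#' averaged over positives, with tied scores processed in a group (all
#' ties receive the precision of the full tied block).
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  if (!sum(labels == 1)) stop("need at least one positive")
  o <- order(-scores)
  s <- scores[o]; y <- labels[o]
  groups <- cumsum(!duplicated(s))
  tp_cum <- cumsum(y)
  n_cum <- seq_along(y)
  last <- !duplicated(groups, fromLast = TRUE)
  tp_g <- tp_cum[last]
  n_g <- n_cum[last]
  prec <- tp_g / n_g
  dtp <- diff(c(0, tp_g))
  sum(prec * dtp) / sum(labels == 1)
}

#' Build the clean negative evaluation pool
#'
#' All ordered non-self gene pairs minus every positive from any split and
#' every train/validation negative, so no evaluation negative was seen in
#' any role during training.
#'
#' @param genes gene identifier universe.
#' @param positives positives from all splits: a two-column data.frame or
#'   a character vector of `"regulator|target"` keys.
#' @param negatives train/validation negatives, same formats.
#' @return character vector of pool keys (`"a|b"`).
#' @export
build_clean_pool <- function(genes, positives, negatives = character()) {
  genes <- unique(as.character(genes))
  n <- length(genes)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  idx <- idx[idx$i != idx$j, , drop = FALSE]
  pool <- paste(genes[idx$i], genes[idx$j], sep = "|")
  pool <- setdiff(pool, c(edge_keys(positives), edge_keys(negatives)))
  if (!length(pool)) stop("clean negative pool is empty")
  pool
}

score_lookup <- function(scores, keys) {
  if (is.data.frame(scores)) {
    sc <- scores$score
    if (is.null(sc)) sc <- scores$prob
    scores <- stats::setNames(sc, paste(scores$source, scores$target,
                                        sep = "|"))
  }
  out <- scores[keys]
  out[is.na(out)] <- 0 # unscored pairs: the model abstained
  as.numeric(out)
}

threshold_metrics <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1,
    accuracy = (tp + tn) / length(labels))
}

#' Bootstrapped sampled evaluation metrics
#'
#' Pairs the test positives with an equal number of negatives drawn
#' uniformly from the clean pool, computes AUROC/AUPRC and thresholded
#' precision/recall/F1/accuracy on the union, and repeats over bootstrap
#' iterations; summary statistics average across iterations.
#'
#' @param scores predictions: a `global_grn`-style data.frame or a named
#'   numeric vector keyed `"source|target"`. Pairs without a score count
#'   as 0.
#' @param test_positives test-set positive edges (data.frame or keys).
#' @param pool clean negative pool from [build_clean_pool()].
#' @param iterations bootstrap iterations (default 100).
#' @param seed integer seed; fixed seeds reproduce the report exactly.
#' @param threshold operating threshold for the classification metrics.
#' @return a `metric_report`: list with `summary` (mean and sd per
#'   metric), `iterations` (per-iteration data.frame), `n_positives`.
#' @export
sampled_metrics <- function(scores, test_positives, pool,
                            iterations = 100L, seed = 1L,
                            threshold = 0.5) {
  pos_keys <- edge_keys(test_positives)
  if (!length(pos_keys)) stop("no test positives")
  if (length(pool) < length(pos_keys))
    stop("clean pool smaller than the positive set")
  pos_scores <- score_lookup(scores, pos_keys)
  set.seed(seed)
  rows <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    neg_keys <- sample(pool, length(pos_keys))
    s <- c(pos_scores, score_lookup(scores, neg_keys))
    y <- c(rep(1, length(pos_keys)), rep(0, length(neg_keys)))
    tm <- threshold_metrics(s, y, threshold)
    rows[[it]] <- data.frame(iteration = it, auroc = auroc(s, y),
                             auprc = auprc(s, y), t(tm))
  }
  iter_df <- do.call(rbind, rows)
  mets <- setdiff(names(iter_df), "iteration")
  report <- list(
    summary = data.frame(metric = mets,
                         mean = vapply(iter_df[mets], mean, numeric(1)),
                         sd = vapply(iter_df[mets], stats::sd, numeric(1)),
                         row.names = NULL),
    iterations = iter_df,
    n_positives = length(pos_keys))
  class(report) <- "metric_report"
  report
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("metric_report: %d positives, %d iterations\n",
              x$n_positives, nrow(x$iterations)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Full-matrix ranking metrics over the entire clean pool
#'
#' @inheritParams sampled_metrics
#' @return list with `auroc` and `auprc`.
#' @export
full_matrix_metrics <- function(scores, test_positives, pool) {
  pos_keys <- edge_keys(test_positives)
  if (!length(pos_keys)) stop("no test positives")
  s <- c(score_lookup(scores, pos_keys), score_lookup(scores, pool))
  y <- c(rep(1, length(pos_keys)), rep(0, length(pool)))
  list(auroc = auroc(s, y), auprc = auprc(s, y))
}

#' Early precision and the early precision ratio
#'
#' `EP@k` is the fraction of the top-`k` ranked pairs that are
#' ground-truth edges; `EPR` divides `EP@k` at `k = `number of
#' ground-truth edges by the ground-truth density of the evaluated pair
#' space, so a random ranking has expected EPR 1.
#'
#' @param scores data.frame (`source`, `target`, `score`) or named
#'   vector covering the evaluated pair space.
#' @param ground_truth ground-truth edges (data.frame or keys).
#' @param cutoffs integer vector of `k` values; each must not exceed the
#'   number of scored pairs.
#' @return list with `ep` (named by cutoff), `epr`, `k_gt`,
#'   `density`.
#' @export
early_precision <- function(scores, ground_truth, cutoffs = NULL) {
  if (is.data.frame(scores)) {
    keys <- paste(scores$source, scores$target, sep = "|")
    sc <- scores$score
    if (is.null(sc)) sc <- scores$prob
  } else {
    keys <- names(scores)
    sc <- as.numeric(scores)
  }
  gt_k <- edge_keys(ground_truth)
  n_gt_scored <- sum(keys %in% gt_k)
  k_gt <- min(length(gt_k), length(keys))
  if (is.null(cutoffs)) cutoffs <- k_gt
  if (any(cutoffs > length(keys)))
    stop("cutoff exceeds the number of scored pairs")
  ord <- order(-sc)
  hits <- keys[ord] %in% gt_k
  ep <- vapply(cutoffs, function(k) mean(hits[seq_len(k)]), numeric(1))
  names(ep) <- paste0("EP@", cutoffs)
  density <- n_gt_scored / length(keys)
  epr <- if (density > 0) mean(hits[seq_len(k_gt)]) / density else NA_real_
  list(ep = ep, epr = epr, k_gt = k_gt, density = density)
}
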
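#' Run the full synthetic benchmark end to end
#'
#' Simulates a dataset with known ground truth, splits the regulatory
#' edges by anchor TF, builds the co-expression network, trains the model
#' on the training TFs' subgraphs, infers a global network for the
#' held-out TFs, and evaluates it against the held-out edges on a clean
#' negative pool -- alongside an absolute-correlation ranking baseline
#' scored on exactly the same evaluation pairs.
#'
#' @param spec a [synthetic_spec()]; its `seed` drives data generation.
#' @param cfg a [run_config()]; its `seed` drives initialisation,
#'   sampling and training.
#' @param epochs training epoch cap (see [train_model()]).
#' @param verbose print training progress.
#' @return list with `model`, `history`, `grn`, `sampled`
#'   (metric_report), `full`, `ep`, `baseline_sampled`, `split`,
#'   `net`, `dataset`, and `pool_size`.
#' @export
run_benchmark <- function(spec = synthetic_spec(), cfg = run_config(),
                          epochs = 30L, verbose = FALSE) {
  ds <- simulate_dataset(spec)
  split <- make_benchmark_split(ds, holdout_tf_fraction = 0.2,
                                val_tf_fraction = 0.1, seed = spec$seed)
  net <- build_gcen(ds$expr, cfg$gcen_threshold)
  gt_trainval <- rbind(split$train, split$val)
  class(gt_trainval) <- c("ground_truth_network", "data.frame")
  set.seed(cfg$seed)
  train_ls <- prepare_subgraphs(net, ds$expr, gt_trainval,
                                split$train_tfs, cfg)
  val_ls <- prepare_subgraphs(net, ds$expr, gt_trainval, split$val_tfs, cfg)
  model <- grn_model_init(cfg)
  fit <- train_model(model, train_ls, val_ls, gt_trainval,
                     epochs = epochs, verbose = verbose)
  grn <- infer_grn(fit$model, ds$expr, tfs = split$test_tfs, net = net)
  pool <- build_clean_pool(ds$expr$gene_ids, positives = ds$grn,
                           negatives = fit$negatives_used)
  sampled <- sampled_metrics(grn, split$test, pool,
                             iterations = cfg$bootstrap_iterations,
                             seed = cfg$seed)
  full <- full_matrix_metrics(grn, split$test, pool)
  ep <- early_precision(grn, split$test)
  baseline <- correlation_baseline(ds$expr)
  baseline_sampled <- sampled_metrics(baseline, split$test, pool,
                                      iterations = cfg$bootstrap_iterations,
                                      seed = cfg$seed)
  list(model = fit$model, history = fit$history, grn = grn,
       sampled = sampled, full = full, ep = ep,
       baseline_sampled = baseline_sampled, split = split, net = net,
       dataset = ds, pool_size = length(pool))
}

#' Absolute-correlation ranking baseline
#'
#' Scores every ordered gene pair by the absolute Pearson correlation of
#' the arcsinh-transformed expression profiles -- the naive co-expression
#' ranking the model is expected to beat, since correlation is symmetric
#' and blind to regulator identity.
#'
#' @param expr an [expression_matrix()].
#' @return named numeric vector keyed `"source|target"` over all ordered
#'   non-self pairs.
#' @export
correlation_baseline <- function(expr) {
  cc <- abs(pearson_matrix(arcsinh_transform(expr$values)))
  n <- nrow(cc)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  idx <- idx[idx$i != idx$j, , drop = FALSE]
  stats::setNames(cc[cbind(idx$i, idx$j)],
                  paste(expr$gene_ids[idx$i], expr$gene_ids[idx$j],
                        sep = "|"))
}
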
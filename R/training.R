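# Training loop: dynamic negative resampling, mini-batched Adam with L1
# regularisation, plateau learning-rate decay and early stopping.

ls_pairs <- function(ls) {
  nodes <- ls$subgraph$node_ids
  data.frame(
    i = c(match(ls$positives$regulator, nodes),
          match(ls$negatives$regulator, nodes)),
    j = c(match(ls$positives$target, nodes),
          match(ls$negatives$target, nodes)),
    y = c(rep(1, nrow(ls$positives)), rep(0, nrow(ls$negatives))))
}

#' Prepare labeled training subgraphs for a set of anchor TFs
#'
#' Samples one fixed-capacity subgraph per TF, labels it with the supplied
#' ground-truth edges (subgraphs without any positive are discarded), and
#' precomputes feature blocks and index arrays. Stochastic neighbour
#' selection uses the current RNG state; seed beforehand for
#' reproducibility.
#'
#' @param net a `coexpression_network`.
#' @param expr the [expression_matrix()].
#' @param gt a [ground_truth_network()] providing labels.
#' @param tfs anchor TFs to sample.
#' @param cfg a [run_config()].
#' @return list of prepared `labeled_subgraph` objects.
#' @export
prepare_subgraphs <- function(net, expr, gt, tfs, cfg = run_config()) {
  adj <- gcen_adjacency(net)
  out <- list()
  for (tf in tfs) {
    if (!tf %in% net$gene_ids) next
    sg <- sample_training_subgraph(net, tf, cfg$subgraph_size, adj = adj)
    if (is.null(sg)) next
    ls <- label_subgraph(sg, gt)
    if (is.null(ls)) next
    ls$features <- assemble_features(sg, expr)
    ls$arr <- subgraph_arrays(sg)
    out[[length(out) + 1L]] <- ls
  }
  out
}

#' Train the model on labeled subgraphs
#'
#' Each epoch shuffles the subgraphs, redraws balanced negatives (dynamic
#' negative sampling), and takes one Adam step per mini-batch of
#' `cfg$batch_size` subgraphs on the summed loss (scaled by batch size),
#' with L1 regularisation on all parameters. The learning rate halves
#' after `cfg$lr_patience` epochs without validation improvement and
#' training stops early after `cfg$patience`; the best-validation
#' checkpoint is returned. Validation negatives are drawn once so the
#' early-stopping signal is stable.
#'
#' @param model a [grn_model_init()] model.
#' @param train_ls,val_ls prepared subgraphs from [prepare_subgraphs()];
#'   `val_ls` may be empty (training loss then drives the schedule).
#' @param gt ground-truth network used for negative exclusion.
#' @param epochs optional cap overriding `cfg$epochs`.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint), `history` data.frame
#'   (epoch, bce, kl, total, val_total, lr), `epochs_run`, and
#'   `negatives_used` (keys of every negative pair drawn, for clean-pool
#'   exclusion).
#' @export
train_model <- function(model, train_ls, val_ls = list(), gt,
                        epochs = NULL, verbose = FALSE) {
  cfg <- model$cfg
  if (!length(train_ls)) stop("no training subgraphs")
  if (is.null(epochs)) epochs <- cfg$epochs
  set.seed(cfg$seed)
  trainable <- list(transcoder = model$transcoder[transcoder_grad_names],
                    vae = model$vae)
  adam <- adam_init(trainable)
  lr <- cfg$learning_rate
  best_val <- Inf
  best_model <- model
  plateau <- 0L
  stall <- 0L
  neg_keys <- character()
  # fixed validation negatives for a stable early-stopping signal
  val_ls <- lapply(val_ls, function(ls) sample_negatives(ls, gt))
  neg_keys <- c(neg_keys, unlist(lapply(val_ls, function(ls)
    paste(ls$negatives$regulator, ls$negatives$target, sep = "|"))))
  history <- data.frame()
  for (ep in seq_len(epochs)) {
    ord <- sample(length(train_ls))
    ep_bce <- 0; ep_kl <- 0; ep_total <- 0
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (batch in batches) {
      g_acc <- NULL
      for (si in batch) {
        ls <- sample_negatives(train_ls[[si]], gt)
        neg_keys <- c(neg_keys, paste(ls$negatives$regulator,
                                      ls$negatives$target, sep = "|"))
        res <- model_loss_grads(model, ls$features, ls$arr, ls_pairs(ls),
                                training = TRUE)
        if (!is.finite(res$loss$total))
          stop("non-finite training loss at epoch ", ep,
               " (subgraph ", ls$subgraph$anchor, ")")
        model$bn_state <- res$bn_state
        g_acc <- if (is.null(g_acc)) res$grads else
          params_map2(g_acc, res$grads, `+`)
        ep_bce <- ep_bce + res$loss$bce
        ep_kl <- ep_kl + res$loss$kl
        ep_total <- ep_total + res$loss$total
      }
      nb <- length(batch)
      cur <- list(transcoder = model$transcoder[transcoder_grad_names],
                  vae = model$vae)
      g_acc <- params_map2(g_acc, cur, function(g, p)
        g / nb + cfg$l1_lambda * sign(p))
      stepped <- adam_step(cur, g_acc, adam, lr)
      adam <- stepped$state
      model$transcoder[transcoder_grad_names] <- stepped$params$transcoder
      model$vae <- stepped$params$vae
    }
    n_tr <- length(train_ls)
    val_total <- if (length(val_ls)) {
      mean(vapply(val_ls, function(ls)
        model_eval_loss(model, ls$features, ls$arr, ls_pairs(ls))$total,
        numeric(1)))
    } else ep_total / n_tr
    history <- rbind(history, data.frame(
      epoch = ep, bce = ep_bce / n_tr, kl = ep_kl / n_tr,
      total = ep_total / n_tr, val_total = val_total, lr = lr))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g",
                      ep, ep_total / n_tr, val_total, lr))
    if (val_total < best_val - 1e-9) {
      best_val <- val_total
      best_model <- model
      best_model$epoch <- ep
      plateau <- 0L
      stall <- 0L
    } else {
      plateau <- plateau + 1L
      stall <- stall + 1L
      if (plateau >= cfg$lr_patience) {
        lr <- lr * cfg$lr_factor
        plateau <- 0L
      }
      if (stall >= cfg$patience) break
    }
  }
  list(model = best_model, history = history, epochs_run = nrow(history),
       negatives_used = unique(neg_keys))
}
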
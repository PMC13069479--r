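#' Initialise a full regulatory-network model
#'
#' Combines the expression transcoder with the graph-transformer VAE under
#' one seeded parameter initialisation.
#'
#' @param cfg a [run_config()].
#' @return a `grn_model`: list with `cfg`, `transcoder` and `vae`
#'   parameter lists, and batch-norm `bn_state`.
#' @export
grn_model_init <- function(cfg = run_config()) {
  validate_run_config(cfg)
  set.seed(cfg$seed)
  tc <- transcoder_init(cfg$embed_dim, cfg$heads, cfg$leaky_slope)
  gv <- gvae_init(cfg)
  model <- list(cfg = cfg, transcoder = tc, vae = gv$params,
                bn_state = gv$bn_state)
  class(model) <- "grn_model"
  model
}

#' @export
print.grn_model <- function(x, ...) {
  n_par <- length(params_unlist(x$vae)) +
    length(params_unlist(x$transcoder[transcoder_grad_names]))
  cat(sprintf(
    "grn_model: embed %d, hidden %d, latent %d, %d+%d blocks, %d heads (%d parameters)\n",
    x$cfg$embed_dim, x$cfg$hidden_dim, x$cfg$latent_dim,
    x$cfg$encoder_blocks, x$cfg$decoder_blocks, x$cfg$heads, n_par))
  invisible(x)
}

#' Run the model forward on one subgraph
#'
#' @param model a `grn_model`.
#' @param features feature block from [assemble_features()].
#' @param arr subgraph arrays (internal) or a `tf_subgraph`.
#' @param training training mode: latents are sampled and batch-norm
#'   statistics update; in evaluation mode the pass is deterministic.
#' @return list with `prob` (nodes x nodes, `NA` diagonal), `logits`,
#'   latent distribution, embeddings, caches and the updated `bn_state`.
#' @export
model_forward <- function(model, features, arr, training = FALSE) {
  if (inherits(arr, "tf_subgraph")) arr <- subgraph_arrays(arr)
  emb <- embed_subgraph(features, model$transcoder)
  fw <- gvae_forward(emb, arr, model$vae, model$bn_state,
                         model$cfg$heads, model$cfg$leaky_slope, training)
  fw$emb <- emb
  fw$prob_masked <- fw$prob
  diag(fw$prob_masked) <- NA_real_
  fw
}

#' Encode a subgraph's embeddings to the latent distribution
#'
#' @param model a `grn_model`.
#' @param emb gene embeddings (nodes x embed_dim), e.g. from
#'   [embed_subgraph()].
#' @param arr subgraph arrays or a `tf_subgraph`.
#' @return list with `node_mu`, `node_log_var`, `edge_mu`,
#'   `edge_log_var`.
#' @export
encode <- function(model, emb, arr) {
  if (inherits(arr, "tf_subgraph")) arr <- subgraph_arrays(arr)
  enc <- encode_stage(emb, arr, model$vae, model$bn_state,
                      model$cfg$heads, model$cfg$leaky_slope,
                      training = FALSE)
  enc$latent
}

#' Decode sampled latents to node embeddings and edge attentions
#'
#' @param model a `grn_model`.
#' @param z latents from [reparameterize()] (list with `z_n`, `z_e`).
#' @param arr subgraph arrays or a `tf_subgraph`.
#' @return list with `Zp` (node embeddings) and `edge_att` (one scalar
#'   per directed edge).
#' @export
decode <- function(model, z, arr) {
  if (inherits(arr, "tf_subgraph")) arr <- subgraph_arrays(arr)
  dec <- decode_stage(z$z_n, z$z_e, arr, model$vae, model$bn_state,
                      model$cfg$heads, model$cfg$leaky_slope,
                      training = FALSE)
  list(Zp = dec$Zp, edge_att = dec$edge_att)
}

# loss + full parameter gradient for one labeled subgraph.
# pairs: data.frame(i, j, y) of node indices and labels.
model_loss_grads <- function(model, features, arr, pairs, training = TRUE) {
  if (any(!is.finite(features))) stop("non-finite feature values")
  fwc <- transcoder_forward_cached(features, model$transcoder)
  emb <- fwc$emb
  fw <- gvae_forward(emb, arr, model$vae, model$bn_state,
                         model$cfg$heads, model$cfg$leaky_slope, training)
  idx <- cbind(pairs$i, pairs$j)
  prob <- fw$prob[idx]
  bce <- bce_loss(prob, pairs$y)
  kl <- kl_divergence(fw$latent$node_mu, fw$latent$node_log_var) +
    kl_divergence(fw$latent$edge_mu, fw$latent$edge_log_var)
  lb <- total_loss(bce, kl, model$cfg$beta_mode, arr$n, model$cfg$beta_fixed)
  dM <- matrix(0, arr$n, arr$n)
  dM[idx] <- dM[idx] + (prob - pairs$y)
  gb <- gvae_backward(dM, fw, arr, model$vae, model$cfg$heads,
                          model$cfg$leaky_slope, lb$beta)
  tg <- transcoder_backward_cached(fwc$handle, features, gb$demb,
                                   model$transcoder)
  list(loss = lb, grads = list(transcoder = tg, vae = gb$grads),
       bn_state = fw$bn_state)
}

# evaluation-mode loss only (no gradient), for validation tracking
model_eval_loss <- function(model, features, arr, pairs) {
  fw <- model_forward(model, features, arr, training = FALSE)
  prob <- fw$prob[cbind(pairs$i, pairs$j)]
  bce <- bce_loss(prob, pairs$y)
  kl <- kl_divergence(fw$latent$node_mu, fw$latent$node_log_var) +
    kl_divergence(fw$latent$edge_mu, fw$latent$edge_log_var)
  total_loss(bce, kl, model$cfg$beta_mode, arr$n, model$cfg$beta_fixed)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds all parameters, batch-norm state, the
#' configuration that produced them, and the epoch counter.
#'
#' @param model a `grn_model` (optionally with `$epoch`).
#' @param path file path (RDS).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `grn_model`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "grn_model")) stop("not a model checkpoint: ", path)
  model
}
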
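#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the inference pipeline: the
#' co-expression threshold used to build the GCEN, the subgraph sampler
#' capacity, model dimensions, and training/evaluation settings. Defaults
#' correspond to the reference configuration (100-node subgraphs, 64-dim gene
#' embeddings, 16-dim latents, 4 attention heads, Adam at 1e-3, batch size 8,
#' 100 epochs, retention threshold 0.3, 100 bootstrap iterations).
#'
#' @param gcen_threshold absolute-correlation threshold for co-expression
#'   edges, in `[0, 1)`.
#' @param subgraph_size training subgraph capacity (anchor TF plus
#'   `subgraph_size - 1` neighbours).
#' @param embed_dim width of the per-gene expression embedding.
#' @param latent_dim width of the variational latent space.
#' @param heads attention heads; must divide `embed_dim` and `hidden_dim`.
#' @param hidden_dim hidden width of the graph transformer blocks.
#' @param encoder_blocks,decoder_blocks number of graph transformer blocks in
#'   the encoder / decoder stacks.
#' @param learning_rate initial Adam learning rate.
#' @param batch_size subgraphs per optimiser step.
#' @param epochs maximum training epochs.
#' @param beta_mode KL weight mode: `"per_gene"` uses `1 / n_genes` of each
#'   subgraph, `"fixed"` uses `beta_fixed`.
#' @param beta_fixed KL weight when `beta_mode = "fixed"`.
#' @param retention_threshold minimum predicted probability for an edge to be
#'   kept at inference.
#' @param bootstrap_iterations iterations of 1:1 negative resampling used by
#'   the sampled evaluation metrics.
#' @param l1_lambda L1 regularisation coefficient applied to all weights.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param lr_patience plateau length (epochs) before the learning rate is
#'   halved.
#' @param lr_factor multiplicative learning-rate decay on plateau.
#' @param leaky_slope negative slope of the leaky ReLU activations.
#' @param tf_weight aggregation multiplier for TF-initiated edges.
#' @param seed integer seed controlling sampling, initialisation and training.
#' @return an object of class `run_config` (a validated named list).
#' @export
run_config <- function(gcen_threshold = 0.1,
                       subgraph_size = 100L,
                       embed_dim = 64L,
                       latent_dim = 16L,
                       heads = 4L,
                       hidden_dim = 64L,
                       encoder_blocks = 3L,
                       decoder_blocks = 3L,
                       learning_rate = 0.001,
                       batch_size = 8L,
                       epochs = 100L,
                       beta_mode = c("per_gene", "fixed"),
                       beta_fixed = 0.01,
                       retention_threshold = 0.3,
                       bootstrap_iterations = 100L,
                       l1_lambda = 1e-5,
                       patience = 10L,
                       lr_patience = 5L,
                       lr_factor = 0.5,
                       leaky_slope = 0.01,
                       tf_weight = 2,
                       seed = 1L) {
  beta_mode <- match.arg(beta_mode)
  cfg <- list(
    gcen_threshold = as.numeric(gcen_threshold),
    subgraph_size = as.integer(subgraph_size),
    embed_dim = as.integer(embed_dim),
    latent_dim = as.integer(latent_dim),
    heads = as.integer(heads),
    hidden_dim = as.integer(hidden_dim),
    encoder_blocks = as.integer(encoder_blocks),
    decoder_blocks = as.integer(decoder_blocks),
    learning_rate = as.numeric(learning_rate),
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    beta_mode = beta_mode,
    beta_fixed = as.numeric(beta_fixed),
    retention_threshold = as.numeric(retention_threshold),
    bootstrap_iterations = as.integer(bootstrap_iterations),
    l1_lambda = as.numeric(l1_lambda),
    patience = as.integer(patience),
    lr_patience = as.integer(lr_patience),
    lr_factor = as.numeric(lr_factor),
    leaky_slope = as.numeric(leaky_slope),
    tf_weight = as.numeric(tf_weight),
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  with(cfg, {
    if (!(gcen_threshold >= 0 && gcen_threshold < 1))
      stop("gcen_threshold must lie in [0, 1)")
    if (!(retention_threshold >= 0 && retention_threshold <= 1))
      stop("retention_threshold must lie in [0, 1]")
    for (nm in c("subgraph_size", "embed_dim", "latent_dim", "heads",
                 "hidden_dim", "encoder_blocks", "decoder_blocks",
                 "batch_size", "epochs", "bootstrap_iterations")) {
      v <- cfg[[nm]]
      if (length(v) != 1L || is.na(v) || v < 1L)
        stop(sprintf("%s must be a positive integer", nm))
    }
    if (subgraph_size < 2L) stop("subgraph_size must be at least 2")
    if (embed_dim %% heads != 0L) stop("embed_dim must be divisible by heads")
    if (hidden_dim %% heads != 0L) stop("hidden_dim must be divisible by heads")
    if (learning_rate <= 0) stop("learning_rate must be positive")
    if (beta_fixed <= 0) stop("beta_fixed must be positive")
  })
  invisible(cfg)
}

#' Save / load a run configuration as YAML
#'
#' Round-trips exactly: `load_config(save_config(cfg, f))` equals `cfg`.
#'
#' @param cfg a [run_config()] object.
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` returns a
#'   `run_config`.
#' @export
save_config <- function(cfg, path) {
  validate_run_config(cfg)
  yaml::write_yaml(unclass(cfg), path, precision = 22L)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}
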
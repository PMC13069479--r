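#' Initialise expression-transcoder parameters
#'
#' The transcoder lifts each gene's scalar sequence (cells plus the TF-flag
#' position) to `embed_dim` channels with a kernel-1, stride-1 convolution,
#' applies one multi-head self-attention encoder layer over positions (no
#' positional encoding: cells are exchangeable observations), and
#' mean-pools over positions into one fixed-width embedding per gene.
#'
#' @param embed_dim embedding width (default 64).
#' @param heads attention heads (default 4); must divide `embed_dim`.
#' @param leaky_slope negative slope of the leaky ReLU.
#' @return named list of parameters consumed by [embed_subgraph()].
#' @export
transcoder_init <- function(embed_dim = 64L, heads = 4L, leaky_slope = 0.01) {
  if (embed_dim %% heads != 0L) stop("embed_dim must be divisible by heads")
  d <- embed_dim
  list(
    conv_w = stats::runif(d, -1, 1) / sqrt(d), conv_b = rep(0, d),
    Wq = glorot(d, d), bq = rep(0, d),
    Wk = glorot(d, d), bk = rep(0, d),
    Wv = glorot(d, d), bv = rep(0, d),
    Wo = glorot(d, d), bo = rep(0, d),
    ln1_g = rep(1, d), ln1_b = rep(0, d),
    ff_W1 = glorot(d, d), ff_b1 = rep(0, d),
    ff_W2 = glorot(d, d), ff_b2 = rep(0, d),
    ln2_g = rep(1, d), ln2_b = rep(0, d),
    heads = as.integer(heads), slope = leaky_slope
  )
}

transcoder_grad_names <- c("conv_w", "conv_b", "Wq", "bq", "Wk", "bk",
                           "Wv", "bv", "Wo", "bo", "ln1_g", "ln1_b",
                           "ff_W1", "ff_b1", "ff_W2", "ff_b2",
                           "ln2_g", "ln2_b")

#' Embed a subgraph's expression features into fixed-width gene vectors
#'
#' @param features feature block from [assemble_features()]: genes x
#'   (cells + 1) numeric matrix.
#' @param params transcoder parameters from [transcoder_init()].
#' @return genes x `embed_dim` embedding matrix; the output width is
#'   independent of the number of cells.
#' @export
embed_subgraph <- function(features, params) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("non-finite feature values")
  if (ncol(features) < 2L)
    stop("feature block needs at least one cell column plus the TF flag")
  emb <- .transcoder_forward_cpp(features, params)
  rownames(emb) <- rownames(features)
  emb
}

shape_transcoder_grads <- function(g, params) {
  out <- lapply(transcoder_grad_names, function(nm) {
    gi <- g[[nm]]
    if (is.matrix(params[[nm]])) matrix(gi, nrow(params[[nm]])) else as.numeric(gi)
  })
  names(out) <- transcoder_grad_names
  out
}

# gradient of all transcoder parameters given d(loss)/d(embeddings);
# recomputes activations gene by gene in C++
transcoder_backward <- function(features, demb, params) {
  shape_transcoder_grads(
    .transcoder_backward_cpp(as.matrix(features), demb, params), params)
}

# forward keeping activations cached in C++ for the matching backward
transcoder_forward_cached <- function(features, params) {
  .transcoder_forward_cached_cpp(as.matrix(features), params)
}

transcoder_backward_cached <- function(handle, features, demb, params) {
  shape_transcoder_grads(
    .transcoder_backward_cached_cpp(handle, as.matrix(features), demb,
                                    params), params)
}
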
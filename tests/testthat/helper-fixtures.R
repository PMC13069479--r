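# Shared fixtures: all data is generated in code at test time.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(embed_dim = 8L, hidden_dim = 8L, latent_dim = 4L, heads = 2L,
         encoder_blocks = 2L, decoder_blocks = 2L, subgraph_size = 6L,
         seed = 7L),
    list(...))
  do.call(run_config, args)
}

# hand-built subgraph with arbitrary node/edge structure
toy_subgraph <- function(n = 6L, edges = NULL, anchor_tf = TRUE) {
  ids <- paste0("g", seq_len(n))
  if (is.null(edges))
    edges <- data.frame(a = c("g1", "g1", "g2", "g4"),
                        b = c("g2", "g3", "g5", "g6"),
                        weight = c(0.5, -0.4, 0.3, 0.8),
                        stringsAsFactors = FALSE)
  sg <- list(anchor = "g1", node_ids = ids, edges = edges,
             is_tf = stats::setNames(c(anchor_tf, rep(FALSE, n - 1L)), ids),
             hop_reached = 1L, mode = "train")
  class(sg) <- "tf_subgraph"
  sg
}

toy_features <- function(sg, n_cells = 5L, seed = 11L) {
  set.seed(seed)
  f <- matrix(rnorm(length(sg$node_ids) * (n_cells + 1L)),
              length(sg$node_ids), n_cells + 1L)
  rownames(f) <- sg$node_ids
  f
}

# small random correlation-like symmetric matrix
random_symmetric <- function(n, seed = 1L) {
  set.seed(seed)
  m <- matrix(runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# random co-expression network over n genes with given edge probability
random_network <- function(n, p_edge = 0.2, seed = 1L, n_tfs = 2L) {
  set.seed(seed)
  ids <- paste0("g", seq_len(n))
  cc <- diag(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (runif(1) < p_edge) {
      w <- runif(1, 0.2, 0.9) * sample(c(-1, 1), 1)
      cc[i, j] <- w; cc[j, i] <- w
    }
  }
  dimnames(cc) <- list(ids, ids)
  build_network(cc, threshold = 0.1,
                is_tf = c(rep(TRUE, n_tfs), rep(FALSE, n - n_tfs)))
}

expect_same_edges <- function(a, b) {
  key <- function(df) sort(paste(df$a, df$b, df$weight))
  expect_identical(key(a), key(b))
}
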
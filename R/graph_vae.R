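# Edge-aware graph-transformer variational autoencoder.
#
# The encoder stacks graph transformer blocks whose pairwise attention
# logits incorporate edge features (signed co-expression weights):
#   a_ij = softmax_j( q_i . (k_j + We e_ij) / sqrt(d_head) )
# and projects nodes and edges to the mean / log-variance of a Gaussian
# latent. The decoder lifts sampled latents, applies further blocks and a
# small MLP, and reconstructs a probabilistic adjacency matrix from
# source/target-projected inner products plus a pooled edge term.
#
# Forward and backward passes are written out explicitly; the gradient of
# every trainable parameter is verified against finite differences in the
# test suite.

block_init <- function(h) {
  list(
    Wq = glorot(h, h), bq = rep(0, h),
    Wk = glorot(h, h), bk = rep(0, h),
    Wv = glorot(h, h), bv = rep(0, h),
    We = glorot(h, h), be = rep(0, h),
    Wo = glorot(h, h), bo = rep(0, h),
    ff_W1 = glorot(h, h), ff_b1 = rep(0, h),
    ff_W2 = glorot(h, h), ff_b2 = rep(0, h),
    bn_n_gamma = rep(1, h), bn_n_beta = rep(0, h),
    er_W = glorot(3L * h, h), er_b = rep(0, h),
    bn_e_gamma = rep(1, h), bn_e_beta = rep(0, h)
  )
}

block_zero_grads <- function(bp) params_map(bp, function(x) x * 0)

#' Initialise the graph-transformer VAE parameters
#'
#' @param cfg a [run_config()].
#' @return list with trainable `params` and batch-norm `bn_state`
#'   (running statistics, tracked during training as the fallback for
#'   single-row inputs; multi-row batches always normalise by their own
#'   statistics).
#' @keywords internal
gvae_init <- function(cfg) {
  d <- cfg$embed_dim; h <- cfg$hidden_dim; L <- cfg$latent_dim
  params <- list(
    node_in_W = glorot(d, h), node_in_b = rep(0, h),
    edge_in_W = glorot(1L, h), edge_in_b = rep(0, h),
    enc_blocks = lapply(seq_len(cfg$encoder_blocks), function(i) block_init(h)),
    node_mu_W = glorot(h, L), node_mu_b = rep(0, L),
    node_lv_W = glorot(h, L), node_lv_b = rep(0, L),
    edge_mu_W = glorot(h, L), edge_mu_b = rep(0, L),
    edge_lv_W = glorot(h, L), edge_lv_b = rep(0, L),
    dec_node_W = glorot(L, h), dec_node_b = rep(0, h),
    dec_edge_W = glorot(L, h), dec_edge_b = rep(0, h),
    dec_blocks = lapply(seq_len(cfg$decoder_blocks), function(i) block_init(h)),
    nm_W1 = glorot(h, h), nm_b1 = rep(0, h),
    nm_W2 = glorot(h, L), nm_b2 = rep(0, L),
    em_W1 = glorot(h, h), em_b1 = rep(0, h),
    em_W2 = glorot(h, 1L), em_b2 = rep(0, 1L),
    rec_Ws = glorot(L, L), rec_Wt = glorot(L, L),
    rec_pool = 1
  )
  bn_one <- function() list(
    node = list(run_mean = rep(0, h), run_var = rep(1, h), seen = FALSE),
    edge = list(run_mean = rep(0, h), run_var = rep(1, h), seen = FALSE))
  bn_state <- list(enc = lapply(seq_len(cfg$encoder_blocks), function(i) bn_one()),
                   dec = lapply(seq_len(cfg$decoder_blocks), function(i) bn_one()))
  list(params = params, bn_state = bn_state)
}

# directed edge arrays for one subgraph: each undirected co-expression edge
# contributes both orientations; edge t and t + n_und are mutual reverses
subgraph_arrays <- function(sg) {
  n <- length(sg$node_ids)
  ai <- match(sg$edges$a, sg$node_ids)
  bi <- match(sg$edges$b, sg$node_ids)
  list(n = n, n_und = length(ai),
       src = c(ai, bi), dst = c(bi, ai),
       w = rep(sg$edges$weight, 2L),
       is_tf = as.logical(sg$is_tf[sg$node_ids]))
}

# 0/1 map from hidden columns to heads: logits = (q[dst]*ksum) %*% head_map
head_map <- function(h, H) {
  dh <- h %/% H
  hm <- matrix(0, h, H)
  for (i in seq_len(H)) hm[((i - 1L) * dh + 1L):(i * dh), i] <- 1
  hm
}

# numerically stable softmax within dst groups, per head (columns)
segment_softmax <- function(logits, groups, n) {
  .segment_softmax_cpp(logits, as.integer(groups), as.integer(n))
}

#' Edge-aware pairwise attention weights of one block
#'
#' Computes, for every directed edge and attention head, the attention
#' weight of target node `dst` over its in-neighbourhood:
#' `softmax( q_dst . (k_src + We e) / sqrt(d_head) )`. Weights sum to 1
#' over each target node's in-edges, per head.
#'
#' @param x node features (nodes x hidden).
#' @param e edge features (directed edges x hidden).
#' @param src,dst integer endpoint indices per directed edge.
#' @param bp block parameters (as in [gvae_init()]`$params$enc_blocks`).
#' @param heads number of attention heads.
#' @return matrix (directed edges x heads) of attention weights.
#' @export
pairwise_attention <- function(x, e, src, dst, bp, heads = 4L) {
  att <- attention_forward(x, e, src, dst, bp, heads)
  att$alpha
}

attention_forward <- function(x, e, src, dst, bp, H) {
  h <- ncol(x)
  dh <- h %/% H
  scale <- sqrt(dh)
  q <- add_bias(x %*% bp$Wq, bp$bq)
  k <- add_bias(x %*% bp$Wk, bp$bk)
  v <- add_bias(x %*% bp$Wv, bp$bv)
  ep <- add_bias(e %*% bp$We, bp$be)
  ksum <- k[src, , drop = FALSE] + ep
  hm <- head_map(h, H)
  logits <- ((q[dst, , drop = FALSE] * ksum) %*% hm) / scale
  alpha <- segment_softmax(logits, dst, nrow(x))
  list(alpha = alpha, q = q, k = k, v = v, ep = ep, ksum = ksum,
       hm = hm, scale = scale, dh = dh)
}

scatter_rows <- function(values, groups, n) {
  .segment_sum_rows_cpp(values, as.integer(groups), as.integer(n))
}

block_forward <- function(x, e, arr, bp, bn_blk, H, slope, training) {
  n <- nrow(x)
  cache <- list(x = x, e = e, has_edges = length(arr$src) > 0L)
  if (cache$has_edges) {
    att <- attention_forward(x, e, arr$src, arr$dst, bp, H)
    cache$att <- att
    alpha_full <- att$alpha[, rep(seq_len(H), each = att$dh), drop = FALSE]
    vsum <- att$v[arr$src, , drop = FALSE] + att$ep
    cache$vsum <- vsum
    cache$alpha_full <- alpha_full
    m <- scatter_rows(alpha_full * vsum, arr$dst, n)
  } else {
    m <- matrix(0, n, ncol(x))
  }
  cache$m <- m
  u <- x + add_bias(m %*% bp$Wo, bp$bo)
  cache$u <- u
  f1 <- add_bias(u %*% bp$ff_W1, bp$ff_b1)
  f1a <- lrelu_f(f1, slope)
  un <- u + add_bias(f1a %*% bp$ff_W2, bp$ff_b2)
  cache$f1 <- f1; cache$f1a <- f1a; cache$un <- un
  act <- lrelu_f(un, slope)
  bnf <- bn_forward(act, c(list(gamma = bp$bn_n_gamma, beta = bp$bn_n_beta),
                           bn_blk$node), training)
  cache$bn_n <- bnf$cache
  bn_blk$node <- bnf$state[c("run_mean", "run_var", "seen")]
  x_out <- bnf$y
  if (cache$has_edges) {
    ec <- cbind(x[arr$dst, , drop = FALSE], x[arr$src, , drop = FALSE], e)
    pre_e <- add_bias(ec %*% bp$er_W, bp$er_b)
    ge <- lrelu_f(pre_e, slope)
    en_pre <- e + ge
    act_e <- lrelu_f(en_pre, slope)
    bne <- bn_forward(act_e, c(list(gamma = bp$bn_e_gamma, beta = bp$bn_e_beta),
                               bn_blk$edge), training)
    cache$ec <- ec; cache$pre_e <- pre_e; cache$en_pre <- en_pre
    cache$bn_e <- bne$cache
    bn_blk$edge <- bne$state[c("run_mean", "run_var", "seen")]
    e_out <- bne$y
  } else {
    e_out <- e
  }
  list(x = x_out, e = e_out, cache = cache, bn_blk = bn_blk)
}

block_backward <- function(dx_out, de_out, cache, arr, bp, H, slope) {
  g <- block_zero_grads(bp)
  n <- nrow(cache$x)
  h <- ncol(cache$x)
  dx <- matrix(0, n, h)
  de <- matrix(0, nrow(cache$e), h)
  # edge path
  if (cache$has_edges && nrow(cache$e)) {
    bne <- bn_backward(de_out, cache$bn_e, bp$bn_e_gamma)
    g$bn_e_gamma <- bne$dgamma; g$bn_e_beta <- bne$dbeta
    d_enpre <- bne$dx * lrelu_g(cache$en_pre, slope)
    de <- de + d_enpre
    dpre <- d_enpre * lrelu_g(cache$pre_e, slope)
    g$er_W <- crossprod(cache$ec, dpre)
    g$er_b <- colSums(dpre)
    dec_ <- dpre %*% t(bp$er_W)
    dx <- dx + scatter_rows(dec_[, 1:h, drop = FALSE], arr$dst, n)
    dx <- dx + scatter_rows(dec_[, (h + 1):(2 * h), drop = FALSE], arr$src, n)
    de <- de + dec_[, (2 * h + 1):(3 * h), drop = FALSE]
  }
  # node path
  bnn <- bn_backward(dx_out, cache$bn_n, bp$bn_n_gamma)
  g$bn_n_gamma <- bnn$dgamma; g$bn_n_beta <- bnn$dbeta
  dun <- bnn$dx * lrelu_g(cache$un, slope)
  du <- dun
  g$ff_W2 <- crossprod(cache$f1a, dun)
  g$ff_b2 <- colSums(dun)
  df1 <- (dun %*% t(bp$ff_W2)) * lrelu_g(cache$f1, slope)
  g$ff_W1 <- crossprod(cache$u, df1)
  g$ff_b1 <- colSums(df1)
  du <- du + df1 %*% t(bp$ff_W1)
  dO <- du
  dx <- dx + du # residual
  g$Wo <- crossprod(cache$m, dO)
  g$bo <- colSums(dO)
  dm <- dO %*% t(bp$Wo)
  if (cache$has_edges) {
    att <- cache$att
    dh <- att$dh
    dmsg <- dm[arr$dst, , drop = FALSE]
    dalpha_full <- dmsg * cache$vsum
    dvsum <- dmsg * cache$alpha_full
    dalpha <- dalpha_full %*% att$hm
    # segment softmax backward within dst groups, per head
    ssum <- .segment_expand_sum_cpp(att$alpha * dalpha,
                                    as.integer(arr$dst), as.integer(n))
    dlog <- att$alpha * (dalpha - ssum)
    dP <- dlog[, rep(seq_len(H), each = dh), drop = FALSE] / att$scale
    dq_edge <- dP * att$ksum
    dksum <- dP * att$q[arr$dst, , drop = FALSE]
    dq <- scatter_rows(dq_edge, arr$dst, n)
    dk <- scatter_rows(dksum, arr$src, n)
    dv <- scatter_rows(dvsum, arr$src, n)
    dep <- dksum + dvsum
    g$Wq <- crossprod(cache$x, dq); g$bq <- colSums(dq)
    g$Wk <- crossprod(cache$x, dk); g$bk <- colSums(dk)
    g$Wv <- crossprod(cache$x, dv); g$bv <- colSums(dv)
    g$We <- crossprod(cache$e, dep); g$be <- colSums(dep)
    dx <- dx + dq %*% t(bp$Wq) + dk %*% t(bp$Wk) + dv %*% t(bp$Wv)
    de <- de + dep %*% t(bp$We)
  }
  list(dx = dx, de = de, g = g)
}

# ---- staged forward ----------------------------------------------------

encode_stage <- function(emb, arr, params, bn_state, H, slope, training) {
  cache <- list()
  pre_x <- add_bias(emb %*% params$node_in_W, params$node_in_b)
  x <- lrelu_f(pre_x, slope)
  cache$emb <- emb; cache$pre_x <- pre_x
  ew <- matrix(arr$w, ncol = 1L)
  pre_e <- add_bias(ew %*% params$edge_in_W, params$edge_in_b)
  e <- lrelu_f(pre_e, slope)
  cache$ew <- ew; cache$pre_e <- pre_e
  cache$blocks <- list()
  for (b in seq_along(params$enc_blocks)) {
    bf <- block_forward(x, e, arr, params$enc_blocks[[b]],
                        bn_state$enc[[b]], H, slope, training)
    x <- bf$x; e <- bf$e
    cache$blocks[[b]] <- bf$cache
    bn_state$enc[[b]] <- bf$bn_blk
  }
  cache$x_top <- x; cache$e_top <- e
  clamp <- function(m) pmin(pmax(m, -10), 10)
  out <- list(
    node_mu = add_bias(x %*% params$node_mu_W, params$node_mu_b),
    node_log_var = clamp(add_bias(x %*% params$node_lv_W, params$node_lv_b)),
    edge_mu = add_bias(e %*% params$edge_mu_W, params$edge_mu_b),
    edge_log_var = clamp(add_bias(e %*% params$edge_lv_W, params$edge_lv_b)))
  list(latent = out, cache = cache, bn_state = bn_state)
}

decode_stage <- function(z_n, z_e, arr, params, bn_state, H, slope, training) {
  cache <- list(z_n = z_n, z_e = z_e)
  pre_x <- add_bias(z_n %*% params$dec_node_W, params$dec_node_b)
  x <- lrelu_f(pre_x, slope)
  pre_e <- add_bias(z_e %*% params$dec_edge_W, params$dec_edge_b)
  e <- lrelu_f(pre_e, slope)
  cache$pre_x <- pre_x; cache$pre_e <- pre_e
  cache$blocks <- list()
  for (b in seq_along(params$dec_blocks)) {
    bf <- block_forward(x, e, arr, params$dec_blocks[[b]],
                        bn_state$dec[[b]], H, slope, training)
    x <- bf$x; e <- bf$e
    cache$blocks[[b]] <- bf$cache
    bn_state$dec[[b]] <- bf$bn_blk
  }
  cache$x_top <- x; cache$e_top <- e
  nm1 <- add_bias(x %*% params$nm_W1, params$nm_b1)
  nm1a <- lrelu_f(nm1, slope)
  Zp <- add_bias(nm1a %*% params$nm_W2, params$nm_b2)
  cache$nm1 <- nm1; cache$nm1a <- nm1a
  if (nrow(e)) {
    em1 <- add_bias(e %*% params$em_W1, params$em_b1)
    em1a <- lrelu_f(em1, slope)
    a_e <- as.numeric(add_bias(em1a %*% params$em_W2, params$em_b2))
    cache$em1 <- em1; cache$em1a <- em1a
  } else {
    a_e <- numeric()
  }
  list(Zp = Zp, edge_att = a_e, cache = cache, bn_state = bn_state)
}

recon_stage <- function(Zp, a_e, arr, params) {
  Zs <- Zp %*% params$rec_Ws
  Zt <- Zp %*% params$rec_Wt
  M <- tcrossprod(Zs, Zt)
  if (arr$n_und > 0L) {
    pooled <- (a_e[seq_len(arr$n_und)] + a_e[arr$n_und + seq_len(arr$n_und)]) / 2
    add <- params$rec_pool * pooled
    i <- arr$src[seq_len(arr$n_und)]
    j <- arr$dst[seq_len(arr$n_und)]
    M[cbind(i, j)] <- M[cbind(i, j)] + add
    M[cbind(j, i)] <- M[cbind(j, i)] + add
  }
  list(logits = M, prob = 1 / (1 + exp(-M)), Zs = Zs, Zt = Zt)
}

# full forward pass through the VAE for one subgraph's embeddings
gvae_forward <- function(emb, arr, params, bn_state, H, slope,
                             training = FALSE) {
  enc <- encode_stage(emb, arr, params, bn_state, H, slope, training)
  ld <- enc$latent
  if (training) {
    eps_n <- matrix(stats::rnorm(length(ld$node_mu)), nrow(ld$node_mu),
                    ncol(ld$node_mu))
    eps_e <- matrix(stats::rnorm(length(ld$edge_mu)), nrow(ld$edge_mu),
                    ncol(ld$edge_mu))
    z_n <- ld$node_mu + exp(0.5 * ld$node_log_var) * eps_n
    z_e <- ld$edge_mu + exp(0.5 * ld$edge_log_var) * eps_e
  } else {
    eps_n <- NULL; eps_e <- NULL
    z_n <- ld$node_mu
    z_e <- ld$edge_mu
  }
  dec <- decode_stage(z_n, z_e, arr, params, enc$bn_state, H, slope, training)
  rec <- recon_stage(dec$Zp, dec$edge_att, arr, params)
  list(latent = ld, eps_n = eps_n, eps_e = eps_e, z_n = z_n, z_e = z_e,
       Zp = dec$Zp, edge_att = dec$edge_att, logits = rec$logits,
       prob = rec$prob, enc_cache = enc$cache, dec_cache = dec$cache,
       rec = rec, bn_state = dec$bn_state, training = training)
}

# backward through the VAE given dL/dlogits and the KL weight beta.
# returns gradient for every trainable parameter plus dL/d(embeddings)
gvae_backward <- function(dM, fw, arr, params, H, slope, beta) {
  g <- params_map(params, function(x) x * 0)
  L <- ncol(fw$Zp)
  # reconstruction
  dZs <- dM %*% fw$rec$Zt
  dZt <- crossprod(dM, fw$rec$Zs)
  g$rec_Ws <- crossprod(fw$Zp, dZs)
  g$rec_Wt <- crossprod(fw$Zp, dZt)
  dZp <- dZs %*% t(params$rec_Ws) + dZt %*% t(params$rec_Wt)
  da <- numeric(length(fw$edge_att))
  if (arr$n_und > 0L) {
    i <- arr$src[seq_len(arr$n_und)]
    j <- arr$dst[seq_len(arr$n_und)]
    dpool <- dM[cbind(i, j)] + dM[cbind(j, i)]
    pooled <- (fw$edge_att[seq_len(arr$n_und)] +
                 fw$edge_att[arr$n_und + seq_len(arr$n_und)]) / 2
    g$rec_pool <- sum(dpool * pooled)
    da[seq_len(arr$n_und)] <- params$rec_pool * dpool / 2
    da[arr$n_und + seq_len(arr$n_und)] <- params$rec_pool * dpool / 2
  }
  # decoder MLPs
  dc <- fw$dec_cache
  dnm1a <- dZp %*% t(params$nm_W2)
  g$nm_W2 <- crossprod(dc$nm1a, dZp)
  g$nm_b2 <- colSums(dZp)
  dnm1 <- dnm1a * lrelu_g(dc$nm1, slope)
  g$nm_W1 <- crossprod(dc$x_top, dnm1)
  g$nm_b1 <- colSums(dnm1)
  dx <- dnm1 %*% t(params$nm_W1)
  de <- matrix(0, nrow(dc$e_top), ncol(dc$e_top))
  if (length(fw$edge_att)) {
    da_m <- matrix(da, ncol = 1L)
    dem1a <- da_m %*% t(params$em_W2)
    g$em_W2 <- crossprod(dc$em1a, da_m)
    g$em_b2 <- sum(da_m)
    dem1 <- dem1a * lrelu_g(dc$em1, slope)
    g$em_W1 <- crossprod(dc$e_top, dem1)
    g$em_b1 <- colSums(dem1)
    de <- de + dem1 %*% t(params$em_W1)
  }
  # decoder blocks (reverse)
  for (b in rev(seq_along(params$dec_blocks))) {
    bb <- block_backward(dx, de, dc$blocks[[b]], arr,
                         params$dec_blocks[[b]], H, slope)
    g$dec_blocks[[b]] <- bb$g
    dx <- bb$dx; de <- bb$de
  }
  # decoder input lifts
  dprex <- dx * lrelu_g(dc$pre_x, slope)
  g$dec_node_W <- crossprod(dc$z_n, dprex)
  g$dec_node_b <- colSums(dprex)
  dz_n <- dprex %*% t(params$dec_node_W)
  dpree <- de * lrelu_g(dc$pre_e, slope)
  g$dec_edge_W <- crossprod(dc$z_e, dpree)
  g$dec_edge_b <- colSums(dpree)
  dz_e <- dpree %*% t(params$dec_edge_W)
  # reparameterisation + KL
  ld <- fw$latent
  if (fw$training) {
    dmu_n <- dz_n
    dlv_n <- dz_n * fw$eps_n * 0.5 * exp(0.5 * ld$node_log_var)
    dmu_e <- dz_e
    dlv_e <- dz_e * fw$eps_e * 0.5 * exp(0.5 * ld$edge_log_var)
  } else {
    dmu_n <- dz_n; dlv_n <- ld$node_log_var * 0
    dmu_e <- dz_e; dlv_e <- ld$edge_log_var * 0
  }
  dmu_n <- dmu_n + beta * ld$node_mu
  dlv_n <- dlv_n + beta * 0.5 * (exp(ld$node_log_var) - 1)
  dmu_e <- dmu_e + beta * ld$edge_mu
  dlv_e <- dlv_e + beta * 0.5 * (exp(ld$edge_log_var) - 1)
  # variational heads
  ec <- fw$enc_cache
  g$node_mu_W <- crossprod(ec$x_top, dmu_n); g$node_mu_b <- colSums(dmu_n)
  g$node_lv_W <- crossprod(ec$x_top, dlv_n); g$node_lv_b <- colSums(dlv_n)
  dx <- dmu_n %*% t(params$node_mu_W) + dlv_n %*% t(params$node_lv_W)
  de <- matrix(0, nrow(ec$e_top), ncol(ec$e_top))
  if (nrow(ec$e_top)) {
    g$edge_mu_W <- crossprod(ec$e_top, dmu_e); g$edge_mu_b <- colSums(dmu_e)
    g$edge_lv_W <- crossprod(ec$e_top, dlv_e); g$edge_lv_b <- colSums(dlv_e)
    de <- dmu_e %*% t(params$edge_mu_W) + dlv_e %*% t(params$edge_lv_W)
  }
  # encoder blocks (reverse)
  for (b in rev(seq_along(params$enc_blocks))) {
    bb <- block_backward(dx, de, ec$blocks[[b]], arr,
                         params$enc_blocks[[b]], H, slope)
    g$enc_blocks[[b]] <- bb$g
    dx <- bb$dx; de <- bb$de
  }
  # input lifts
  dprex <- dx * lrelu_g(ec$pre_x, slope)
  g$node_in_W <- crossprod(ec$emb, dprex)
  g$node_in_b <- colSums(dprex)
  demb <- dprex %*% t(params$node_in_W)
  dpree <- de * lrelu_g(ec$pre_e, slope)
  g$edge_in_W <- crossprod(ec$ew, dpree)
  g$edge_in_b <- colSums(dpree)
  list(grads = g, demb = demb)
}

#' Reparameterised sampling from a latent distribution
#'
#' `z = mu + sigma * eps` with `eps` standard normal during training; at
#' evaluation the mean is returned, making inference deterministic.
#'
#' @param ld list with `node_mu`, `node_log_var`, `edge_mu`,
#'   `edge_log_var` (from the encoder).
#' @param training draw noise (`TRUE`) or return means (`FALSE`).
#' @param seed optional integer seed for the draw.
#' @return list with `z_n` (nodes x latent) and `z_e` (edges x latent).
#' @export
reparameterize <- function(ld, training = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!training)
    return(list(z_n = ld$node_mu, z_e = ld$edge_mu))
  eps_n <- matrix(stats::rnorm(length(ld$node_mu)), nrow(ld$node_mu),
                  ncol(ld$node_mu))
  eps_e <- matrix(stats::rnorm(length(ld$edge_mu)), nrow(ld$edge_mu),
                  ncol(ld$edge_mu))
  list(z_n = ld$node_mu + exp(0.5 * ld$node_log_var) * eps_n,
       z_e = ld$edge_mu + exp(0.5 * ld$edge_log_var) * eps_e)
}

#' Reconstruct the probabilistic adjacency matrix of a subgraph
#'
#' Edge logit `(i, j)` is the inner product of the source-projected and
#' target-projected decoder embeddings plus a learned scalar times the
#' pooled (mean of both orientations) edge attention of the co-expression
#' edge `{i, j}` when one exists; a sigmoid maps logits to probabilities
#' strictly inside `(0, 1)`. The diagonal is set to `NA` (self-edges are
#' excluded from training and aggregation).
#'
#' @param Zp decoder node embeddings (nodes x latent).
#' @param edge_att decoder per-directed-edge attention scalars.
#' @param arr subgraph arrays (internal; see `subgraph_arrays`).
#' @param params VAE parameter list.
#' @return nodes x nodes probability matrix with `NA` diagonal.
#' @export
reconstruct_adjacency <- function(Zp, edge_att, arr, params) {
  rec <- recon_stage(Zp, edge_att, arr, params)
  p <- rec$prob
  diag(p) <- NA_real_
  p
}
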
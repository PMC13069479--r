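# arrays for a hand-built directed edge structure
toy_arr <- function(n, src, dst, w = NULL, n_und = length(src) / 2) {
  if (is.null(w)) w <- rep(0.5, length(src))
  list(n = n, n_und = n_und, src = src, dst = dst, w = w,
       is_tf = c(TRUE, rep(FALSE, n - 1L)))
}

test_that("attention weights are uniform when queries/keys coincide", {
  h <- 4L
  bp <- scregnet:::block_init(h)
  bp$Wq[] <- 0; bp$Wk[] <- 0; bp$We[] <- 0
  bp$bq <- rep(1, h); bp$bk <- rep(0, h); bp$be <- rep(0, h)
  x <- matrix(rnorm(5 * h), 5, h)
  e <- matrix(0, 4, h)
  # four edges, all into node 1
  alpha <- pairwise_attention(x, e, src = 2:5, dst = rep(1L, 4), bp,
                              heads = 2L)
  expect_equal(unname(alpha), matrix(0.25, 4, 2))
  # a single in-neighbour receives weight 1
  alpha1 <- pairwise_attention(x, e[1, , drop = FALSE], src = 2L,
                               dst = 1L, bp, heads = 2L)
  expect_equal(unname(alpha1), matrix(1, 1, 2))
})

test_that("attention matches a hand-computed scalar softmax", {
  # 1-dim, 1-head: logit_t = q[dst] * (k[src] + We * e_t)
  bp <- scregnet:::block_init(1L)
  bp$Wq[] <- 1.3; bp$bq <- 0.2
  bp$Wk[] <- -0.7; bp$bk <- 0.1
  bp$We[] <- 0.9; bp$be <- -0.05
  x <- matrix(c(0.5, -1.2, 2.0), 3, 1)
  e <- matrix(c(0.4, -0.6), 2, 1)
  alpha <- pairwise_attention(x, e, src = c(2L, 3L), dst = c(1L, 1L), bp,
                              heads = 1L)
  q1 <- 1.3 * 0.5 + 0.2
  lg <- q1 * ((-0.7 * c(-1.2, 2.0) + 0.1) + (0.9 * c(0.4, -0.6) - 0.05))
  expect_equal(as.numeric(alpha), exp(lg) / sum(exp(lg)), tolerance = 1e-8)
})

test_that("attention weights normalise per target node and head", {
  set.seed(6)
  h <- 8L
  bp <- scregnet:::block_init(h)
  n <- 10L
  src <- sample(n, 40, replace = TRUE)
  dst <- sample(n, 40, replace = TRUE)
  keep <- src != dst
  src <- src[keep]; dst <- dst[keep]
  x <- matrix(rnorm(n * h), n, h)
  e <- matrix(rnorm(length(src) * h), length(src), h)
  alpha <- pairwise_attention(x, e, src, dst, bp, heads = 4L)
  for (i in unique(dst)) {
    sums <- colSums(alpha[dst == i, , drop = FALSE])
    expect_equal(unname(sums), rep(1, 4L), tolerance = 1e-6)
  }
})

test_that("one graph transformer block matches scalar arithmetic", {
  slope <- 0.01
  lr <- function(z) ifelse(z > 0, z, slope * z)
  bp <- scregnet:::block_init(1L)
  set.seed(7)
  for (nm in c("Wq", "Wk", "Wv", "We", "Wo", "ff_W1", "ff_W2", "er_W"))
    bp[[nm]][] <- round(rnorm(length(bp[[nm]])), 2)
  for (nm in c("bq", "bk", "bv", "be", "bo", "ff_b1", "ff_b2", "er_b"))
    bp[[nm]][] <- round(rnorm(length(bp[[nm]])), 2) / 5
  x <- matrix(c(0.8, -0.3, 1.1), 3, 1)
  e <- matrix(c(0.5, -0.2, 0.5, -0.2), 4, 1) # both orientations
  arr <- toy_arr(3L, src = c(1L, 2L, 2L, 3L), dst = c(2L, 1L, 3L, 2L),
                 n_und = 2)
  bn_blk <- list(node = list(run_mean = 0, run_var = 1, seen = FALSE),
                 edge = list(run_mean = 0, run_var = 1, seen = FALSE))
  out <- scregnet:::block_forward(x, e, arr, bp, bn_blk, H = 1L,
                                  slope = slope, training = TRUE)
  # independent scalar evaluation
  q <- as.numeric(x) * bp$Wq[1] + bp$bq
  k <- as.numeric(x) * bp$Wk[1] + bp$bk
  v <- as.numeric(x) * bp$Wv[1] + bp$bv
  ep <- as.numeric(e) * bp$We[1] + bp$be
  lg <- q[arr$dst] * (k[arr$src] + ep)
  alpha <- numeric(4)
  for (i in 1:3) {
    grp <- which(arr$dst == i)
    if (length(grp)) alpha[grp] <- exp(lg[grp]) / sum(exp(lg[grp]))
  }
  m <- numeric(3)
  for (t in 1:4) m[arr$dst[t]] <- m[arr$dst[t]] +
      alpha[t] * (v[arr$src[t]] + ep[t])
  u <- as.numeric(x) + m * bp$Wo[1] + bp$bo
  un <- u + lr(u * bp$ff_W1[1] + bp$ff_b1) * bp$ff_W2[1] + bp$ff_b2
  act <- lr(un)
  mu <- mean(act); va <- mean(act^2) - mu^2
  xn <- (act - mu) / sqrt(va + 1e-5) * bp$bn_n_gamma + bp$bn_n_beta
  expect_equal(as.numeric(out$x), xn, tolerance = 1e-8)
  ec <- cbind(x[arr$dst], x[arr$src], as.numeric(e))
  ge <- lr(ec %*% bp$er_W + bp$er_b)
  ae <- lr(as.numeric(e) + as.numeric(ge))
  mue <- mean(ae); vae <- mean(ae^2) - mue^2
  en <- (ae - mue) / sqrt(vae + 1e-5) * bp$bn_e_gamma + bp$bn_e_beta
  expect_equal(as.numeric(out$e), en, tolerance = 1e-8)
})

test_that("blocks preserve shapes and the residual path", {
  set.seed(8)
  h <- 8L
  bp <- scregnet:::block_init(h)
  n <- 7L
  arr <- toy_arr(n, src = c(1L, 2L, 3L, 2L, 1L, 4L),
                 dst = c(2L, 1L, 2L, 3L, 4L, 1L), n_und = 3)
  x <- matrix(rnorm(n * h), n, h)
  e <- matrix(rnorm(6 * h), 6, h)
  bn_blk <- list(node = list(run_mean = rep(0, h), run_var = rep(1, h),
                             seen = FALSE),
                 edge = list(run_mean = rep(0, h), run_var = rep(1, h),
                             seen = FALSE))
  out <- scregnet:::block_forward(x, e, arr, bp, bn_blk, 2L, 0.01, TRUE)
  expect_equal(dim(out$x), dim(x))
  expect_equal(dim(out$e), dim(e))
  # zeroing attention (Wv = We = 0 => zero messages) does not zero output:
  # the residual path carries the input through
  bp0 <- bp
  bp0$Wv[] <- 0; bp0$bv[] <- 0; bp0$We[] <- 0; bp0$be[] <- 0
  out0 <- scregnet:::block_forward(x, e, arr, bp0, bn_blk, 2L, 0.01, TRUE)
  expect_gt(stats::sd(out0$x), 0)
  # leaky (not standard) ReLU: strongly negative pre-activations retain
  # scaled signal, so two distinct negative inputs stay distinct
  z <- matrix(c(-5, -3), 2, 1)
  expect_equal(scregnet:::lrelu_f(z, 0.01), z * 0.01)
})

test_that("the encoder produces 16-dim latents under defaults", {
  cfg <- run_config()
  expect_equal(cfg$latent_dim, 16L)
  set.seed(9)
  model <- grn_model_init(tiny_config())
  sg <- toy_subgraph()
  emb <- embed_subgraph(toy_features(sg), model$transcoder)
  ld <- encode(model, emb, sg)
  expect_equal(ncol(ld$node_mu), 4L) # tiny config latent
  full <- grn_model_init(run_config(seed = 2L))
  emb64 <- embed_subgraph(toy_features(sg), full$transcoder)
  ld64 <- encode(full, emb64, sg)
  expect_equal(ncol(ld64$node_mu), 16L)
  expect_equal(ncol(ld64$edge_mu), 16L)
  expect_true(all(is.finite(unlist(ld64))))
})

test_that("forward passes stay finite over many random draws", {
  model <- grn_model_init(tiny_config())
  sg <- toy_subgraph()
  arr <- scregnet:::subgraph_arrays(sg)
  for (s in 1:100) {
    set.seed(s)
    f <- toy_features(sg, seed = s)
    fw <- model_forward(model, f, arr, training = s %% 2 == 0)
    p <- fw$prob
    expect_true(all(is.finite(p)))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("reparameterisation follows z = mu + sigma * eps", {
  mu <- matrix(2, 50, 4)
  ld <- list(node_mu = mu, node_log_var = matrix(-60, 50, 4),
             edge_mu = mu[1:2, ], edge_log_var = matrix(-60, 2, 4))
  z <- reparameterize(ld, training = TRUE, seed = 1)
  expect_equal(z$z_n, mu, tolerance = 1e-10) # sigma ~ 0
  ld$node_log_var <- matrix(2 * log(3), 50, 4)
  z1 <- reparameterize(ld, training = TRUE, seed = 5)
  z2 <- reparameterize(ld, training = TRUE, seed = 5)
  expect_identical(z1, z2)
  expect_identical(reparameterize(ld, training = FALSE)$z_n, ld$node_mu)
  # law of large numbers at mu = 2, sigma = 3
  ld2 <- list(node_mu = matrix(2, 2500, 4),
              node_log_var = matrix(2 * log(3), 2500, 4),
              edge_mu = matrix(0, 0, 4), edge_log_var = matrix(0, 0, 4))
  draws <- reparameterize(ld2, training = TRUE, seed = 2)$z_n
  expect_lt(abs(mean(draws) - 2), 3 * 3 / sqrt(length(draws)))
  expect_lt(abs(stats::sd(draws) - 3) / 3, 0.05)
})

test_that("decoding responds to latent perturbations", {
  model <- grn_model_init(tiny_config())
  sg <- toy_subgraph()
  arr <- scregnet:::subgraph_arrays(sg)
  set.seed(10)
  z <- list(z_n = matrix(rnorm(6 * 4), 6, 4),
            z_e = matrix(rnorm(8 * 4), 8, 4))
  d1 <- decode(model, z, arr)
  expect_equal(nrow(d1$Zp), 6L)
  expect_true(all(is.finite(d1$Zp)))
  z2 <- z
  z2$z_n[3, ] <- z2$z_n[3, ] + 0.5
  d2 <- decode(model, z2, arr)
  expect_gt(max(abs(d2$Zp[3, ] - d1$Zp[3, ])), 0)
})

test_that("adjacency reconstruction is a sigmoid of inner products", {
  model <- grn_model_init(tiny_config())
  params <- model$vae
  params$rec_Ws <- diag(4); params$rec_Wt <- diag(4)
  arr <- toy_arr(3L, src = integer(), dst = integer(), w = numeric(),
                 n_und = 0)
  # zero embeddings, no pooled term -> all probabilities 0.5
  p0 <- reconstruct_adjacency(matrix(0, 3, 4), numeric(), arr, params)
  expect_true(all(p0[!is.na(p0)] == 0.5))
  expect_true(all(is.na(diag(p0))))
  # increasing the inner product increases the probability
  Zp <- matrix(c(1, 0, 0, 0, 0.5, 0, 0, 0, -0.5, 0, 0, 0), 3, 4,
               byrow = TRUE)
  p1 <- reconstruct_adjacency(Zp, numeric(), arr, params)
  probs <- sapply(c(0.5, 1, 2), function(s) {
    reconstruct_adjacency(Zp * s, numeric(), arr, params)[1, 2]
  })
  expect_true(all(diff(probs) > 0))
  # identical embeddings with symmetric pooling give a symmetric score
  Zs <- matrix(rnorm(12), 3, 4)
  Zs[2, ] <- Zs[1, ]
  p2 <- reconstruct_adjacency(Zs, numeric(), arr, params)
  expect_equal(p2[1, 2], p2[2, 1])
})

test_that("every VAE gradient matches finite differences", {
  cfg <- tiny_config()
  model <- grn_model_init(cfg)
  sg <- toy_subgraph()
  arr <- scregnet:::subgraph_arrays(sg)
  f <- toy_features(sg)
  pairs <- data.frame(i = c(1, 1, 2, 3), j = c(2, 4, 5, 6), y = c(1, 0, 1, 0))
  loss_at <- function(m) {
    set.seed(99)
    fw <- model_forward(m, f, arr, training = TRUE)
    prob <- fw$prob[cbind(pairs$i, pairs$j)]
    bce <- bce_loss(prob, pairs$y)
    kl <- kl_divergence(fw$latent$node_mu, fw$latent$node_log_var) +
      kl_divergence(fw$latent$edge_mu, fw$latent$edge_log_var)
    total_loss(bce, kl, cfg$beta_mode, arr$n)$total
  }
  set.seed(99)
  res <- scregnet:::model_loss_grads(model, f, arr, pairs, training = TRUE)
  nested_get <- function(obj, path) { for (p in path) obj <- obj[[p]]; obj }
  nested_bump <- function(obj, path, i, h) {
    if (length(path) == 1L) { obj[[path[[1]]]][i] <- obj[[path[[1]]]][i] + h; return(obj) }
    obj[[path[[1]]]] <- nested_bump(obj[[path[[1]]]], path[-1], i, h)
    obj
  }
  paths <- list(list("vae", "node_in_W"), list("vae", "edge_in_W"),
                list("vae", "enc_blocks", 1L, "We"),
                list("vae", "enc_blocks", 2L, "er_W"),
                list("vae", "enc_blocks", 1L, "bn_n_gamma"),
                list("vae", "node_lv_W"), list("vae", "edge_mu_W"),
                list("vae", "dec_blocks", 2L, "Wv"),
                list("vae", "dec_node_W"), list("vae", "nm_W1"),
                list("vae", "em_W2"), list("vae", "rec_Wt"),
                list("vae", "rec_pool"), list("transcoder", "Wo"),
                list("transcoder", "conv_b"))
  set.seed(123)
  for (pth in paths) {
    gv <- nested_get(res$grads, pth)
    i <- sample(length(gv), 1L)
    h <- 1e-6
    fd <- (loss_at(nested_bump(model, pth, i, h)) -
             loss_at(nested_bump(model, pth, i, -h))) / (2 * h)
    expect_equal(gv[i], fd, tolerance = 1e-4,
                 label = paste(unlist(pth), collapse = "/"))
  }
})
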
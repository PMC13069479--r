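# Shared neural-network plumbing: initialisers, activations, batch norm,
# Adam over arbitrarily nested parameter lists.

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

lrelu_f <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

lrelu_g <- function(x, slope) {
  g <- x
  pos <- x > 0
  g[pos] <- 1
  g[!pos] <- slope
  g
}

# add a length-ncol(x) vector to every row (fast sweep replacement)
add_bias <- function(x, b) x + rep(b, each = nrow(x))

# multiply / divide every row elementwise by a vector
mul_cols <- function(x, v) x * rep(v, each = nrow(x))

# ---- batch norm over rows (per-column statistics) ----------------------

bn_init <- function(d) {
  list(gamma = rep(1, d), beta = rep(0, d),
       run_mean = rep(0, d), run_var = rep(1, d))
}

# returns list(y, cache, state). Normalisation always uses the statistics
# of the current batch (= one subgraph's nodes or edges) when it has more
# than one row: subgraphs differ systematically in activation scale, so a
# cross-subgraph running average does not transfer and blows up the
# stacked blocks at evaluation. Running statistics are still tracked in
# training mode as the fallback for degenerate single-row inputs.
bn_forward <- function(x, bn, training, momentum = 0.1, eps = 1e-5) {
  if (nrow(x) > 1L) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    if (training) {
      if (is.null(bn$seen) || !bn$seen) {
        bn$run_mean <- mu
        bn$run_var <- v
        bn$seen <- TRUE
      } else {
        bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
        bn$run_var <- (1 - momentum) * bn$run_var + momentum * v
      }
    }
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
  }
  sd <- sqrt(v + eps)
  xhat <- mul_cols(add_bias(x, -mu), 1 / sd)
  y <- add_bias(mul_cols(xhat, bn$gamma), bn$beta)
  list(y = y, cache = list(xhat = xhat, sd = sd, batch = nrow(x) > 1L),
       state = bn)
}

# returns list(dx, dgamma, dbeta)
bn_backward <- function(dy, cache, gamma) {
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxh <- mul_cols(dy, gamma)
  if (cache$batch) {
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * cache$xhat)
    dx <- mul_cols(add_bias(dxh, -m1) - mul_cols(cache$xhat, m2),
                   1 / cache$sd)
  } else {
    dx <- mul_cols(dxh, 1 / cache$sd)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- nested-list parameter algebra -------------------------------------

params_map <- function(p, f) {
  if (is.list(p)) lapply(p, params_map, f = f) else f(p)
}

params_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- params_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

params_unlist <- function(p) unlist(p, use.names = FALSE)

params_relist <- function(values, skeleton) {
  i <- 0L
  fill <- function(p) {
    if (is.list(p)) return(lapply(p, fill))
    n <- length(p)
    out <- p
    out[] <- values[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  fill(skeleton)
}

# ---- Adam --------------------------------------------------------------

adam_init <- function(params) {
  list(m = params_map(params, function(x) x * 0),
       v = params_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- params_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- params_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- params_map2(state$m, state$v,
                     function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- params_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}
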
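#' Binary cross-entropy over labeled pairs (summed)
#'
#' `-sum(y * log(p) + (1 - y) * log(1 - p))` with probabilities clipped to
#' `[1e-7, 1 - 1e-7]`. Summed, not averaged, over the labeled pairs of a
#' subgraph.
#'
#' @param prob predicted probabilities in `(0, 1)`.
#' @param labels 0/1 vector of the same length.
#' @return non-negative scalar.
#' @export
bce_loss <- function(prob, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  if (length(prob) != length(labels)) stop("length mismatch")
  eps <- 1e-7
  p <- pmin(pmax(prob, eps), 1 - eps)
  -sum(labels * log(p) + (1 - labels) * log(1 - p))
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' `0.5 * sum(mu^2 + sigma^2 - log(sigma^2) - 1)`; non-negative, zero
#' exactly when `mu = 0` and `sigma = 1` everywhere.
#'
#' @param mu means (vector or matrix).
#' @param log_var log-variances of matching shape.
#' @return non-negative scalar.
#' @export
kl_divergence <- function(mu, log_var) {
  if (length(mu) != length(log_var)) stop("shape mismatch")
  if (!length(mu)) return(0)
  0.5 * sum(mu^2 + exp(log_var) - log_var - 1)
}

#' Combine reconstruction and regularisation terms
#'
#' `total = bce + beta * kl` with `beta = 1 / n_genes` of the subgraph by
#' default (`per_gene`), or a fixed value.
#'
#' @param bce,kl non-negative loss components.
#' @param beta_mode `"per_gene"` or `"fixed"`.
#' @param n_genes subgraph gene count (required for `per_gene`).
#' @param beta_fixed value used when `beta_mode = "fixed"`.
#' @return list with `bce`, `kl`, `beta`, `total`.
#' @export
total_loss <- function(bce, kl, beta_mode = "per_gene", n_genes = NULL,
                       beta_fixed = 0.01) {
  beta <- if (identical(beta_mode, "per_gene")) {
    if (is.null(n_genes) || n_genes < 1) stop("n_genes must be positive")
    1 / n_genes
  } else beta_fixed
  list(bce = bce, kl = kl, beta = beta, total = bce + beta * kl)
}
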
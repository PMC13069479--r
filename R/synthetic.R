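#' Specification of a synthetic regulatory benchmark
#'
#' Defines the generative conditions for a ground-truth GRN and matching
#' expression data. Defaults describe a compact but realistic single-cell
#' benchmark: 150 genes of which 15 are TFs, 300 cells, a mean TF
#' out-degree of 8 with a geometric-like tail, unit regulator-target
#' coupling, moderate additive noise and 30% dropout zeros, with a fifth of
#' the regulatory edges repressive (negative sign).
#'
#' @param n_genes total genes.
#' @param n_tfs transcription factors (must be fewer than `n_genes`).
#' @param edges_per_tf mean TF out-degree; realised degrees are
#'   `1 + Geometric` with this mean.
#' @param effect_size regulator-to-target coupling strength.
#' @param noise_sd additive Gaussian noise standard deviation on regulated
#'   genes.
#' @param dropout_rate probability that an expression entry is zeroed,
#'   mimicking scRNA-seq sparsity; in `[0, 1)`.
#' @param n_cells number of cells.
#' @param neg_fraction fraction of repressive (negative-sign) edges.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 150L, n_tfs = 15L, edges_per_tf = 8,
                           effect_size = 1, noise_sd = 0.5,
                           dropout_rate = 0.3, n_cells = 300L,
                           neg_fraction = 0.2, seed = 1L) {
  stopifnot(n_tfs < n_genes, n_tfs >= 0, dropout_rate >= 0, dropout_rate < 1,
            n_cells >= 2, edges_per_tf >= 1, effect_size >= 0, noise_sd >= 0)
  spec <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
               edges_per_tf = edges_per_tf, effect_size = effect_size,
               noise_sd = noise_sd, dropout_rate = dropout_rate,
               n_cells = as.integer(n_cells), neg_fraction = neg_fraction,
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

synthetic_gene_ids <- function(spec) {
  tf <- if (spec$n_tfs) sprintf("TF%02d", seq_len(spec$n_tfs)) else character()
  tgt_n <- spec$n_genes - spec$n_tfs
  tgt <- if (tgt_n) sprintf("G%03d", seq_len(tgt_n)) else character()
  list(tfs = tf, targets = tgt, all = c(tf, tgt))
}

#' Simulate a directed acyclic TF-to-target regulatory network
#'
#' TFs are ordered; a TF may regulate later TFs (keeping the graph acyclic)
#' or any non-TF gene. Out-degrees are `1 + Geometric` with mean
#' `edges_per_tf`. Each edge carries a sign: `-1` (repressive) with
#' probability `neg_fraction`, else `+1`.
#'
#' @param spec a [synthetic_spec()].
#' @return a [ground_truth_network()] with an extra `sign` column (empty
#'   when `n_tfs = 0`).
#' @export
simulate_grn <- function(spec) {
  set.seed(spec$seed)
  ids <- synthetic_gene_ids(spec)
  if (!spec$n_tfs) {
    gt <- data.frame(regulator = character(), target = character(),
                     source = character(), stringsAsFactors = FALSE)
    gt$sign <- numeric()
    class(gt) <- c("ground_truth_network", "data.frame")
    return(gt)
  }
  edges <- list()
  for (i in seq_len(spec$n_tfs)) {
    allowed <- c(if (i < spec$n_tfs) ids$tfs[(i + 1):spec$n_tfs], ids$targets)
    if (!length(allowed)) next
    k <- min(1L + stats::rgeom(1L, 1 / spec$edges_per_tf), length(allowed))
    tg <- sample(allowed, k)
    edges[[i]] <- data.frame(regulator = ids$tfs[i], target = tg,
                             stringsAsFactors = FALSE)
  }
  gt <- do.call(rbind, edges)
  gt$source <- "synthetic"
  gt$sign <- ifelse(stats::runif(nrow(gt)) < spec$neg_fraction, -1, 1)
  rownames(gt) <- NULL
  class(gt) <- c("ground_truth_network", "data.frame")
  gt
}

#' Simulate expression data consistent with a regulatory network
#'
#' Linear-Gaussian structural model propagated in topological order: root
#' genes are standard normal per cell; each regulated gene is
#' `effect_size * sum(sign_r * value_r)` over its regulators plus
#' `noise_sd` Gaussian noise. A softplus maps latent values to non-negative
#' "counts", and entries are then independently zeroed with probability
#' `dropout_rate`. Regulator-target pairs are therefore more strongly
#' correlated than random pairs whenever `effect_size > 0`.
#'
#' @param grn a [ground_truth_network()] with a `sign` column (as from
#'   [simulate_grn()]; a missing column defaults to `+1`).
#' @param spec the [synthetic_spec()] used to generate it.
#' @return an [expression_matrix()] with TF flags set.
#' @export
simulate_expression <- function(grn, spec) {
  set.seed(spec$seed + 1L)
  ids <- synthetic_gene_ids(spec)
  if (!"sign" %in% names(grn)) grn$sign <- rep(1, nrow(grn))
  # topological order: TFs in index order (edges only go forward), then targets
  order_ids <- ids$all
  if (nrow(grn) && any(!grn$regulator %in% ids$tfs))
    stop("grn regulators must be TFs of the same spec")
  regs_of <- split(seq_len(nrow(grn)), grn$target)
  latent <- matrix(0, spec$n_genes, spec$n_cells,
                   dimnames = list(order_ids, NULL))
  for (g in order_ids) {
    ridx <- regs_of[[g]]
    if (is.null(ridx)) {
      latent[g, ] <- stats::rnorm(spec$n_cells)
    } else {
      contrib <- grn$sign[ridx] * latent[grn$regulator[ridx], , drop = FALSE]
      latent[g, ] <- spec$effect_size * colSums(contrib) +
        spec$noise_sd * stats::rnorm(spec$n_cells)
    }
  }
  counts <- log1p(exp(pmin(latent, 30))) # softplus, overflow-guarded
  if (spec$dropout_rate > 0) {
    drop <- matrix(stats::runif(length(counts)) < spec$dropout_rate,
                   nrow(counts))
    counts[drop] <- 0
  }
  expression_matrix(counts,
                    gene_ids = order_ids,
                    cell_ids = sprintf("cell%03d", seq_len(spec$n_cells)),
                    tf_ids = ids$tfs)
}

#' Simulate a complete benchmark dataset
#'
#' @param spec a [synthetic_spec()].
#' @return list with `grn`, `expr`, `tfs` and the `spec` used.
#' @export
simulate_dataset <- function(spec = synthetic_spec()) {
  grn <- simulate_grn(spec)
  expr <- simulate_expression(grn, spec)
  list(grn = grn, expr = expr, tfs = synthetic_gene_ids(spec)$tfs,
       spec = spec)
}

#' Split ground-truth edges into train/validation/test by anchor TF
#'
#' All edges of a TF land on the same side, so evaluation TFs are never
#' seen during training (anchor-level holdout).
#'
#' @param ds a dataset from [simulate_dataset()] (or any list with `grn`
#'   and `tfs`).
#' @param holdout_tf_fraction fraction of TFs held out for testing.
#' @param val_tf_fraction fraction of the remaining TFs used for
#'   validation.
#' @param seed integer seed for the TF draw.
#' @return list with `train_tfs`, `val_tfs`, `test_tfs` and matching edge
#'   data.frames `train`, `val`, `test`.
#' @export
make_benchmark_split <- function(ds, holdout_tf_fraction = 0.2,
                                 val_tf_fraction = 0.1, seed = 1L) {
  tfs <- unique(ds$tfs)
  if (length(tfs) < 3L) stop("at least 3 TFs are required to split")
  set.seed(seed)
  n_test <- max(1L, round(holdout_tf_fraction * length(tfs)))
  test_tfs <- sample(tfs, n_test)
  rest <- setdiff(tfs, test_tfs)
  n_val <- max(1L, round(val_tf_fraction * length(rest)))
  val_tfs <- sample(rest, n_val)
  train_tfs <- setdiff(rest, val_tfs)
  pick <- function(set) {
    out <- ds$grn[ds$grn$regulator %in% set, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(train_tfs = train_tfs, val_tfs = val_tfs, test_tfs = test_tfs,
       train = pick(train_tfs), val = pick(val_tfs), test = pick(test_tfs))
}
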
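#' Inverse hyperbolic sine transform
#'
#' Variance-stabilising transform applied to raw expression before
#' correlations are computed: `asinh(x) = log(x + sqrt(x^2 + 1))`. Unlike
#' `log1p` it is defined for negative values and behaves linearly near zero.
#'
#' @param values numeric vector or matrix of finite values.
#' @return transformed object of the same shape.
#' @export
arcsinh_transform <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("arcsinh_transform requires finite numeric input")
  asinh(values)
}

#' Pairwise Pearson correlation between genes
#'
#' Correlates every pair of gene rows across cells. Genes with zero variance
#' have undefined correlations; their rows and columns (including the
#' diagonal) are set to 0 so they can never form co-expression edges.
#'
#' @param expr an [expression_matrix()] or a genes x cells numeric matrix.
#' @return symmetric genes x genes correlation matrix.
#' @export
pearson_matrix <- function(expr) {
  m <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  if (ncol(m) < 2L) stop("correlation requires at least 2 cells")
  sds <- apply(m, 1L, stats::sd)
  cc <- suppressWarnings(stats::cor(t(m)))
  zero <- sds == 0
  cc[zero, ] <- 0
  cc[, zero] <- 0
  cc[!is.finite(cc)] <- 0
  dimnames(cc) <- list(rownames(m), rownames(m))
  cc
}

#' Build the gene co-expression network (GCEN)
#'
#' Retains every unordered gene pair whose absolute correlation strictly
#' exceeds the threshold; signed weights are kept because negative
#' co-expression carries repressive signal downstream. Genes with no
#' surviving edge remain as isolated nodes so gene indexing stays stable.
#'
#' @param corr symmetric correlation matrix (e.g. from [pearson_matrix()]).
#' @param threshold retention threshold tau in `[0, 1)`; an edge is kept iff
#'   `|r| > tau` (strict).
#' @param is_tf optional logical TF flag per gene, carried on the network.
#' @return a `coexpression_network`: list with `gene_ids`, `is_tf`, an
#'   `edges` data.frame (`a`, `b`, `weight`, canonical a < b ordering) and
#'   `threshold`.
#' @export
build_network <- function(corr, threshold = 0.1, is_tf = NULL) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr)) stop("correlation matrix must be square")
  if (max(abs(corr - t(corr))) > 1e-8)
    stop("correlation matrix is not symmetric")
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)")
  ids <- rownames(corr)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(corr)))
  if (is.null(is_tf)) is_tf <- rep(FALSE, length(ids))
  keep <- which(upper.tri(corr) & abs(corr) > threshold, arr.ind = TRUE)
  edges <- data.frame(a = ids[keep[, 1L]], b = ids[keep[, 2L]],
                      weight = corr[keep], stringsAsFactors = FALSE)
  ord <- order(match(edges$a, ids), match(edges$b, ids))
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  net <- list(gene_ids = ids, is_tf = is_tf, edges = edges,
              threshold = threshold)
  class(net) <- "coexpression_network"
  net
}

#' Build a GCEN directly from expression data
#'
#' Convenience wrapper: arcsinh transform, Pearson correlations, threshold.
#'
#' @param expr an [expression_matrix()].
#' @param threshold retention threshold.
#' @return a `coexpression_network`.
#' @export
build_gcen <- function(expr, threshold = 0.1) {
  stopifnot(inherits(expr, "expression_matrix"))
  cc <- pearson_matrix(arcsinh_transform(expr$values))
  build_network(cc, threshold, is_tf = expr$is_tf)
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf(
    "coexpression_network: %d genes, %d edges (|r| > %g), %d TFs\n",
    length(x$gene_ids), nrow(x$edges), x$threshold, sum(x$is_tf)))
  invisible(x)
}

# adjacency list keyed by gene id, preserving edge insertion order per gene
gcen_adjacency <- function(net) {
  adj <- stats::setNames(vector("list", length(net$gene_ids)), net$gene_ids)
  for (g in net$gene_ids) adj[[g]] <- character()
  if (nrow(net$edges)) {
    sp_a <- split(net$edges$b, factor(net$edges$a, levels = net$gene_ids))
    sp_b <- split(net$edges$a, factor(net$edges$b, levels = net$gene_ids))
    for (g in net$gene_ids) adj[[g]] <- c(sp_a[[g]], sp_b[[g]])
  }
  adj
}

# weight lookup: named numeric with key "a|b" in canonical gene-index order
gcen_weight_map <- function(net) {
  if (!nrow(net$edges)) return(stats::setNames(numeric(), character()))
  stats::setNames(net$edges$weight, paste(net$edges$a, net$edges$b, sep = "|"))
}

#' Export a co-expression network as a TSV edge list
#'
#' @param net a `coexpression_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
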
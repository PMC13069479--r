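# helper: build a network from an explicit undirected edge list
net_from_edges <- function(edges, ids = NULL, tfs = character()) {
  if (is.null(ids)) ids <- sort(unique(c(edges$a, edges$b)))
  n <- length(ids)
  cc <- diag(n); dimnames(cc) <- list(ids, ids)
  for (k in seq_len(nrow(edges))) {
    w <- if (!is.null(edges$weight)) edges$weight[k] else 0.5
    cc[edges$a[k], edges$b[k]] <- w
    cc[edges$b[k], edges$a[k]] <- w
  }
  build_network(cc, 0.1, is_tf = ids %in% tfs)
}

test_that("a star anchor reaches its target in one hop", {
  edges <- data.frame(a = "hub", b = paste0("n", 1:300))
  net <- net_from_edges(edges, tfs = "hub")
  nb <- collect_neighborhood(net, "hub", target = 99L)
  expect_equal(length(nb$neighbors), 300L)
  expect_equal(nb$hop_reached, 1L)
  expect_false(nb$exhausted)
})

test_that("a path graph expands hop by hop until the target is met", {
  ids <- c("tf", paste0("g", 1:120))
  edges <- data.frame(a = ids[-length(ids)], b = ids[-1])
  net <- net_from_edges(edges, ids = ids, tfs = "tf")
  nb <- collect_neighborhood(net, "tf", target = 99L)
  expect_equal(length(nb$neighbors), 99L)
  expect_equal(nb$hop_reached, 99L)
  expect_identical(nb$neighbors, paste0("g", 1:99))
})

test_that("an exhausted component returns all reachable neighbours", {
  edges <- data.frame(a = rep("tf", 39), b = paste0("g", 1:39))
  net <- net_from_edges(edges, ids = c("tf", paste0("g", 1:39), "iso"),
                        tfs = "tf")
  nb <- collect_neighborhood(net, "tf", target = 99L)
  expect_equal(length(nb$neighbors), 39L)
  expect_true(nb$exhausted)
  expect_error(collect_neighborhood(net, "nope", 99L), "anchor")
})

test_that("training subgraphs hold exactly `size` nodes when possible", {
  edges <- data.frame(a = "hub", b = paste0("n", 1:300))
  net <- net_from_edges(edges, tfs = "hub")
  set.seed(1)
  sg <- sample_training_subgraph(net, "hub", size = 100L)
  expect_equal(length(sg$node_ids), 100L)
  expect_identical(sg$node_ids[1L], "hub")
  # exactly 99 neighbours: all taken, no sampling branch
  edges2 <- data.frame(a = "hub", b = paste0("n", 1:99))
  net2 <- net_from_edges(edges2, tfs = "hub")
  sg2 <- sample_training_subgraph(net2, "hub", size = 100L)
  expect_setequal(sg2$node_ids, c("hub", paste0("n", 1:99)))
  # isolated anchor is skipped with a message
  net3 <- net_from_edges(edges2, ids = c("hub", paste0("n", 1:99), "lone"),
                         tfs = c("hub", "lone"))
  expect_message(expect_null(sample_training_subgraph(net3, "lone", 100L)),
                 "isolated")
})

test_that("equal seeds reproduce identical subgraphs", {
  net <- random_network(60, p_edge = 0.3, seed = 2)
  set.seed(42)
  a <- sample_training_subgraph(net, "g1", size = 20L)
  set.seed(42)
  b <- sample_training_subgraph(net, "g1", size = 20L)
  expect_identical(a$node_ids, b$node_ids)
  expect_same_edges(a$edges, b$edges)
})

test_that("induced edge sets are complete and exact on random graphs", {
  for (s in 1:50) {
    net <- random_network(25, p_edge = 0.15, seed = 100 + s)
    set.seed(s)
    sg <- sample_training_subgraph(net, "g1", size = 12L)
    if (is.null(sg)) next
    wm <- stats::setNames(net$edges$weight,
                          paste(net$edges$a, net$edges$b, sep = "|"))
    # brute force over all node pairs of the subgraph
    expected <- character()
    for (i in seq_along(sg$node_ids)) for (j in seq_along(sg$node_ids)) {
      if (i >= j) next
      k1 <- paste(sg$node_ids[i], sg$node_ids[j], sep = "|")
      k2 <- paste(sg$node_ids[j], sg$node_ids[i], sep = "|")
      if (k1 %in% names(wm)) expected <- c(expected, k1)
      if (k2 %in% names(wm)) expected <- c(expected, k2)
    }
    got <- paste(sg$edges$a, sg$edges$b, sep = "|")
    expect_setequal(got, expected)
  }
})

test_that("inference subgraphs cover every collected neighbour", {
  edges <- data.frame(a = "tf1", b = paste0("n", 1:250))
  net <- net_from_edges(edges, tfs = "tf1")
  sgs <- enumerate_inference_subgraphs(net, "tf1", size = 100L)
  expect_equal(length(sgs), ceiling(250 / 99))
  expect_true(all(vapply(sgs, function(s) s$node_ids[1L] == "tf1",
                         logical(1))))
  covered <- unique(unlist(lapply(sgs, function(s) s$node_ids[-1L])))
  nb <- collect_neighborhood(net, "tf1", target = 99L)
  expect_setequal(covered, nb$neighbors)
  # small neighbourhood: a single subgraph
  edges2 <- data.frame(a = "tf1", b = paste0("n", 1:10))
  net2 <- net_from_edges(edges2, tfs = "tf1")
  sgs2 <- enumerate_inference_subgraphs(net2, "tf1", size = 100L)
  expect_equal(length(sgs2), 1L)
  expect_equal(length(sgs2[[1]]$node_ids), 11L)
  expect_equal(length(enumerate_inference_subgraphs(net2, character())), 0L)
})

test_that("inference coverage holds on random graphs and is deterministic", {
  for (s in 1:50) {
    net <- random_network(30, p_edge = 0.12, seed = 200 + s, n_tfs = 3L)
    tfs <- net$gene_ids[net$is_tf]
    sgs <- enumerate_inference_subgraphs(net, tfs, size = 10L)
    for (tf in tfs) {
      nb <- collect_neighborhood(net, tf, target = 9L)
      covered <- as.character(unique(unlist(lapply(
        Filter(function(x) x$anchor == tf, sgs),
        function(x) setdiff(x$node_ids, tf)))))
      expect_setequal(covered, nb$neighbors)
    }
    sgs2 <- enumerate_inference_subgraphs(net, tfs, size = 10L)
    expect_identical(lapply(sgs, `[[`, "node_ids"),
                     lapply(sgs2, `[[`, "node_ids"))
  }
})
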
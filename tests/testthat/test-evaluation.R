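test_that("the clean pool excludes positives, negatives and self-pairs", {
  genes <- c("a", "b", "c", "d")
  pos <- data.frame(regulator = c("a", "b"), target = c("b", "c"))
  neg <- "c|d"
  pool <- build_clean_pool(genes, pos, neg)
  expect_length(pool, 4 * 3 - 3)
  expect_length(intersect(pool, c("a|b", "b|c", "c|d")), 0L)
  expect_false(any(pool %in% paste(genes, genes, sep = "|")))
  expect_error(build_clean_pool("a", character()), "empty")
})

test_that("AUROC equals exhaustive Mann-Whitney pair counting", {
  set.seed(15)
  for (r in 1:10) {
    s <- round(runif(12), 2) # ties likely
    y <- rbinom(12, 1, 0.4)
    if (sum(y) == 0 || sum(y) == 12) next
    pos <- s[y == 1]; neg <- s[y == 0]
    wins <- 0
    for (p in pos) for (q in neg)
      wins <- wins + (p > q) + 0.5 * (p == q)
    expect_equal(auroc(s, y), wins / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
  expect_equal(auroc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
})

test_that("AUPRC is 1 for a perfect ranking and penalises misranking", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_lt(auprc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 1)
  # brute-force check on a small ranking without ties
  s <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  y <- c(1, 0, 1, 0, 0)
  # precision at each recalled positive: 1/1 and 2/3
  expect_equal(auprc(s, y), mean(c(1, 2 / 3)), tolerance = 1e-12)
})

test_that("sampled metrics separate a perfect scorer and match iteration count", {
  genes <- paste0("g", 1:12)
  pos <- paste0("g1|", paste0("g", 2:5))
  pool <- build_clean_pool(genes, pos)
  scores <- stats::setNames(rep(1, length(pos)), pos)
  rep1 <- sampled_metrics(scores, pos, pool, iterations = 25L, seed = 4L)
  expect_equal(nrow(rep1$iterations), 25L)
  s <- rep1$summary
  expect_equal(s$mean[s$metric == "auroc"], 1)
  expect_equal(s$sd[s$metric == "auroc"], 0)
  expect_error(sampled_metrics(scores, pos, pool[1:2], 5L), "smaller")
  # fixed seed reproduces the full report exactly
  rep2 <- sampled_metrics(scores, pos, pool, iterations = 25L, seed = 4L)
  expect_identical(rep1, rep2)
})

test_that("random scores give sampled AUROC near one half", {
  set.seed(16)
  genes <- paste0("g", 1:30)
  all_pairs <- build_clean_pool(genes, character())
  pos <- sample(all_pairs, 40)
  pool <- setdiff(all_pairs, pos)
  scores <- stats::setNames(runif(length(all_pairs)), all_pairs)
  rep <- sampled_metrics(scores, pos, pool, iterations = 100L, seed = 8L)
  s <- rep$summary
  m <- s$mean[s$metric == "auroc"]
  se <- s$sd[s$metric == "auroc"] / sqrt(100)
  # mean within 3 standard errors of chance, allowing for the shared
  # positive set (its own sampling noise is of order 1/sqrt(n_pos))
  expect_lt(abs(m - 0.5), max(3 * se, 3 * 0.5 / sqrt(40)))
})

test_that("full-matrix metrics rank over the entire pool", {
  genes <- paste0("g", 1:10)
  pos <- c("g1|g2", "g1|g3", "g2|g4")
  pool <- build_clean_pool(genes, pos)
  perfect <- stats::setNames(rep(1, 3), pos)
  fm <- full_matrix_metrics(perfect, pos, pool)
  expect_equal(fm$auroc, 1)
  expect_equal(fm$auprc, 1)
  # all scores equal: midrank convention gives 0.5
  flat <- stats::setNames(rep(0.7, length(c(pos, pool))), c(pos, pool))
  expect_equal(full_matrix_metrics(flat, pos, pool)$auroc, 0.5)
  # hand-set scores against exhaustive pair counting
  set.seed(17)
  scr <- stats::setNames(round(runif(length(pool)), 1), pool)
  scr_pos <- stats::setNames(round(runif(3), 1), pos)
  fm2 <- full_matrix_metrics(c(scr_pos, scr), pos, pool)
  wins <- 0
  for (p in scr_pos) for (q in scr)
    wins <- wins + (p > q) + 0.5 * (p == q)
  expect_equal(fm2$auroc, wins / (3 * length(pool)), tolerance = 1e-12)
})

test_that("AUROC agrees with pROC on random score vectors", {
  skip_if_not_installed("pROC")
  set.seed(22)
  for (r in 1:5) {
    s <- runif(40)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(s, y), ref, tolerance = 1e-10)
  }
})

test_that("early precision and EPR match the worked example", {
  keys <- paste0("p", 1:10)
  scores <- stats::setNames(seq(1, 0.1, length.out = 10), keys)
  gt <- keys[c(1, 4)] # positives at ranks 1 and 4
  ep <- early_precision(scores, gt, cutoffs = 4L)
  expect_equal(unname(ep$ep["EP@4"]), 0.5)
  expect_equal(ep$density, 0.2)
  expect_equal(ep$epr, 2.5) # EP@2 = 0.5 over density 0.2
  # all positives ranked first
  ep2 <- early_precision(scores, keys[1:3], cutoffs = 3L)
  expect_equal(unname(ep2$ep["EP@3"]), 1)
  expect_error(early_precision(scores, gt, cutoffs = 99L), "cutoff")
})

test_that("a random ranking has expected EPR near one", {
  set.seed(18)
  keys <- paste0("p", 1:100)
  gt <- sample(keys, 20)
  eprs <- replicate(200, {
    early_precision(stats::setNames(runif(100), keys), gt)$epr
  })
  expect_lt(abs(mean(eprs) - 1), 0.1)
})

test_that("sampled AUROC converges to the full-matrix value", {
  set.seed(19)
  genes <- paste0("g", 1:15)
  allp <- build_clean_pool(genes, character())
  pos <- sample(allp, 12)
  pool <- setdiff(allp, pos)
  scores <- stats::setNames(runif(length(allp))^2, allp)
  scores[pos] <- pmin(1, scores[pos] + runif(12, 0, 0.5))
  full <- full_matrix_metrics(scores, pos, pool)$auroc
  rep <- sampled_metrics(scores, pos, pool, iterations = 2000L, seed = 3L)
  s <- rep$summary
  expect_equal(s$mean[s$metric == "auroc"], full, tolerance = 0.02)
})

test_that("unscored pairs count as zero (the model abstained)", {
  pos <- c("a|b", "a|c")
  pool <- c("b|a", "c|a", "b|c", "c|b")
  scores <- stats::setNames(0.9, "a|b") # a|c unscored
  fm <- full_matrix_metrics(scores, pos, pool)
  # a|b beats all 4 negatives; a|c ties the 4 zero-scored negatives
  expect_equal(fm$auroc, (4 + 4 * 0.5) / 8, tolerance = 1e-12)
})
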
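# deterministic 6-gene x 4-cell layer with distinct values per cell
scoring_cm <- function() {
  set.seed(21)
  v <- matrix(sample(1:200, 24), nrow = 6)
  cm <- make_cm(v)
  cm
}

test_that("average score: identity, cancellation, location invariance", {
  cm <- scoring_cm()
  x <- as.matrix(cm$lognorm)
  z <- t(scale(t(x)))
  sv <- score_average(cm, Signature(up = "g01"))
  expect_equal(unname(sv$raw), unname(z["g01", ]))

  # up and down contributions with equal means cancel
  svu <- score_average(cm, Signature(up = c("g01", "g02")))
  svd <- score_average(cm, Signature(up = c("g03"), down = c("g01", "g02")))
  expect_equal(svd$raw + svu$raw, score_average(cm, Signature(up = "g03"))$raw)

  # adding a constant to every entry leaves z-based scores unchanged
  cm2 <- cm; cm2$lognorm <- cm$lognorm + 5
  expect_equal(score_average(cm2, Signature(up = c("g01", "g04")))$raw,
               score_average(cm, Signature(up = c("g01", "g04")))$raw)

  expect_error(suppressWarnings(score_average(cm, Signature(up = "absent"))),
               "no signature genes")
  expect_warning(score_average(cm, Signature(up = c("g01", "absent"))),
                 "dropped")
})

test_that("rank-recovery AUC score: perfect enrichment and tie handling", {
  set.seed(3)
  G <- 40
  v <- matrix(stats::rnorm(G * 3), nrow = G)
  # cell 1: make genes g01..g04 the top-expressed
  v[1:4, 1] <- 100 + 1:4
  cm <- make_cm(v)
  up <- c("g01", "g02", "g03", "g04")
  sv <- score_rank_auc(cm, Signature(up = up), top_frac = 0.25)
  expect_equal(unname(sv$raw[1]), 1)

  # independent oracle: integrate the recovery curve directly
  oracle_cell <- function(vals, up_idx, top_frac) {
    G <- length(vals)
    top_n <- ceiling(top_frac * G)
    rdesc <- G + 1 - rank(vals)
    hits <- vapply(seq_len(top_n), function(t) sum(rdesc[up_idx] <= t),
                   numeric(1))
    sum(hits) / sum(pmin(seq_len(top_n), length(up_idx)))
  }
  for (cell in 1:3)
    expect_equal(unname(sv$raw[cell]),
                 oracle_cell(v[, cell], 1:4, 0.25), tolerance = 1e-12)

  # all-equal expression: average ranks put every gene at (G+1)/2
  cm0 <- make_cm(matrix(1, nrow = 10, ncol = 2))
  sv0 <- score_rank_auc(cm0, Signature(up = c("g01", "g02")), top_frac = 0.5)
  expect_equal(unname(sv0$raw),
               rep(oracle_cell(rep(1, 10), 1:2, 0.5), 2))
})

test_that("capped U score: extremes and monotonicity", {
  G <- 30
  v <- matrix(0, nrow = G, ncol = 2)
  v[1:3, 1] <- c(9, 8, 7)          # best case in cell 1: up genes rank 1..3
  v[10:12, 2] <- c(9, 8, 7)        # up genes buried below the cap elsewhere
  cm <- make_cm(v)
  up <- c("g01", "g02", "g03")
  sv <- score_u(cm, Signature(up = up), rank_cap = 10)
  expect_equal(unname(sv$raw[1]), 1)

  # worst case: all up genes at/below the cap ceiling
  v2 <- matrix(0, nrow = G, ncol = 1)
  v2[10:15, 1] <- 1:6              # push other genes up; up genes tie at bottom
  cm2 <- make_cm(v2)
  sv2 <- score_u(cm2, Signature(up = up), rank_cap = 10)
  expect_equal(unname(sv2$raw[1]), 0)

  # improving a signature gene's rank never decreases the score
  set.seed(9)
  base <- stats::rnorm(G)
  prev <- -Inf
  for (val in seq(min(base) - 1, max(base) + 1, length.out = 8)) {
    w <- base; w[1] <- val
    cmw <- make_cm(matrix(w, ncol = 1))
    s <- score_u(cmw, Signature(up = c("g01", "g05")), rank_cap = 15)$raw
    expect_gte(s + 1e-12, prev)
    prev <- s
  }
})

test_that("centered rank-mean score: limits, null expectation, reversal", {
  G <- 50
  v <- matrix(stats::rnorm(G), ncol = 1)
  v[1:5] <- 100 + 1:5              # extreme top
  cm <- make_cm(matrix(v, ncol = 1))
  sv <- score_rank_mean(cm, Signature(up = sprintf("g%02d", 1:5)))
  expect_equal(unname(sv$raw), 0.5 - 5 / (2 * G), tolerance = 1e-12)

  # random gene sets have expectation 0 (exact average over all genes)
  all_single <- vapply(sprintf("g%02d", 1:G), function(g)
    unname(score_rank_mean(cm, Signature(up = g))$raw), numeric(1))
  expect_equal(mean(all_single), 0, tolerance = 1e-12)

  # reversing the ranking negates the centered score
  cmr <- cm; cmr$lognorm <- -cm$lognorm
  svr <- score_rank_mean(cmr, Signature(up = sprintf("g%02d", 1:5)))
  expect_equal(unname(svr$raw), -unname(sv$raw), tolerance = 1e-12)
})

test_that("score scaling stores and applies training statistics", {
  sv <- trtkit:::score_vector(c(a = 1, b = 2, c = 3), "average")
  expect_equal(scale_scores(sv, 0, 1)$scaled, sv$raw)
  expect_equal(unname(scale_scores(sv, 1, 0.5)$scaled[["b"]]), 2)
  scaled <- scale_scores(sv, mean(sv$raw), stats::sd(sv$raw))$scaled
  expect_equal(mean(scaled), 0); expect_equal(stats::sd(scaled), 1)
  expect_error(scale_scores(sv, 0, 0), "positive")
})

test_that("clone aggregation takes the maximum over member cells", {
  sv <- trtkit:::score_vector(c(c1 = 0.2, c2 = 0.9, c3 = 0.4, c4 = 0.7),
                              "average")
  ct <- CloneTable(data.frame(clone_id = c("A", "B"), patient = "P1"))
  agg <- aggregate_clone_scores(sv, c("A", "A", "A", "B"), ct)
  expect_equal(unname(agg$raw), c(0.9, 0.7))
  # adding a cell can never lower a clone's score
  sv2 <- trtkit:::score_vector(c(sv$raw, c5 = -1), "average")
  agg2 <- aggregate_clone_scores(sv2, c("A", "A", "A", "B", "A"), ct)
  expect_gte(agg2$raw[["A"]], agg$raw[["A"]])
  expect_error(aggregate_clone_scores(sv, c("A", "A", "A", "X"), ct),
               "without scored cells")
})

test_that("threshold fitting maximizes training accuracy over midpoints", {
  tm <- fit_threshold(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(tm$threshold, 0.5)
  expect_equal(tm$train_accuracy, 1)
  tm2 <- fit_threshold(c(0.1, 0.8, 0.2, 0.9), c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(tm2$threshold, 0.5)
  # overlapping scores: equals the exhaustive-midpoint oracle
  set.seed(14)
  for (i in 1:50) {
    s <- round(stats::rnorm(12), 2)
    l <- stats::runif(12) < 0.5
    if (!any(l) || all(l) || length(unique(s)) < 2) next
    got <- fit_threshold(s, l)
    ora <- oracle_threshold(s, l)
    expect_equal(got$train_accuracy, ora$train_accuracy)
    expect_true(mean((s >= got$threshold) == l) == ora$train_accuracy)
  }
  expect_error(fit_threshold(c(1, 2), c(TRUE, TRUE)), "non-empty")
  # boundary counts as reactive
  expect_true(apply_threshold(tm, 0.5))
})

test_that("cached scoring matches the public scoring functions", {
  sim <- shared_cohort()
  ct <- sim$ct
  cache <- build_cache(sim$cm, ct, with_ranks = TRUE)
  sig <- Signature(up = sim$truth$up_genes[1:10],
                   down = sim$truth$down_genes[1:5])
  for (m in c("average", "rank_auc", "u_score", "rank_mean")) {
    pub <- switch(m,
                  average = score_average(sim$cm, sig),
                  rank_auc = score_rank_auc(sim$cm, sig),
                  u_score = score_u(sim$cm, sig),
                  rank_mean = score_rank_mean(sim$cm, sig))
    expect_equal(trtkit:::score_cells_cached(cache, sig, m), pub$raw,
                 tolerance = 1e-12, info = m)
  }
})

test_that("scores are invariant to gene and cell order", {
  cm <- scoring_cm()
  sig <- Signature(up = c("g02", "g05"), down = "g03")
  perm_g <- sample(nrow(cm$counts)); perm_c <- sample(ncol(cm$counts))
  cmp <- make_cm(as.matrix(cm$counts)[perm_g, perm_c])
  rownames(cmp$counts) <- rownames(cm$counts)[perm_g]
  colnames(cmp$counts) <- colnames(cm$counts)[perm_c]
  cmp$lognorm <- cmp$counts
  cmp$cell_meta$barcode <- colnames(cmp$counts)
  for (f in list(score_average, score_rank_auc, score_u, score_rank_mean)) {
    a <- f(cm, sig)$raw
    b <- f(cmp, sig)$raw
    expect_equal(b[names(a)], a, tolerance = 1e-12)
  }
})
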
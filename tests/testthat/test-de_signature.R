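make_labeled_cells <- function(values, labels) {
  cm <- make_cm(values)
  list(cm = cm, labels = labels)
}

test_that("single-cell rank test: degenerate, exact and symmetric cases", {
  # gene identical in all cells -> no separation, P = 1
  v <- rbind(rep(2, 6), c(1, 2, 3, 10, 11, 12))
  fx <- make_labeled_cells(v, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  de <- wilcoxon_de(fx$cm, fx$labels)
  expect_equal(de$p[1], 1)
  # complete separation, n1 = n2 = 3, no ties: exact two-sided P = 2/20
  expect_equal(de$p[2], 0.1, tolerance = 1e-12)
  # swapping group labels negates logFC, P unchanged
  de2 <- wilcoxon_de(fx$cm, !fx$labels)
  expect_equal(de2$p, de$p)
  expect_equal(de2$logFC, -de$logFC)
})

test_that("single-cell rank test matches wilcox.test across random data", {
  set.seed(42)
  for (rep in 1:5) {
    n1 <- sample(9:15, 1); n2 <- sample(9:15, 1)
    v <- matrix(sample(0:4, 20 * (n1 + n2), replace = TRUE), nrow = 20)
    labels <- rep(c(TRUE, FALSE), c(n1, n2))
    fx <- make_labeled_cells(v, labels)
    de <- wilcoxon_de(fx$cm, fx$labels)
    ref <- apply(v, 1, function(row)
      suppressWarnings(stats::wilcox.test(row[labels], row[!labels],
                                          exact = FALSE, correct = TRUE)$p.value))
    expect_equal(de$p, unname(ref), tolerance = 1e-10)
  }
})

simulate_null_profiles <- function(n_genes, n1 = 20, n2 = 20, seed = 1) {
  set.seed(seed)
  mu <- stats::runif(n_genes, 0.1, 2)
  sd <- 0.1 + 0.2 * mu
  x <- matrix(stats::rnorm(n_genes * (n1 + n2), mean = mu, sd = sd),
              nrow = n_genes)
  rownames(x) <- sprintf("g%04d", seq_len(n_genes))
  list(x = x, labels = rep(c(TRUE, FALSE), c(n1, n2)))
}

test_that("quasi-likelihood F analogue is calibrated and powered", {
  nul <- simulate_null_profiles(2000, seed = 8)
  de <- ql_f_de(nul$x, nul$labels)
  t1e <- mean(de$p < 0.05)
  expect_gte(t1e, 0.03); expect_lte(t1e, 0.07)

  # a gene shifted by 5 baseline SDs must be found
  x <- nul$x
  x[1, nul$labels] <- x[1, nul$labels] + 5 * stats::sd(x[1, !nul$labels])
  de2 <- ql_f_de(x, nul$labels)
  expect_lt(de2$adj_p[de2$gene == "g0001"], 0.05)

  # duplicating every clone profile leaves logFC unchanged
  de3 <- ql_f_de(cbind(nul$x, nul$x), rep(nul$labels, 2))
  expect_equal(de3$logFC, de$logFC)

  expect_error(ql_f_de(nul$x[, 1:3], c(TRUE, FALSE, FALSE)), "2 clones")
})

test_that("moderated t analogue is calibrated and nests the plain t test", {
  nul <- simulate_null_profiles(2000, seed = 12)
  de <- moderated_t_de(nul$x, nul$labels)
  t1e <- mean(de$p < 0.05)
  expect_gte(t1e, 0.03); expect_lte(t1e, 0.07)

  # prior weight 0 reduces to the ordinary equal-variance two-sample t
  de0 <- moderated_t_de(nul$x[1:50, ], nul$labels, prior_df = 0)
  ref <- apply(nul$x[1:50, ], 1, function(row)
    stats::t.test(row[nul$labels], row[!nul$labels], var.equal = TRUE)$p.value)
  expect_equal(de0$p, unname(ref), tolerance = 1e-10)

  # shrinkage: the posterior variance lies between raw and trend values
  st <- trtkit:::pseudobulk_group_stats(nul$x, nul$labels)
  sq <- trtkit:::squeeze_variances(st$s2, st$df, st$amean)
  expect_true(is.finite(sq$prior_df) && sq$prior_df > 0)
  lo <- pmin(st$s2, sq$s2_prior); hi <- pmax(st$s2, sq$s2_prior)
  expect_true(all(sq$s2_post >= lo - 1e-12 & sq$s2_post <= hi + 1e-12))
})

test_that("variance squeezing agrees with an established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  nul <- simulate_null_profiles(1000, seed = 33)
  st <- trtkit:::pseudobulk_group_stats(nul$x, nul$labels)
  sq <- trtkit:::squeeze_variances(st$s2, st$df, st$amean)
  ref <- limma::squeezeVar(st$s2, df = st$df, covariate = st$amean)
  expect_gt(stats::cor(sq$s2_post, ref$var.post), 0.95)
  expect_equal(log(sq$prior_df), log(ref$df.prior), tolerance = 0.5)
})

test_that("the pseudo-bulk engines agree on logFC sign and direction", {
  sim <- shared_cohort()
  prof <- pseudobulk_by_clone(sim$cm, sim$ct)
  lab_clone <- sim$ct$label == "tumor_reactive"
  d1 <- ql_f_de(prof, lab_clone)
  d2 <- moderated_t_de(prof, lab_clone)
  expect_equal(sign(d1$logFC), sign(d2$logFC))
  # and both point the planted genes the right way
  expect_true(all(d1$logFC[d1$gene %in% sim$truth$up_genes] > 0))
  expect_true(all(d1$logFC[d1$gene %in% sim$truth$down_genes] < 0))
})

test_that("signature derivation honors criterion, side, budget and ties", {
  set.seed(4)
  de <- trtkit:::de_result(gene = sprintf("g%03d", 1:200),
                           logFC = c(stats::rnorm(120, 1), stats::rnorm(80, -1)),
                           stat = stats::rnorm(200),
                           p = stats::runif(200), method = "test")
  sig <- derive_signature(de, "p_value", length = 10, side = "up")
  expect_length(sig$up, 10)
  expect_true(all(de$logFC[match(sig$up, de$gene)] > 0))
  expect_length(sig$down, 0)

  both <- derive_signature(de, "p_value", length = 90, side = "both")
  expect_equal(length(both$up) + length(both$down), 90)
  expect_true(length(both$down) > 0)

  # ties on P broken by |logFC| descending, then gene id
  de2 <- trtkit:::de_result(gene = c("gb", "ga", "gc"),
                            logFC = c(1, 2, 2), stat = 1:3,
                            p = c(0.5, 0.5, 0.5), method = "test")
  sig2 <- derive_signature(de2, "p_value", length = 2, side = "up")
  expect_equal(sig2$up, c("ga", "gc"))

  expect_warning(derive_signature(de2, "p_value", length = 10, side = "up"),
                 "available")
})

test_that("BH adjustment is monotone in raw P order", {
  set.seed(6)
  de <- ql_f_de(simulate_null_profiles(500, seed = 2)$x,
                rep(c(TRUE, FALSE), c(20, 20)))
  o <- order(de$p)
  expect_true(all(diff(de$adj_p[o]) >= -1e-15))
  expect_true(all(de$adj_p >= de$p - 1e-15))
})

test_that("additional DE engines can be registered and used", {
  register_de_method("plain_t", function(profiles, labels, adjust = "BH")
    moderated_t_de(profiles, labels, adjust, prior_df = 0),
    kind = "pseudobulk")
  expect_true("plain_t" %in% de_methods()$name)
  eng <- trtkit:::get_de_method("plain_t")
  nul <- simulate_null_profiles(50, seed = 3)
  expect_s3_class(eng$fun(nul$x, nul$labels), "DeResult")
})
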
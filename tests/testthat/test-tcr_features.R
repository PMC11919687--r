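test_that("CDR3 featurization: mask semantics and linearity", {
  tab <- atchley_factors()
  # homopolymer: descriptor means equal the residue's table row
  f <- featurize_cdr3("AAAAAAAA")
  expect_equal(unname(f[1:5]), unname(as.numeric(tab["A", ])))
  expect_equal(unname(f[["len"]]), 3)   # 8 residues - 3 head - 2 tail
  expect_identical(featurize_cdr3("CASSLGTDTQYF"), featurize_cdr3("CASSLGTDTQYF"))
  # single substitution shifts the mean by (row_new - row_old)/n_selected
  s1 <- "CASSLGTDTQYF"; s2 <- "CASSKGTDTQYF"   # position 5: L -> K (masked in)
  d <- featurize_cdr3(s2)[1:5] - featurize_cdr3(s1)[1:5]
  n_sel <- nchar(s1) - 5
  expect_equal(unname(d),
               unname(as.numeric(tab["K", ] - tab["L", ])) / n_sel,
               tolerance = 1e-12)
  expect_error(featurize_cdr3("CAXSS"), "invalid amino acid")
  expect_warning(featurize_cdr3("CASS"), "shorter than mask")
})

test_that("property tables round-trip through TSV", {
  tab <- atchley_factors()
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(cbind(aa = rownames(tab), tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  back <- read_property_table(path)
  expect_equal(as.matrix(back), as.matrix(tab))
  bad <- tab[-1, ]
  utils::write.table(cbind(aa = rownames(bad), bad), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_property_table(path), "20 canonical")
})

test_that("avidity classifier recovers a planted physicochemical rule", {
  set.seed(61)
  seqs <- simulate_cdr3_families(30, 8, mutations = 4, seed = 3)$cdr3
  feat1 <- vapply(seqs, function(s) featurize_cdr3(s)[["f1"]], numeric(1))
  labels <- ifelse(feat1 > stats::median(feat1), "high", "low")
  train <- seq_along(seqs) %% 2 == 0
  model <- fit_avidity_model(seqs[train], labels[train])
  ct <- CloneTable(data.frame(clone_id = sprintf("c%03d", which(!train)),
                              patient = "P1", cdr3b = seqs[!train]))
  pred <- predict_avidity(model, ct)
  expect_gt(mean(pred$avidity_call == labels[!train]), 0.9)

  # zero-signal labels: held-out accuracy near chance
  set.seed(62)
  rand_labels <- sample(labels)
  m0 <- fit_avidity_model(seqs[train], rand_labels[train])
  p0 <- predict_avidity(m0, ct)
  expect_lt(mean(p0$avidity_call == rand_labels[!train]), 0.65)
  expect_gt(mean(p0$avidity_call == rand_labels[!train]), 0.35)

  # missing beta chain -> unknown, excluded downstream
  ct2 <- CloneTable(data.frame(clone_id = c("a", "b"), patient = "P1",
                               cdr3b = c("CASSLGTDTQYF", NA)))
  p2 <- predict_avidity(model, ct2)
  expect_equal(p2$avidity_call[2], "unknown")
  expect_error(fit_avidity_model(seqs[1:4], rep("high", 4)), "both")
})

test_that("TCR distance is a symmetric metric using both chains", {
  a <- list(cdr3a = "CAVRDSNYQLIW", cdr3b = "CASSLGTDTQYF")
  b <- list(cdr3a = "CAVRDGNYQLIW", cdr3b = "CASSLGQDTQYF")
  expect_equal(tcr_distance(a, a), 0)
  expect_equal(tcr_distance(a, b), tcr_distance(b, a))
  # missing alpha: beta-only with full weight
  a0 <- list(cdr3a = NA, cdr3b = a$cdr3b)
  b0 <- list(cdr3a = NA, cdr3b = b$cdr3b)
  fa <- featurize_cdr3(a$cdr3b); fb <- featurize_cdr3(b$cdr3b)
  expect_equal(tcr_distance(a0, b0), sqrt(sum((fa - fb)^2)))
  # triangle inequality on random triples
  set.seed(13)
  seqs <- simulate_cdr3_families(9, 1, mutations = 0, seed = 4)$cdr3
  tcrs <- lapply(seq(1, 9, by = 3), function(i)
    list(cdr3a = seqs[i], cdr3b = seqs[i + 1]))
  d12 <- tcr_distance(tcrs[[1]], tcrs[[2]])
  d13 <- tcr_distance(tcrs[[1]], tcrs[[3]])
  d23 <- tcr_distance(tcrs[[2]], tcrs[[3]])
  expect_lte(d12, d13 + d23 + 1e-12)
  expect_lte(d13, d12 + d23 + 1e-12)
})

test_that("distance matrices are symmetric, zero-diagonal, order-invariant", {
  ct <- random_clone_table(n = 6, seed = 9)
  D <- distance_matrix(ct)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 6))
  expect_equal(D["cl002", "cl005"],
               tcr_distance(ct[2, ], ct[5, ]))
  perm <- sample(6)
  ctp <- ct[perm, ]; class(ctp) <- class(ct)
  Dp <- distance_matrix(ctp)
  expect_equal(Dp[rownames(D), colnames(D)], D)
  # identical clones: all-zero matrix
  ct2 <- CloneTable(data.frame(clone_id = c("a", "b"), patient = "P1",
                               cdr3b = "CASSLGTDTQYF"))
  expect_true(all(distance_matrix(ct2) == 0))
})

test_that("UPGMA reproduces the hand-computed merge order", {
  D <- matrix(c(0, 2, 6,
                2, 0, 6,
                6, 6, 0), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  h <- upgma(D)
  expect_equal(h$height, c(2, 6))
  expect_equal(length(h$height), 2)   # n - 1 merges
  cl <- cut_clusters(h, 2)
  expect_equal(cl[["A"]], cl[["B"]])
  expect_false(cl[["A"]] == cl[["C"]])
  expect_equal(unname(cut_clusters(h, 1)), rep(1, 3))
  expect_equal(sort(unique(unname(cut_clusters(h, 3)))), 1:3)
  expect_error(cut_clusters(h, 4), "between")
  Dn <- D; Dn[1, 2] <- NaN
  expect_error(upgma(Dn), "non-finite")
})

test_that("UPGMA equals the brute-force average-linkage oracle", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    p <- matrix(stats::rnorm(n * 3), nrow = n)
    D <- as.matrix(stats::dist(p))
    h <- upgma(D)
    o <- oracle_upgma(D)
    expect_equal(h$height, o$height, tolerance = 1e-9)
    expect_equal(t(apply(h$merge, 1, sort)), o$merge, ignore_attr = TRUE)
    # ultrametric: merge heights non-decreasing
    expect_true(all(diff(h$height) >= -1e-12))
  }
})

test_that("planted CDR3 families are recovered by clustering", {
  fam <- simulate_cdr3_families(4, 6, mutations = 0, seed = 8)
  ct <- CloneTable(data.frame(clone_id = sprintf("c%02d", seq_len(nrow(fam))),
                              patient = "P1", cdr3b = fam$cdr3))
  D <- distance_matrix(ct)
  cl <- cut_clusters(upgma(D), 4)
  expect_equal(oracle_ari(cl, fam$family), 1)
  # with a modest mutation load, recovery stays essentially perfect
  fam2 <- simulate_cdr3_families(3, 8, mutations = 1, seed = 15)
  ct2 <- CloneTable(data.frame(clone_id = sprintf("d%02d", seq_len(nrow(fam2))),
                               patient = "P1", cdr3b = fam2$cdr3))
  cl2 <- cut_clusters(upgma(distance_matrix(ct2)), 3)
  expect_gte(oracle_ari(cl2, fam2$family), 0.8)
})
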
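# Shared fixtures and independent oracles, built in code at test time.

# small deterministic CellMatrix: `values` (genes x cells) become the counts
# when they are valid UMI counts, and always become the analysis (lognorm)
# layer, so fixtures can use arbitrary real values directly
make_cm <- function(values, patients = NULL, clones = NULL) {
  g <- nrow(values); n <- ncol(values)
  rownames(values) <- sprintf("g%02d", seq_len(g))
  colnames(values) <- sprintf("c%02d", seq_len(n))
  meta <- data.frame(barcode = colnames(values),
                     patient = patients %||% rep("P1", n),
                     clone_id = clones %||% rep(NA_character_, n))
  counts <- pmax(round(values), 0)
  cm <- CellMatrix(counts, meta)
  cm$lognorm <- Matrix::Matrix(values, sparse = FALSE,
                               dimnames = dimnames(values))
  cm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# memoised moderate-signal cohort shared across tests
.fixture_env <- new.env()
shared_cohort <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_cohort(
      sim_config(n_patients = 5, clones_per_patient = 20, n_genes = 400,
                 effect_size = 2, seed = 77))
  .fixture_env$sim
}

random_clone_table <- function(n = 8, seed = 1) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rand_cdr3 <- function(k) vapply(seq_len(k), function(i)
    paste(sample(aa, sample(10:16, 1), replace = TRUE), collapse = ""),
    character(1))
  CloneTable(data.frame(
    clone_id = sprintf("cl%03d", seq_len(n)),
    patient = sample(c("PA", "PB"), n, replace = TRUE),
    cdr3a = rand_cdr3(n), cdr3b = rand_cdr3(n),
    n_cells = sample(1:9, n, replace = TRUE),
    label = sample(c("tumor_reactive", "non_tumor_reactive", "unknown"),
                   n, replace = TRUE),
    trt_score = round(stats::rnorm(n), 3),
    trt_call = sample(c(TRUE, FALSE), n, replace = TRUE),
    avidity_call = sample(c("high", "low", "unknown"), n, replace = TRUE),
    frequency = NA_real_))
}

# ---- independent oracles -------------------------------------------------

# MCC as the Pearson correlation of the binary prediction/truth vectors
oracle_mcc <- function(pred, truth) {
  if (stats::sd(pred) == 0 || stats::sd(truth) == 0) return(0)
  stats::cor(as.numeric(pred), as.numeric(truth))
}

# AUC as the fraction of concordant positive-negative pairs (ties = 1/2)
oracle_auc <- function(scores, labels) {
  pos <- which(labels); neg <- which(!labels)
  s <- outer(scores[pos], scores[neg], function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(s)
}

# exhaustive-midpoint threshold search
oracle_threshold <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- (s[-1] + s[-length(s)]) / 2
  acc <- vapply(cand, function(tau) mean((scores >= tau) == labels), numeric(1))
  list(threshold = cand[which.max(acc)], train_accuracy = max(acc))
}

# literal UPGMA: maintain member lists, recompute the full average linkage
# between clusters at every step
oracle_upgma <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  ids <- -seq_len(n)                      # hclust convention: leaves negative
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    i <- best[2]; j <- best[3]
    merges[step, ] <- sort(c(ids[i], ids[j]))
    heights[step] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    ids[i] <- step
    clusters[[j]] <- NULL
    ids <- ids[-j]
  }
  list(merge = merges, height = heights)
}

# adjusted Rand index between two labelings
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
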
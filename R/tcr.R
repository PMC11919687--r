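#' Amino-acid physicochemical property table
#'
#' Default table: the five Atchley factors per residue (polarity/
#' accessibility, secondary-structure propensity, size, codon composition,
#' charge), the standard low-dimensional physicochemical embedding for CDR3
#' sequence comparison. Alternative tables (e.g. Kidera factors or a
#' solvent-exposure-weighted set) can be loaded from TSV with
#' [read_property_table()].
#'
#' @return data.frame with 20 rows (rownames = one-letter residues) and one
#'   column per descriptor.
#' @export
atchley_factors <- function() {
  tab <- matrix(c(
    -0.591, -1.302, -0.733,  1.570, -0.146,   # A
    -1.343,  0.465, -0.862, -1.020, -0.255,   # C
     1.050,  0.302, -3.656, -0.259, -3.242,   # D
     1.357, -1.453,  1.477,  0.113, -0.837,   # E
    -1.006, -0.590,  1.891, -0.397,  0.412,   # F
    -0.384,  1.652,  1.330,  1.045,  2.064,   # G
     0.336, -0.417, -1.673, -1.474, -0.078,   # H
    -1.239, -0.547,  2.131,  0.393,  0.816,   # I
     1.831, -0.561,  0.533, -0.277,  1.648,   # K
    -1.019, -0.987, -1.505,  1.266, -0.912,   # L
    -0.663, -1.524,  2.219, -1.005,  1.212,   # M
     0.945,  0.828,  1.299, -0.169,  0.933,   # N
     0.189,  2.081, -1.628,  0.421, -1.392,   # P
     0.931, -0.179, -3.005, -0.503, -1.853,   # Q
     1.538, -0.055,  1.502,  0.440,  2.897,   # R
    -0.228,  1.399, -4.760,  0.670, -2.647,   # S
    -0.032,  0.326,  2.213,  0.908,  1.313,   # T
    -1.337, -0.279, -0.544,  1.242, -1.262,   # V
    -0.595,  0.009,  0.672, -2.128, -0.184,   # W
     0.260,  0.830,  3.097, -0.838,  1.512),  # Y
    ncol = 5, byrow = TRUE,
    dimnames = list(AA_ALPHABET, paste0("f", 1:5)))
  as.data.frame(tab)
}

#' @rdname atchley_factors
#' @param path TSV with a residue column (`aa`) and numeric descriptor
#'   columns.
#' @export
read_property_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"aa" %in% names(df)) stop("property table needs an 'aa' column")
  rownames(df) <- df$aa
  df$aa <- NULL
  if (!setequal(rownames(df), AA_ALPHABET))
    stop("property table must cover the 20 canonical residues")
  if (any(!vapply(df, is.numeric, logical(1))) || any(!is.finite(as.matrix(df))))
    stop("property table values must be finite numerics")
  df[AA_ALPHABET, , drop = FALSE]
}

#' Featurize a CDR3 sequence
#'
#' The mask keeps the central, typically solvent-exposed loop residues
#' (default: drop the first 3 and last 2 positions, which are the conserved
#' anchors). The feature vector is the per-descriptor mean over the masked
#' residues, with the number of selected residues appended (`len`).
#' Sequences too short for the mask fall back to the full sequence with a
#' warning.
#'
#' @param seq CDR3 amino-acid string.
#' @param mask integer c(n_head, n_tail) positions to drop.
#' @param table property table (default [atchley_factors()]).
#' @return named numeric vector (descriptor means + `len`).
#' @export
featurize_cdr3 <- function(seq, mask = c(3, 2), table = atchley_factors()) {
  aa <- strsplit(seq, "")[[1]]
  if (any(!aa %in% AA_ALPHABET))
    stop("invalid amino acid in CDR3: ", seq)
  if (length(aa) > sum(mask) + 0) {
    sel <- aa[seq.int(mask[1] + 1, length(aa) - mask[2])]
  } else {
    warning("sequence shorter than mask, using full sequence: ", seq)
    sel <- aa
  }
  m <- colMeans(as.matrix(table[sel, , drop = FALSE]))
  c(m, len = length(sel))
}

featurize_many <- function(seqs, mask = c(3, 2), table = atchley_factors()) {
  t(vapply(seqs, featurize_cdr3, numeric(ncol(table) + 1),
           mask = mask, table = table))
}

#' Structural-avidity classifier on CDR3beta composition
#'
#' A regularized binary logistic model over the physicochemical descriptors
#' of the solvent-exposed CDR3beta residues, classifying TCRs as likely to
#' bind their pMHC with high or low structural avidity. This is a trainable
#' analogue of published k_off-based avidity predictors: the binary class is
#' modeled, not k_off itself, and the model must be trained on labeled data
#' (or the synthetic demo fit).
#'
#' @param cdr3b CDR3beta sequences.
#' @param labels `"high"`/`"low"` (or logical, TRUE = high).
#' @param mask,table as in [featurize_cdr3()].
#' @param alpha,lambda elastic-net settings for the logistic fit.
#' @param prob_threshold probability at or above which a TCR is called high
#'   (default 0.5; the boundary counts as high).
#' @return an `AvidityModel`.
#' @export
fit_avidity_model <- function(cdr3b, labels, mask = c(3, 2),
                              table = atchley_factors(), alpha = 0,
                              lambda = 0.01, prob_threshold = 0.5) {
  hi <- labels == "high" | labels == TRUE
  if (!any(hi) || all(hi)) stop("need both high and low labels")
  feats <- featurize_many(cdr3b, mask, table)
  mu <- colMeans(feats); sd <- apply(feats, 2, stats::sd)
  sd[sd == 0] <- 1
  z <- sweep(sweep(feats, 2, mu), 2, sd, "/")
  enet <- fit_elastic_net(z, hi, alpha = alpha, lambda = lambda)
  structure(list(enet = enet, mask = mask, table = table, mu = mu, sd = sd,
                 prob_threshold = prob_threshold),
            class = "AvidityModel")
}

#' Predict structural avidity for a clone table
#'
#' Clones lacking a CDR3beta sequence get `avidity_call = "unknown"` and are
#' excluded from downstream candidate selection.
#'
#' @param model an `AvidityModel`.
#' @param ct a [CloneTable()].
#' @return the CloneTable with `avidity_call` filled in.
#' @export
predict_avidity <- function(model, ct) {
  stopifnot(inherits(model, "AvidityModel"), inherits(ct, "CloneTable"))
  has_b <- !is.na(ct$cdr3b)
  ct$avidity_call <- "unknown"
  if (any(has_b)) {
    feats <- featurize_many(ct$cdr3b[has_b], model$mask, model$table)
    z <- sweep(sweep(feats, 2, model$mu), 2, model$sd, "/")
    p <- predict_lr(model$enet, z)
    ct$avidity_call[has_b] <- ifelse(p >= model$prob_threshold, "high", "low")
  }
  ct
}

#' Physicochemical TCR distance
#'
#' Euclidean distance between the concatenated alpha/beta CDR3 descriptor
#' vectors, chain-weighted. When either TCR lacks an alpha chain the beta
#' chain carries all the weight. Symmetric, zero on identical TCRs, and a
#' metric (it is a weighted Euclidean distance in descriptor space).
#'
#' @param tcrA,tcrB lists (or 1-row data.frames) with `cdr3b` and optional
#'   `cdr3a`.
#' @param table property table.
#' @param weights chain weights c(alpha, beta), renormalized to sum 1.
#' @param mask residue mask, see [featurize_cdr3()].
#' @return non-negative real.
#' @export
tcr_distance <- function(tcrA, tcrB, table = atchley_factors(),
                         weights = c(alpha = 0.5, beta = 0.5),
                         mask = c(3, 2)) {
  a_ok <- !is.null(tcrA$cdr3a) && !is.na(tcrA$cdr3a) &&
          !is.null(tcrB$cdr3a) && !is.na(tcrB$cdr3a)
  w <- if (a_ok) weights / sum(weights) else c(alpha = 0, beta = 1)
  db <- featurize_cdr3(tcrA$cdr3b, mask, table) -
        featurize_cdr3(tcrB$cdr3b, mask, table)
  d2 <- w[["beta"]] * sum(db^2)
  if (a_ok) {
    da <- featurize_cdr3(tcrA$cdr3a, mask, table) -
          featurize_cdr3(tcrB$cdr3a, mask, table)
    d2 <- d2 + w[["alpha"]] * sum(da^2)
  }
  sqrt(d2)
}

#' Pairwise TCR distance matrix
#'
#' @param ct a [CloneTable()] (>= 2 clones, all with cdr3b).
#' @inheritParams tcr_distance
#' @return symmetric matrix with zero diagonal, dimnames = clone ids.
#' @export
distance_matrix <- function(ct, table = atchley_factors(),
                            weights = c(alpha = 0.5, beta = 0.5),
                            mask = c(3, 2)) {
  stopifnot(inherits(ct, "CloneTable"), nrow(ct) >= 2)
  if (any(is.na(ct$cdr3b))) stop("all clones need a cdr3b for clustering")
  n <- nrow(ct)
  D <- matrix(0, n, n, dimnames = list(ct$clone_id, ct$clone_id))
  rows <- lapply(seq_len(n), function(i) ct[i, ])
  for (i in seq_len(n - 1))
    for (j in seq.int(i + 1, n)) {
      D[i, j] <- D[j, i] <- tcr_distance(rows[[i]], rows[[j]], table,
                                         weights, mask)
    }
  D
}

#' UPGMA dendrogram
#'
#' Average-linkage agglomerative clustering: at each step the closest pair
#' of clusters is merged and the inter-cluster distance is the size-weighted
#' mean of member pairwise distances, so merge heights are non-decreasing
#' (ultrametric).
#'
#' @param D symmetric distance matrix (no NaN).
#' @return an [stats::hclust] object (merge list, heights, labels).
#' @export
upgma <- function(D) {
  if (any(!is.finite(D))) stop("distance matrix contains non-finite values")
  if (!isSymmetric(unname(D))) stop("distance matrix must be symmetric")
  stats::hclust(stats::as.dist(D), method = "average")
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest merges.
#'
#' @param dendro an hclust object from [upgma()].
#' @param k number of clusters, 1 <= k <= leaves.
#' @return named integer cluster assignment.
#' @export
cut_clusters <- function(dendro, k) {
  n <- length(dendro$order)
  if (k < 1 || k > n) stop("k must be between 1 and the number of leaves")
  stats::cutree(dendro, k = k)
}

#' Export a dendrogram as Newick
#'
#' @param dendro an hclust object.
#' @param path output file.
#' @export
write_dendrogram_newick <- function(dendro, path) {
  ape::write.tree(ape::as.phylo(dendro), file = path)
  invisible(path)
}
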
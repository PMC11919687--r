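#' Signature scoring
#'
#' Four per-cell scoring schemes turn a [Signature()] into a scalar per cell:
#' `score_average` (mean of gene-wise z-scaled log-normalized expression,
#' up minus down), `score_rank_auc` (area under the recovery curve of
#' signature genes within the top fraction of the per-cell expression
#' ranking), `score_u` (capped Mann-Whitney U rank score), and
#' `score_rank_mean` (mean normalized expression rank, centered). Ties in
#' expression ranks use average ranks everywhere. Signature genes absent
#' from the matrix are dropped with a warning; if none remain this is an
#' error.
#'
#' @param cm a [CellMatrix()] with a lognorm layer.
#' @param sig a [Signature()].
#' @return a `ScoreVector`: list with `raw` (named per-cell scores),
#'   `scaled` (`NULL` until [scale_scores()]), `mu`, `sigma`, `method`,
#'   `level`.
#' @name signature_scores
NULL

score_vector <- function(raw, method, level = "cell") {
  structure(list(raw = raw, scaled = NULL, mu = NA_real_, sigma = NA_real_,
                 method = method, level = level),
            class = "ScoreVector")
}

#' @export
print.ScoreVector <- function(x, ...) {
  cat(sprintf("ScoreVector (%s, %s-level): %d scores%s\n", x$method, x$level,
              length(x$raw),
              if (is.null(x$scaled)) "" else
                sprintf(", scaled (mu=%.3g, sigma=%.3g)", x$mu, x$sigma)))
  invisible(x)
}

check_sig_genes <- function(cm, sig) {
  genes <- rownames(cm$lognorm)
  up <- intersect(sig$up, genes)
  down <- intersect(sig$down, genes)
  dropped <- length(sig$up) + length(sig$down) - length(up) - length(down)
  if (dropped > 0)
    warning(dropped, " signature gene(s) absent from the matrix, dropped")
  if (length(up) + length(down) == 0)
    stop("no signature genes present in the matrix")
  list(up = up, down = down)
}

lognorm_dense <- function(cm) {
  if (is.null(cm$lognorm)) stop("lognorm layer absent; call normalize_log()")
  as.matrix(cm$lognorm)
}

# per-cell ranks of gene expression, ascending (highest expression -> rank G),
# average ranks for ties
cell_ranks <- function(x) apply(x, 2, rank)

#' @rdname signature_scores
#' @export
score_average <- function(cm, sig) {
  x <- lognorm_dense(cm)
  gs <- check_sig_genes(cm, sig)
  mu <- rowMeans(x); sd <- apply(x, 1, stats::sd)
  sd[sd == 0] <- 1
  z <- (x - mu) / sd
  s <- colMeans(z[gs$up, , drop = FALSE])
  if (length(gs$down)) s <- s - colMeans(z[gs$down, , drop = FALSE])
  score_vector(s, "average")
}

rank_auc_one_side <- function(r, genes, top_n) {
  # recovery curve: at rank threshold t (1..top_n) count signature genes
  # with rank <= t; AUC = sum over thresholds, normalized by its maximum
  rg <- r[genes]
  # with average (possibly fractional) ranks, a gene with rank r contributes
  # to every integer threshold t >= r, i.e. top_n - ceiling(r) + 1 thresholds
  auc <- sum(pmax(top_n - ceiling(rg) + 1, 0))
  maxauc <- sum(pmin(seq_len(top_n), length(genes)))
  if (maxauc == 0) return(0)
  auc / maxauc
}

#' @rdname signature_scores
#' @param top_frac fraction of the ranking over which the recovery curve is
#'   integrated (default 0.05).
#' @export
score_rank_auc <- function(cm, sig, top_frac = 0.05) {
  stopifnot(top_frac > 0, top_frac <= 1)
  x <- lognorm_dense(cm)
  gs <- check_sig_genes(cm, sig)
  G <- nrow(x)
  top_n <- ceiling(top_frac * G)
  rk <- cell_ranks(x)           # ascending; convert to descending rank
  rk_desc <- G + 1 - rk
  s <- apply(rk_desc, 2, rank_auc_one_side, genes = gs$up, top_n = top_n)
  if (length(gs$down)) {
    s <- s - apply(G + 1 - rk_desc, 2, rank_auc_one_side,
                   genes = gs$down, top_n = top_n)
  }
  score_vector(s, "rank_auc")
}

u_score_one_side <- function(rdesc, genes, rank_cap) {
  rg <- pmin(rdesc[genes], rank_cap)
  n <- length(genes)
  U <- sum(rg) - n * (n + 1) / 2
  Umax <- n * rank_cap - n * (n + 1) / 2
  if (Umax == 0) return(1)
  1 - U / Umax
}

#' @rdname signature_scores
#' @param rank_cap ranks beyond this value are truncated (default 1500);
#'   a cell whose signature genes all sit at or beyond the cap scores 0.
#' @export
score_u <- function(cm, sig, rank_cap = 1500) {
  stopifnot(rank_cap >= 2)
  x <- lognorm_dense(cm)
  gs <- check_sig_genes(cm, sig)
  G <- nrow(x)
  rk_desc <- G + 1 - cell_ranks(x)
  s <- apply(rk_desc, 2, u_score_one_side, genes = gs$up,
             rank_cap = min(rank_cap, G))
  if (length(gs$down)) {
    s <- s - apply(G + 1 - rk_desc, 2, u_score_one_side, genes = gs$down,
                   rank_cap = min(rank_cap, G))
  }
  score_vector(s, "u_score")
}

#' @rdname signature_scores
#' @export
score_rank_mean <- function(cm, sig) {
  x <- lognorm_dense(cm)
  gs <- check_sig_genes(cm, sig)
  G <- nrow(x)
  rk <- cell_ranks(x)            # ascending: top expression -> rank G
  center <- (G + 1) / (2 * G)    # expectation of rank/G under random sets
  s <- colMeans(rk[gs$up, , drop = FALSE] / G) - center
  if (length(gs$down))
    s <- s - (colMeans(rk[gs$down, , drop = FALSE] / G) - center)
  score_vector(s, "rank_mean")
}

#' Scale scores by training statistics
#'
#' Scores are made comparable between training and testing data by an affine
#' transform with the mean and standard deviation of the *training* scores;
#' test data never re-estimates them.
#'
#' @param sv a `ScoreVector`.
#' @param mu_t,sigma_t training mean and standard deviation; `sigma_t` must
#'   be positive.
#' @return the ScoreVector with `scaled = (raw - mu_t)/sigma_t`.
#' @export
scale_scores <- function(sv, mu_t, sigma_t) {
  stopifnot(inherits(sv, "ScoreVector"))
  if (!is.finite(sigma_t) || sigma_t <= 0)
    stop("sigma_t must be positive (degenerate training scores)")
  sv$scaled <- (sv$raw - mu_t) / sigma_t
  sv$mu <- mu_t; sv$sigma <- sigma_t
  sv
}

#' Aggregate cell scores to clones
#'
#' The clone-wise score is the maximum score over the clone's member cells.
#'
#' @param sv a cell-level `ScoreVector` (raw, and scaled if present, named
#'   by barcode).
#' @param clone_ids per-cell clone ids aligned with the scores (NA cells are
#'   ignored).
#' @param ct a [CloneTable()] giving the output clone order; every clone must
#'   have at least one scored cell.
#' @return a clone-level `ScoreVector` named by clone_id.
#' @export
aggregate_clone_scores <- function(sv, clone_ids, ct) {
  stopifnot(inherits(sv, "ScoreVector"), inherits(ct, "CloneTable"))
  stopifnot(length(clone_ids) == length(sv$raw))
  keep <- !is.na(clone_ids)
  mx <- tapply(sv$raw[keep], clone_ids[keep], max)
  missing <- setdiff(ct$clone_id, names(mx))
  if (length(missing))
    stop("clones without scored cells: ", paste(missing, collapse = ", "))
  out <- score_vector(as.numeric(mx[ct$clone_id]), sv$method, level = "clone")
  names(out$raw) <- ct$clone_id
  if (!is.null(sv$scaled)) {
    out$mu <- sv$mu; out$sigma <- sv$sigma
    out$scaled <- (out$raw - out$mu) / out$sigma
  }
  out
}

#' Accuracy-maximizing score threshold
#'
#' Candidate thresholds are the midpoints between adjacent distinct sorted
#' training scores; the one maximizing training accuracy is kept (ties
#' broken toward the smallest threshold). Prediction uses `score >= tau` as
#' tumor-reactive, so the boundary counts as reactive.
#'
#' @param scores numeric training scores (on the scale later used for
#'   prediction).
#' @param labels training labels (`tumor_reactive`/logical TRUE = positive).
#' @return a `ThresholdModel`: list with `threshold` and `train_accuracy`.
#' @export
fit_threshold <- function(scores, labels) {
  pos <- group_split(labels)
  s <- sort(unique(scores))
  if (length(s) < 2) stop("need at least two distinct training scores")
  cand <- (s[-1] + s[-length(s)]) / 2
  acc <- vapply(cand, function(tau) mean((scores >= tau) == pos), numeric(1))
  best <- which(acc == max(acc))[1]   # candidates ascending -> smallest tau
  structure(list(threshold = cand[best], train_accuracy = acc[best]),
            class = "ThresholdModel")
}

#' Apply a threshold model
#'
#' @param tm a `ThresholdModel`.
#' @param scores numeric scores.
#' @return logical calls (`TRUE` = tumor-reactive).
#' @export
apply_threshold <- function(tm, scores) {
  stopifnot(inherits(tm, "ThresholdModel"))
  scores >= tm$threshold
}
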
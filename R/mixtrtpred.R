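#' Combinatorial TCR candidate selection
#'
#' The end-to-end selection of clinically relevant TCRs from a scored,
#' avidity-annotated clone table: (1) drop clones not predicted high
#' structural avidity; (2) drop clones not called tumor-reactive; (3) rank
#' the survivors by tumor-reactive score (ties: larger clone, then clone
#' id); (4) keep the top `top_n`; (5) cluster their TCRs by physicochemical
#' distance (UPGMA) and cut into `k` clusters; (6) keep the top-scoring
#' clone of each cluster. The panel is ordered by score.
#'
#' @param ct a [CloneTable()] with `trt_score`, `trt_call` and
#'   `avidity_call` present.
#' @param top_n clones entering the clustering step (default 20).
#' @param k number of TCR clusters = panel size (default 5; adapt to the
#'   clinical context).
#' @param table,weights,mask passed to [distance_matrix()].
#' @param seed recorded in the provenance block.
#' @return a `CandidatePanel`: data.frame (clone_id, patient, cdr3a, cdr3b,
#'   trt_score, cluster, frequency) with a `provenance` attribute
#'   (parameters and seed) and a `dendrogram` attribute (hclust).
#' @export
run_mixtrtpred <- function(ct, top_n = 20, k = 5, table = atchley_factors(),
                           weights = c(alpha = 0.5, beta = 0.5),
                           mask = c(3, 2), seed = NA_integer_) {
  stopifnot(inherits(ct, "CloneTable"))
  if (any(is.na(ct$trt_score)) || any(is.na(ct$trt_call)))
    stop("trt_score and trt_call must be present; run predict_trt() first")
  surv <- ct[ct$avidity_call == "high" & ct$trt_call, ]
  if (nrow(surv) < k)
    stop(sprintf(paste("only %d clones survive the avidity and reactivity",
                       "filters; choose k <= %d (the cluster count can be",
                       "adapted to the clinical context)"),
                 nrow(surv), nrow(surv)))
  ord <- order(-surv$trt_score,
               -ifelse(is.na(surv$n_cells), 0, surv$n_cells), surv$clone_id)
  surv <- surv[ord, ]
  top <- surv[seq_len(min(top_n, nrow(surv))), ]
  class(top) <- class(ct)
  D <- distance_matrix(top, table, weights, mask)
  if (all(D == 0))
    warning("all TCR distances are zero; clusters follow tie-broken merge order")
  dendro <- upgma(D)
  cl <- cut_clusters(dendro, k)
  top$cluster <- cl[top$clone_id]
  # argmax score per cluster; `top` is already score-ordered so the first
  # clone of each cluster is its top scorer
  panel <- top[!duplicated(top$cluster), ]
  panel <- panel[order(-panel$trt_score), c("clone_id", "patient", "cdr3a",
                                            "cdr3b", "trt_score", "cluster",
                                            "frequency")]
  rownames(panel) <- NULL
  attr(panel, "provenance") <- list(top_n = top_n, k = k,
                                    mask = mask, weights = weights,
                                    seed = seed, timestamp = NULL,
                                    n_input = nrow(ct),
                                    n_surviving = nrow(surv))
  attr(panel, "dendrogram") <- dendro
  class(panel) <- c("CandidatePanel", "data.frame")
  panel
}

#' @export
print.CandidatePanel <- function(x, ...) {
  pr <- attr(x, "provenance")
  cat(sprintf("CandidatePanel: %d TCR candidates (top_n=%d, k=%d, %d survivors of %d clones)\n",
              nrow(x), pr$top_n, pr$k, pr$n_surviving, pr$n_input))
  NextMethod()
}

#' Count clinically relevant clones per patient
#'
#' Clones passing both the tumor-reactivity and the high structural avidity
#' filters.
#'
#' @param ct a [CloneTable()] with `trt_call` and `avidity_call`.
#' @return data.frame (patient, n_relevant).
#' @export
count_clinically_relevant <- function(ct) {
  stopifnot(inherits(ct, "CloneTable"))
  pass <- !is.na(ct$trt_call) & ct$trt_call & ct$avidity_call == "high"
  counts <- tapply(pass, ct$patient, sum)
  data.frame(patient = names(counts), n_relevant = as.integer(counts),
             row.names = NULL)
}

#' Write a candidate panel as CSV
#'
#' @param panel a `CandidatePanel`.
#' @param path CSV path.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "CandidatePanel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}
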
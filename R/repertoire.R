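#' Repertoire richness
#'
#' Number of unique clones with positive abundance.
#'
#' @param abundances non-negative counts or frequencies, optionally named by
#'   clone id; at least one must be positive.
#' @return integer richness.
#' @export
richness <- function(abundances) {
  check_repertoire(abundances)
  sum(abundances > 0)
}

check_repertoire <- function(abundances) {
  if (!length(abundances) || all(abundances <= 0) || any(abundances < 0) ||
      any(!is.finite(abundances)))
    stop("repertoire needs non-negative abundances with at least one positive")
  invisible(TRUE)
}

#' Repertoire clonality (1 - Pielou's evenness)
#'
#' `1 - H / ln(S)` with `H` the natural-log Shannon entropy of the
#' normalized clone frequencies and `S` the richness. Zero-abundance clones
#' are excluded from both. A repertoire of a single clone is maximally
#' clonal by convention (clonality 1). Values lie in [0, 1]: 0 for a
#' perfectly even repertoire, near 1 when a few clones dominate.
#'
#' @inheritParams richness
#' @return clonality in [0, 1].
#' @export
clonality <- function(abundances) {
  check_repertoire(abundances)
  a <- abundances[abundances > 0]
  S <- length(a)
  if (S == 1) return(1)
  p <- a / sum(a)
  H <- -sum(p * log(p))
  1 - H / log(S)
}

#' Cumulative frequency of a clone subset
#'
#' Sum of normalized frequencies over the given clone ids (e.g. the inferred
#' tumor-reactive or high-avidity clones of a microdissected compartment).
#' Ids absent from the repertoire contribute 0 with a warning.
#'
#' @param abundances named non-negative abundances.
#' @param clone_subset character vector of clone ids.
#' @return real in [0, 1].
#' @export
cumulative_frequency <- function(abundances, clone_subset) {
  check_repertoire(abundances)
  if (is.null(names(abundances))) stop("abundances must be named by clone id")
  p <- abundances / sum(abundances)
  missing <- setdiff(clone_subset, names(abundances))
  if (length(missing))
    warning(length(missing), " clone id(s) absent from the repertoire")
  sum(p[intersect(unique(clone_subset), names(p))])
}

#' Per-patient repertoire metrics from a clone table
#'
#' @param ct a [CloneTable()] with `n_cells` or `frequency` abundances.
#' @return data.frame with patient, richness, clonality.
#' @export
repertoire_metrics <- function(ct) {
  stopifnot(inherits(ct, "CloneTable"))
  ab <- if (all(!is.na(ct$frequency))) ct$frequency else ct$n_cells
  out <- do.call(rbind, lapply(split(ab, ct$patient), function(a) {
    data.frame(richness = richness(a), clonality = clonality(a))
  }))
  data.frame(patient = rownames(out), out, row.names = NULL)
}
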
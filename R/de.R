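#' Differential expression: reactive vs non-reactive
#'
#' Three engines cover the two method classes used to derive
#' tumor-reactivity signatures: a single-cell rank test applied directly to
#' log-normalized cells (`wilcoxon_de`), and two bulk-style analogues applied
#' to clone-average log-normalized profiles — a quasi-likelihood F test
#' (`ql_f_de`) and a moderated t test (`moderated_t_de`), both with
#' empirical-Bayes shrinkage of gene-wise variances toward a mean-variance
#' trend. Additional engines can be registered via [register_de_method()].
#'
#' All engines return a `DeResult`: a data.frame with columns `gene`,
#' `logFC` (log2 ratio of group means on the analysis scale, with a small
#' pseudocount), `stat`, `p`, `adj_p`, and a `de_method` attribute.
#'
#' @name de_methods
NULL

de_result <- function(gene, logFC, stat, p, method, adjust = "BH") {
  p <- pmin(pmax(p, 0), 1)
  out <- data.frame(gene = gene, logFC = logFC, stat = stat, p = p,
                    adj_p = stats::p.adjust(p, method = adjust),
                    stringsAsFactors = FALSE)
  attr(out, "de_method") <- method
  attr(out, "adjust") <- adjust
  class(out) <- c("DeResult", "data.frame")
  out
}

LOGFC_PSEUDO <- 0.01

group_split <- function(labels) {
  pos <- labels == "tumor_reactive" | labels == TRUE | labels == 1
  if (!any(pos) || all(pos))
    stop("both groups must be non-empty")
  pos
}

#' @rdname de_methods
#' @param cm a [CellMatrix()] with a lognorm layer.
#' @param labels per-cell labels (`tumor_reactive` vs anything else, or
#'   logical with TRUE = reactive).
#' @param adjust multiple-testing correction passed to [stats::p.adjust()]
#'   (default Benjamini-Hochberg).
#' @export
wilcoxon_de <- function(cm, labels, adjust = "BH") {
  stopifnot(inherits(cm, "CellMatrix"))
  if (is.null(cm$lognorm)) stop("lognorm layer absent; call normalize_log()")
  x <- as.matrix(cm$lognorm)
  pos <- group_split(labels)
  n1 <- sum(pos); n2 <- sum(!pos); n <- n1 + n2
  res <- t(vapply(seq_len(nrow(x)), function(g) {
    v <- as.numeric(x[g, ])
    r <- rank(v)
    U <- sum(r[pos]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    has_ties <- any(ties > 1)
    if (min(n1, n2) <= 8 && !has_ties) {
      # exact two-sided null from the Mann-Whitney distribution
      p <- 2 * min(stats::pwilcox(U, n1, n2),
                   stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))
      p <- min(p, 1)
    } else {
      tie_term <- sum(ties^3 - ties) / (n * (n - 1))
      sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
      if (sigma2 <= 0) return(c(U, 1))
      z <- (U - n1 * n2 / 2)
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
      p <- 2 * stats::pnorm(-abs(z))
    }
    c(U, p)
  }, numeric(2)))
  m1 <- Matrix::rowMeans(x[, pos, drop = FALSE])
  m2 <- Matrix::rowMeans(x[, !pos, drop = FALSE])
  de_result(rownames(x), log2((m1 + LOGFC_PSEUDO) / (m2 + LOGFC_PSEUDO)),
            res[, 1], res[, 2], "wilcoxon_sc", adjust)
}

# Empirical-Bayes squeezing of gene-wise variances toward an
# intensity-dependent trend; moment matching of log variances against the
# scaled-F model (prior df estimated from the excess spread of log s2 over
# the trigamma(df/2) expected under pure chi-squared noise).
squeeze_variances <- function(s2, df, amean, prior_df = NULL, trend = TRUE) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  if (trend && length(unique(amean[ok])) > 2) {
    lo <- stats::lowess(amean[ok], z, f = 0.5)
    ztrend <- stats::approx(lo$x, lo$y, xout = amean, rule = 2, ties = "ordered")$y
  } else {
    ztrend <- rep(mean(z), length(s2))
  }
  # bias of log chi2_df/df
  bias_df <- digamma(df / 2) - log(df / 2)
  if (is.null(prior_df)) {
    resid_var <- stats::var(z - ztrend[ok])
    excess <- resid_var - trigamma(df / 2)
    if (!is.finite(excess) || excess <= trigamma(1e6 / 2)) {
      prior_df <- Inf
    } else {
      prior_df <- 2 * stats::uniroot(function(x) trigamma(x) - excess,
                                     lower = 1e-6, upper = 1e6)$root
    }
  }
  if (is.infinite(prior_df)) {
    s2_prior <- exp(ztrend - bias_df)
    s2_post <- s2_prior
  } else {
    bias_d0 <- digamma(prior_df / 2) - log(prior_df / 2)
    s2_prior <- exp(ztrend - bias_df + bias_d0)
    s2_post <- (prior_df * s2_prior + df * s2) / (prior_df + df)
    s2_post[!ok] <- s2_prior[!ok]
  }
  list(s2_post = s2_post, s2_prior = s2_prior, prior_df = prior_df)
}

pseudobulk_group_stats <- function(profiles, labels) {
  pos <- group_split(labels)
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 < 2 || n2 < 2) stop("need at least 2 clones per group")
  x1 <- profiles[, pos, drop = FALSE]
  x2 <- profiles[, !pos, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  rss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  list(m1 = m1, m2 = m2, s2 = rss / df, df = df, n1 = n1, n2 = n2,
       amean = rowMeans(profiles))
}

#' @rdname de_methods
#' @param profiles genes x clones matrix of clone-average log-normalized
#'   values (see [pseudobulk_by_clone()]).
#' @param prior_df prior degrees of freedom for the variance shrinkage;
#'   `NULL` estimates it from the data, `0` disables shrinkage (ordinary
#'   two-sample statistics).
#' @export
ql_f_de <- function(profiles, labels, adjust = "BH", prior_df = NULL) {
  st <- pseudobulk_group_stats(profiles, labels)
  sq <- if (identical(prior_df, 0)) {
    list(s2_post = st$s2, prior_df = 0)
  } else {
    squeeze_variances(st$s2, st$df, st$amean, prior_df = prior_df)
  }
  se2 <- sq$s2_post * (1 / st$n1 + 1 / st$n2)
  Fstat <- (st$m1 - st$m2)^2 / se2
  df2 <- st$df + if (is.finite(sq$prior_df)) sq$prior_df else 0
  if (is.infinite(sq$prior_df)) {
    p <- stats::pchisq(Fstat, df = 1, lower.tail = FALSE)
  } else {
    p <- stats::pf(Fstat, df1 = 1, df2 = df2, lower.tail = FALSE)
  }
  bad <- !is.finite(Fstat)
  Fstat[bad] <- 0; p[bad] <- 1
  de_result(rownames(profiles),
            log2((st$m1 + LOGFC_PSEUDO) / (st$m2 + LOGFC_PSEUDO)),
            Fstat, p, "ql_f_pseudobulk", adjust)
}

#' @rdname de_methods
#' @export
moderated_t_de <- function(profiles, labels, adjust = "BH", prior_df = NULL) {
  st <- pseudobulk_group_stats(profiles, labels)
  sq <- if (identical(prior_df, 0)) {
    list(s2_post = st$s2, prior_df = 0)
  } else {
    squeeze_variances(st$s2, st$df, st$amean, prior_df = prior_df)
  }
  tstat <- (st$m1 - st$m2) / sqrt(sq$s2_post * (1 / st$n1 + 1 / st$n2))
  df2 <- st$df + if (is.finite(sq$prior_df)) sq$prior_df else 0
  if (is.infinite(sq$prior_df)) {
    p <- 2 * stats::pnorm(-abs(tstat))
  } else {
    p <- 2 * stats::pt(-abs(tstat), df = df2)
  }
  bad <- !is.finite(tstat)
  tstat[bad] <- 0; p[bad] <- 1
  de_result(rownames(profiles),
            log2((st$m1 + LOGFC_PSEUDO) / (st$m2 + LOGFC_PSEUDO)),
            tstat, p, "moderated_t_pseudobulk", adjust)
}

.de_registry <- new.env(parent = emptyenv())

#' Register or list differential expression engines
#'
#' Further engines (e.g. wrappers around other count models) can be plugged
#' in; they must accept `(input, labels, ...)` and return a `DeResult`.
#' `kind` records whether the engine expects single cells (`"cell"`) or
#' clone-average pseudo-bulk profiles (`"pseudobulk"`).
#'
#' @param name engine name.
#' @param fun engine function.
#' @param kind `"cell"` or `"pseudobulk"`.
#' @return `de_methods()` returns a data.frame of registered engines.
#' @export
register_de_method <- function(name, fun, kind = c("pseudobulk", "cell")) {
  kind <- match.arg(kind)
  assign(name, list(fun = fun, kind = kind), envir = .de_registry)
  invisible(name)
}

#' @rdname register_de_method
#' @export
de_methods <- function() {
  nm <- ls(.de_registry)
  data.frame(name = nm,
             kind = vapply(nm, function(n) get(n, envir = .de_registry)$kind,
                           character(1)),
             row.names = NULL)
}

get_de_method <- function(name) {
  if (!exists(name, envir = .de_registry)) stop("unknown DE method: ", name)
  get(name, envir = .de_registry)
}

#' Derive a signature from DE statistics
#'
#' Genes are ordered by the chosen criterion — ascending adjusted P or
#' descending absolute logFC, with ties broken by the other criterion and
#' finally by gene id. `side = "up"` keeps only genes with positive logFC;
#' `side = "both"` splits the length budget between up- and downregulated
#' genes proportionally to their availability.
#'
#' @param de a `DeResult`.
#' @param criterion `"p_value"` or `"logFC"`.
#' @param length target number of signature genes (truncated with a warning
#'   when fewer are available).
#' @param side `"up"` or `"both"`.
#' @return a [Signature()].
#' @export
derive_signature <- function(de, criterion = c("p_value", "logFC"),
                             length = 90, side = c("up", "both")) {
  criterion <- match.arg(criterion)
  side <- match.arg(side)
  stopifnot(length >= 1)
  ord <- if (criterion == "p_value") {
    order(de$p, -abs(de$logFC), de$gene)
  } else {
    order(-abs(de$logFC), de$p, de$gene)
  }
  de <- de[ord, ]
  up_pool <- de$gene[de$logFC > 0]
  down_pool <- de$gene[de$logFC < 0]
  if (side == "up") {
    if (length > base::length(up_pool)) {
      warning("only ", base::length(up_pool), " upregulated genes available")
      length <- base::length(up_pool)
    }
    up <- up_pool[seq_len(length)]
    down <- character()
  } else {
    n_up_avail <- base::length(up_pool); n_down_avail <- base::length(down_pool)
    avail <- n_up_avail + n_down_avail
    if (length > avail) {
      warning("only ", avail, " genes with nonzero logFC available")
      length <- avail
    }
    n_up <- round(length * n_up_avail / avail)
    n_up <- min(max(n_up, length - n_down_avail), n_up_avail)
    up <- up_pool[seq_len(n_up)]
    down <- down_pool[seq_len(length - n_up)]
  }
  Signature(up, down,
            stats = data.frame(gene = de$gene, logFC = de$logFC, p = de$p,
                               adj_p = de$adj_p, stringsAsFactors = FALSE),
            meta = list(criterion = criterion, length = length, side = side,
                        de_method = attr(de, "de_method")))
}
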
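#' Feature recipe for the logistic model family
#'
#' Fits, on training cells only, the feature transformation used by the
#' elastic-net logistic models: gene-wise z-scaling, greedy removal of genes
#' correlated above `correlation_cutoff` (genes are visited in
#' variance-descending order and a gene is kept only if its absolute Pearson
#' correlation with every already-kept gene is at or below the cutoff), an
#' optional relevance filter, and, for the PCA space, principal components
#' retained by explained-variance or relevance rules.
#'
#' Filters: `none`; `wilcoxon_p01` (per-feature rank test against the
#' training labels, raw P < 0.01); `de_bonferroni05` (RNA space only: a DE
#' engine with Bonferroni-adjusted P < 0.05); `pc_var_1e-4` (PCA space only:
#' components explaining more than 1e-4 of the variance).
#'
#' @param cm a [CellMatrix()] with a lognorm layer (training cells).
#' @param labels per-cell training labels.
#' @param space `"rna"` or `"pca"`.
#' @param filter one of the filters above.
#' @param correlation_cutoff absolute-correlation threshold (default 0.8).
#' @param de_method DE engine name for `de_bonferroni05` (default
#'   `"wilcoxon_sc"`, run on the training cells).
#' @param pc_var_min explained-variance floor for `pc_var_1e-4`.
#' @return a `FeatureRecipe` with the fitted artifacts (kept genes, gene
#'   means/sds, PC rotation, explained variances).
#' @export
fit_recipe <- function(cm, labels, space = c("rna", "pca"),
                       filter = c("none", "wilcoxon_p01", "de_bonferroni05",
                                  "pc_var_1e-4"),
                       correlation_cutoff = 0.8, de_method = "wilcoxon_sc",
                       pc_var_min = 1e-4) {
  space <- match.arg(space)
  filter <- match.arg(filter)
  if (space == "rna" && filter == "pc_var_1e-4")
    stop("pc_var_1e-4 filter applies to the pca space only")
  if (space == "pca" && filter == "de_bonferroni05")
    stop("de_bonferroni05 filter applies to the rna space only")
  x <- lognorm_dense(cm)
  pos <- group_split(labels)

  mu <- rowMeans(x); sd <- apply(x, 1, stats::sd)
  keep <- sd > 0
  genes <- rownames(x)[keep]
  z <- (x[keep, , drop = FALSE] - mu[keep]) / sd[keep]

  # greedy correlation pruning, variance-descending visit order
  ord <- order(sd[keep]^2, decreasing = TRUE)
  cm_cor <- abs(stats::cor(t(z[ord, , drop = FALSE])))
  kept <- logical(length(ord))
  for (i in seq_along(ord)) {
    if (!any(kept) || all(cm_cor[i, kept] <= correlation_cutoff))
      kept[i] <- TRUE
  }
  genes <- genes[ord][kept]
  z <- z[genes, , drop = FALSE]

  recipe <- list(space = space, filter = filter,
                 correlation_cutoff = correlation_cutoff,
                 genes = genes, mu = mu[genes], sd = sd[genes],
                 rotation = NULL, explained_var = NULL, pcs = NULL)

  if (space == "rna") {
    if (filter == "wilcoxon_p01") {
      p <- feature_wilcoxon_p(z, pos)
      recipe$genes <- genes[p < 0.01]
    } else if (filter == "de_bonferroni05") {
      eng <- get_de_method(de_method)
      de <- if (eng$kind == "cell") eng$fun(cm, labels, adjust = "bonferroni")
            else stop("de_bonferroni05 in fit_recipe requires a cell-level engine")
      sig_genes <- de$gene[de$adj_p < 0.05]
      recipe$genes <- intersect(genes, sig_genes)
    }
    if (!length(recipe$genes)) stop("all features filtered out")
    recipe$mu <- recipe$mu[recipe$genes]; recipe$sd <- recipe$sd[recipe$genes]
  } else {
    pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    if (filter == "pc_var_1e-4") {
      pcs <- which(ev > pc_var_min)
    } else if (filter == "wilcoxon_p01") {
      p <- feature_wilcoxon_p(t(pc$x), pos)
      pcs <- which(p < 0.01)
    } else {
      pcs <- seq_along(ev)
    }
    if (!length(pcs)) stop("all features filtered out")
    recipe$rotation <- pc$rotation[, pcs, drop = FALSE]
    recipe$explained_var <- ev
    recipe$pcs <- pcs
  }
  class(recipe) <- "FeatureRecipe"
  recipe
}

feature_wilcoxon_p <- function(feat_by_obs, pos) {
  n1 <- sum(pos); n2 <- sum(!pos); n <- n1 + n2
  apply(feat_by_obs, 1, function(v) {
    r <- rank(v)
    U <- sum(r[pos]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(1)
    z <- (U - n1 * n2 / 2)
    2 * stats::pnorm(-abs((z - sign(z) * 0.5) / sqrt(sigma2)))
  })
}

#' Apply a fitted feature recipe
#'
#' Idempotent transform using only training-fitted artifacts.
#'
#' @param recipe a `FeatureRecipe`.
#' @param cm a [CellMatrix()] with a lognorm layer.
#' @return numeric matrix, cells x features.
#' @export
apply_recipe <- function(recipe, cm) {
  stopifnot(inherits(recipe, "FeatureRecipe"))
  x <- lognorm_dense(cm)
  miss <- setdiff(if (recipe$space == "rna") recipe$genes
                  else rownames(recipe$rotation), rownames(x))
  if (length(miss)) stop("matrix lacks recipe genes: ", paste(miss, collapse = ", "))
  if (recipe$space == "rna") {
    z <- (x[recipe$genes, , drop = FALSE] - recipe$mu) / recipe$sd
    t(z)
  } else {
    z <- (x[names(recipe$mu), , drop = FALSE] - recipe$mu) / recipe$sd
    t(z) %*% recipe$rotation
  }
}

#' Fit an elastic-net logistic model
#'
#' Penalized logistic regression by coordinate descent (glmnet), with an
#' unpenalized intercept. `alpha = 0` is ridge, `alpha = 1` is lasso.
#'
#' @param features numeric matrix, observations x features.
#' @param labels binary labels (positive = tumor-reactive).
#' @param alpha elastic-net mixing in [0, 1].
#' @param lambda penalty strength (> 0).
#' @return an `ElasticNetModel` with `coef` (named vector), `intercept`,
#'   `alpha`, `lambda`.
#' @export
fit_elastic_net <- function(features, labels, alpha = 0.5, lambda = 0.01) {
  stopifnot(alpha >= 0, alpha <= 1, lambda > 0, all(is.finite(features)))
  pos <- group_split(labels)
  feat_names <- colnames(features)
  if (ncol(features) == 1) # coordinate-descent solver needs >= 2 columns
    features <- cbind(features, `.zero.` = 0)
  # descending lambda path ending at the requested value gives glmnet a warm
  # start and an exact solution at that value
  path <- lambda * c(64, 16, 4, 1)
  fit <- glmnet::glmnet(features, factor(pos, levels = c(FALSE, TRUE)),
                        family = "binomial", alpha = alpha, lambda = path,
                        standardize = FALSE, thresh = 1e-9)
  cf <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  structure(list(intercept = cf[1],
                 coef = stats::setNames(cf[seq_along(feat_names) + 1], feat_names),
                 alpha = alpha, lambda = lambda),
            class = "ElasticNetModel")
}

#' Predict cell probabilities from an elastic-net model
#'
#' @param model an `ElasticNetModel`.
#' @param features observations x features, same columns as at fit time.
#' @return probabilities in (0, 1), named by observation.
#' @export
predict_lr <- function(model, features) {
  stopifnot(inherits(model, "ElasticNetModel"))
  if (!identical(colnames(features), names(model$coef)))
    stop("feature columns do not match the fitted model")
  eta <- model$intercept + as.numeric(features %*% model$coef)
  stats::setNames(1 / (1 + exp(-eta)), rownames(features))
}

#' Logistic-model grid
#'
#' Enumerates the feature-space x filter structure of the logistic family:
#' RNA-space recipes with no filter, the rank-test filter, and one
#' DE-significance filter per available DE engine; plus the two PCA-space
#' recipes (rank-test filter and explained-variance rule). With eight DE
#' engines this yields the canonical 10 RNA + 2 PCA = 12 models.
#'
#' @param de_methods character vector of DE engine names for the
#'   `de_bonferroni05` variants.
#' @return data.frame with `id`, `space`, `filter`, `de_method`.
#' @export
lr_model_grid <- function(de_methods = "wilcoxon_sc") {
  rna <- data.frame(space = "rna",
                    filter = c("none", "wilcoxon_p01",
                               rep("de_bonferroni05", length(de_methods))),
                    de_method = c(NA, NA, de_methods))
  pca <- data.frame(space = "pca", filter = c("wilcoxon_p01", "pc_var_1e-4"),
                    de_method = NA)
  out <- rbind(rna, pca)
  out$id <- sprintf("lr_%s_%s%s", out$space, out$filter,
                    ifelse(is.na(out$de_method), "", paste0("_", out$de_method)))
  out[, c("id", "space", "filter", "de_method")]
}
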
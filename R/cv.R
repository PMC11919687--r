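#' Leave-one-patient-out fold plan
#'
#' One fold per patient: the test fold is that patient's clones, the
#' training fold is everyone else.
#'
#' @param ct a [CloneTable()].
#' @return a `FoldPlan`: list of `list(test_patient, train_patients)`.
#' @export
make_lopo_folds <- function(ct) {
  stopifnot(inherits(ct, "CloneTable"))
  patients <- sort(unique(ct$patient))
  if (length(patients) < 2) stop("LOPO needs at least 2 patients")
  folds <- lapply(patients, function(p)
    list(test_patient = p, train_patients = setdiff(patients, p)))
  structure(folds, class = "FoldPlan")
}

#' Model specification for the cross-validation registry
#'
#' A spec bundles a model family with its fixed settings and the
#' hyperparameter grid searched by the inner loop of the nested CV.
#'
#' @param id unique model id.
#' @param family `"signature"` or `"lr"`.
#' @param params fixed settings: for `signature`, `de_method` (a registered
#'   DE engine); for `lr`, `space`, `filter` and optionally `de_method`.
#' @param hyper_grid data.frame of hyperparameter combinations: for
#'   `signature`, columns `criterion`, `length`, `side`, `score_method`; for
#'   `lr`, columns `alpha`, `lambda`.
#' @return a `TrtModelSpec`.
#' @export
trt_model_spec <- function(id, family = c("signature", "lr"), params = list(),
                           hyper_grid) {
  family <- match.arg(family)
  stopifnot(is.data.frame(hyper_grid), nrow(hyper_grid) >= 1)
  need <- if (family == "signature")
    c("criterion", "length", "side", "score_method") else c("alpha", "lambda")
  miss <- setdiff(need, names(hyper_grid))
  if (length(miss)) stop("hyper_grid lacks columns: ", paste(miss, collapse = ", "))
  structure(list(id = id, family = family, params = params,
                 hyper_grid = hyper_grid),
            class = "TrtModelSpec")
}

#' Default model registry
#'
#' Builds the registry of candidate models: one signature-score spec per DE
#' engine (criterion, signature length, side and scoring scheme as tuned
#' hyperparameters) and one logistic spec per feature-space/filter recipe
#' (elastic-net alpha and lambda as hyperparameters). With nine DE engines
#' and the full recipe set this is the canonical 9 + 12 = 21-model zoo; by
#' default it enumerates the three in-repo DE engines and the five recipe
#' variants they induce.
#'
#' @param de_methods registered DE engine names for the signature family.
#' @param score_methods scoring schemes to tune over.
#' @param lengths,criteria,sides signature hyperparameter ranges.
#' @param alphas,lambdas elastic-net grids.
#' @param lr_de_methods cell-level DE engines for the logistic
#'   `de_bonferroni05` recipes.
#' @return list of [trt_model_spec()].
#' @export
model_registry <- function(de_methods = c("ql_f_pseudobulk",
                                          "moderated_t_pseudobulk",
                                          "wilcoxon_sc"),
                           score_methods = c("average", "rank_auc", "u_score",
                                             "rank_mean"),
                           lengths = c(30, 60, 90),
                           criteria = c("p_value", "logFC"),
                           sides = c("up", "both"),
                           alphas = c(0, 0.25, 0.5, 0.75, 1),
                           lambdas = 10^seq(-4, 1, length.out = 6),
                           lr_de_methods = "wilcoxon_sc") {
  sig <- lapply(de_methods, function(m)
    trt_model_spec(paste0("sig_", m), "signature", list(de_method = m),
                   expand.grid(criterion = criteria, length = lengths,
                               side = sides, score_method = score_methods,
                               stringsAsFactors = FALSE)))
  grid <- lr_model_grid(lr_de_methods)
  lr <- lapply(seq_len(nrow(grid)), function(i)
    trt_model_spec(grid$id[i], "lr",
                   list(space = grid$space[i], filter = grid$filter[i],
                        de_method = grid$de_method[i]),
                   expand.grid(alpha = alphas, lambda = lambdas)))
  c(sig, lr)
}

#' Precompute shared per-cohort matrices
#'
#' Pseudo-bulk clone profiles, the gene-wise z-scaled log-normalized matrix
#' and (lazily) per-cell descending expression ranks are label-independent,
#' so cross-validation and y-randomization compute them once.
#'
#' @param cm a [CellMatrix()] with lognorm.
#' @param ct a [CloneTable()].
#' @param with_ranks precompute rank matrices for the rank-based scores.
#' @return a `TrtCache` list.
#' @export
build_cache <- function(cm, ct, with_ranks = FALSE) {
  x <- lognorm_dense(cm)
  mu <- rowMeans(x); sd <- apply(x, 1, stats::sd)
  sd0 <- ifelse(sd == 0, 1, sd)
  cache <- list(x = x, z = (x - mu) / sd0,
                pseudobulk = pseudobulk_by_clone(cm, ct),
                cell_clone = cm$cell_meta$clone_id,
                rk_desc = if (with_ranks) nrow(x) + 1 - cell_ranks(x) else NULL)
  class(cache) <- "TrtCache"
  cache
}

score_cells_cached <- function(cache, sig, method, top_frac = 0.05,
                               rank_cap = 1500) {
  up <- intersect(sig$up, rownames(cache$x))
  down <- intersect(sig$down, rownames(cache$x))
  if (!length(up) && !length(down)) stop("no signature genes in the matrix")
  G <- nrow(cache$x)
  if (method %in% c("rank_auc", "u_score", "rank_mean") && is.null(cache$rk_desc))
    cache$rk_desc <- G + 1 - cell_ranks(cache$x)
  s <- switch(method,
    average = {
      v <- colMeans(cache$z[up, , drop = FALSE])
      if (length(down)) v <- v - colMeans(cache$z[down, , drop = FALSE])
      v
    },
    rank_auc = {
      top_n <- ceiling(top_frac * G)
      v <- apply(cache$rk_desc, 2, rank_auc_one_side, genes = up, top_n = top_n)
      if (length(down))
        v <- v - apply(G + 1 - cache$rk_desc, 2, rank_auc_one_side,
                       genes = down, top_n = top_n)
      v
    },
    u_score = {
      cap <- min(rank_cap, G)
      v <- apply(cache$rk_desc, 2, u_score_one_side, genes = up, rank_cap = cap)
      if (length(down))
        v <- v - apply(G + 1 - cache$rk_desc, 2, u_score_one_side,
                       genes = down, rank_cap = cap)
      v
    },
    rank_mean = {
      rk <- G + 1 - cache$rk_desc
      center <- (G + 1) / (2 * G)
      v <- colMeans(rk[up, , drop = FALSE] / G) - center
      if (length(down))
        v <- v - (colMeans(rk[down, , drop = FALSE] / G) - center)
      v
    },
    stop("unknown score method: ", method))
  stats::setNames(s, colnames(cache$x))
}

subset_cells <- function(cm, keep) {
  CellMatrix(cm$counts[, keep, drop = FALSE], cm$cell_meta[keep, ],
             lognorm = if (is.null(cm$lognorm)) NULL
                       else cm$lognorm[, keep, drop = FALSE])
}

hyper_row <- function(hyper_grid, i) as.list(hyper_grid[i, , drop = FALSE])

# Fit one model configuration on the training clones and return scaled
# clone-level scores for every clone in ct plus the fitted threshold.
fit_config <- function(spec, hyper, cm, ct, train_clones, cache) {
  is_train <- ct$clone_id %in% train_clones & ct$label != "unknown"
  tr_labels <- ct$label[is_train] == "tumor_reactive"
  if (!any(tr_labels) || all(tr_labels))
    stop("one-class training labels")
  if (spec$family == "signature") {
    eng <- get_de_method(spec$params$de_method)
    de <- if (eng$kind == "pseudobulk") {
      eng$fun(cache$pseudobulk[, ct$clone_id[is_train], drop = FALSE], tr_labels)
    } else {
      cell_in <- cache$cell_clone %in% ct$clone_id[is_train]
      cell_lab <- (ct$label[match(cache$cell_clone[cell_in], ct$clone_id)]
                   == "tumor_reactive")
      eng$fun(subset_cells(cm, cell_in), cell_lab)
    }
    sig <- derive_signature(de, criterion = hyper$criterion,
                            length = hyper$length, side = hyper$side)
    cell_scores <- score_cells_cached(cache, sig, hyper$score_method)
    clone_scores <- tapply(cell_scores, cache$cell_clone, max)[ct$clone_id]
    tr_scores <- clone_scores[is_train]
    mu_t <- mean(tr_scores); sigma_t <- stats::sd(tr_scores)
    if (!is.finite(sigma_t) || sigma_t <= 0) stop("degenerate training scores")
    scaled <- (clone_scores - mu_t) / sigma_t
    tm <- fit_threshold(scaled[is_train], tr_labels)
    list(model = structure(list(family = "signature", spec_id = spec$id,
                                params = spec$params, hyper = hyper,
                                signature = sig, mu_t = mu_t,
                                sigma_t = sigma_t, threshold = tm),
                           class = "TrtModel"),
         clone_scores = scaled, calls = apply_threshold(tm, scaled))
  } else {
    cell_in <- cache$cell_clone %in% ct$clone_id[is_train]
    cell_lab <- (ct$label[match(cache$cell_clone[cell_in], ct$clone_id)]
                 == "tumor_reactive")
    cm_tr <- subset_cells(cm, cell_in)
    recipe <- fit_recipe(cm_tr, cell_lab, space = spec$params$space,
                         filter = spec$params$filter,
                         de_method = spec$params$de_method %||% "wilcoxon_sc")
    feats_tr <- apply_recipe(recipe, cm_tr)
    enet <- fit_elastic_net(feats_tr, cell_lab, alpha = hyper$alpha,
                            lambda = hyper$lambda)
    feats_all <- apply_recipe(recipe, cm)
    probs <- predict_lr(enet, feats_all)
    clone_scores <- tapply(probs, cache$cell_clone, max)[ct$clone_id]
    tm <- fit_threshold(clone_scores[is_train], tr_labels)
    list(model = structure(list(family = "lr", spec_id = spec$id,
                                params = spec$params, hyper = hyper,
                                recipe = recipe, enet = enet, threshold = tm),
                           class = "TrtModel"),
         clone_scores = clone_scores,
         calls = apply_threshold(tm, clone_scores))
  }
}

eval_clones <- function(scores, calls, ct, clone_ids) {
  sel <- ct$clone_id %in% clone_ids & ct$label != "unknown"
  truth <- ct$label[sel] == "tumor_reactive"
  cc <- confusion_counts(calls[ct$clone_id[sel]], truth)
  auc <- if (any(truth) && !all(truth))
    roc_auc(scores[ct$clone_id[sel]], truth)$auc else NA_real_
  c(as.list(cc),
    list(mcc = unname(mcc(cc[["TP"]], cc[["FP"]], cc[["TN"]], cc[["FN"]])),
         accuracy = unname(accuracy(cc[["TP"]], cc[["FP"]], cc[["TN"]],
                                    cc[["FN"]])),
         auc = auc, n = sum(sel)))
}

# Plain LOPO evaluation of one configuration.
lopo_evaluate <- function(spec, hyper, cm, ct, cache, folds = NULL) {
  if (is.null(folds)) folds <- make_lopo_folds(ct)
  rows <- lapply(folds, function(f) {
    train_clones <- ct$clone_id[ct$patient %in% f$train_patients]
    test_clones <- ct$clone_id[ct$patient == f$test_patient]
    fit <- tryCatch(fit_config(spec, hyper, cm, ct, train_clones, cache),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("fold %s skipped: %s", f$test_patient,
                      conditionMessage(fit)))
      return(NULL)
    }
    ev <- eval_clones(fit$clone_scores, fit$calls, ct, test_clones)
    data.frame(fold = f$test_patient, TP = ev$TP, FP = ev$FP, TN = ev$TN,
               FN = ev$FN, mcc = ev$mcc, accuracy = ev$accuracy,
               auc = ev$auc, n = ev$n)
  })
  do.call(rbind, rows)
}

hyper_label <- function(hyper)
  paste(vapply(hyper, function(v) format(v, digits = 4), character(1)),
        collapse = "|")

# Parsimony tie-break between hyperparameter rows: shorter signatures /
# stronger penalties first, then grid order.
select_best_hyper <- function(spec, mean_mcc) {
  g <- spec$hyper_grid
  best <- max(mean_mcc, na.rm = TRUE)
  cand <- which(!is.na(mean_mcc) & mean_mcc == best)
  if (length(cand) > 1) {
    if (spec$family == "signature") {
      cand <- cand[order(g$length[cand], cand)]
    } else {
      cand <- cand[order(-g$lambda[cand], cand)]
    }
  }
  cand[1]
}

#' Leave-one-patient-out nested cross-validation
#'
#' Outer loop: LOPO over patients, estimating generalization. Inner loop:
#' LOPO over the outer-training patients, selecting each model's
#' hyperparameters by mean inner MCC. The winning model (highest mean outer
#' MCC; ties broken toward the more parsimonious configuration, then
#' registry order) has its hyperparameters re-tuned by a plain LOPO on the
#' whole data and is finally refit on all patients.
#'
#' @param registry list of [trt_model_spec()].
#' @param cm a [CellMatrix()] with lognorm.
#' @param ct a labeled [CloneTable()] (>= 3 patients).
#' @param cache optional [build_cache()] result.
#' @param verbose print progress.
#' @return list with `perf` (per model x outer fold records), `summary`
#'   (per-model mean outer MCC/accuracy), `winner_id`, `final_hyper`, and
#'   `final_model` (a `TrtModel` trained on all data).
#' @export
nested_cv <- function(registry, cm, ct, cache = NULL, verbose = FALSE) {
  stopifnot(inherits(ct, "CloneTable"))
  if (length(unique(ct$patient)) < 3)
    stop("nested CV needs at least 3 patients")
  if (is.null(cache)) cache <- build_cache(cm, ct)
  outer <- make_lopo_folds(ct)
  perf <- list()
  for (spec in registry) {
    for (f in outer) {
      if (verbose) message(spec$id, " / outer fold ", f$test_patient)
      ct_inner <- ct[ct$patient %in% f$train_patients, ]
      class(ct_inner) <- class(ct)
      inner_folds <- make_lopo_folds(ct_inner)
      inner_mean <- vapply(seq_len(nrow(spec$hyper_grid)), function(i) {
        res <- suppressWarnings(
          lopo_evaluate(spec, hyper_row(spec$hyper_grid, i), cm, ct_inner,
                        cache, inner_folds))
        if (is.null(res)) NA_real_ else mean(res$mcc)
      }, numeric(1))
      if (all(is.na(inner_mean))) {
        warning(spec$id, ": all inner configurations failed for fold ",
                f$test_patient)
        next
      }
      best_i <- select_best_hyper(spec, inner_mean)
      hyper <- hyper_row(spec$hyper_grid, best_i)
      train_clones <- ct$clone_id[ct$patient %in% f$train_patients]
      test_clones <- ct$clone_id[ct$patient == f$test_patient]
      fit <- tryCatch(fit_config(spec, hyper, cm, ct, train_clones, cache),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        warning(spec$id, ": outer fold ", f$test_patient, " failed: ",
                conditionMessage(fit))
        next
      }
      ev <- eval_clones(fit$clone_scores, fit$calls, ct, test_clones)
      perf[[length(perf) + 1]] <-
        data.frame(model = spec$id, fold = f$test_patient,
                   hyper = hyper_label(hyper), TP = ev$TP, FP = ev$FP,
                   TN = ev$TN, FN = ev$FN, mcc = ev$mcc,
                   accuracy = ev$accuracy, auc = ev$auc, n = ev$n)
    }
  }
  perf <- do.call(rbind, perf)
  if (is.null(perf)) stop("no model produced any outer-fold result")
  summary <- do.call(rbind, lapply(split(perf, perf$model), function(d)
    data.frame(model = d$model[1], mean_mcc = mean(d$mcc),
               mean_accuracy = mean(d$accuracy),
               pooled_mcc = mcc(sum(d$TP), sum(d$FP), sum(d$TN), sum(d$FN)),
               folds = nrow(d))))
  summary <- summary[order(-summary$mean_mcc), ]
  rownames(summary) <- NULL
  winner_id <- summary$model[1]
  spec <- registry[[which(vapply(registry, `[[`, "", "id") == winner_id)]]
  # fine-tune the winner's hyperparameters by plain LOPO on the whole data
  tune_mean <- vapply(seq_len(nrow(spec$hyper_grid)), function(i) {
    res <- suppressWarnings(
      lopo_evaluate(spec, hyper_row(spec$hyper_grid, i), cm, ct, cache, outer))
    if (is.null(res)) NA_real_ else mean(res$mcc)
  }, numeric(1))
  best_i <- select_best_hyper(spec, tune_mean)
  final_hyper <- hyper_row(spec$hyper_grid, best_i)
  final <- fit_config(spec, final_hyper, cm, ct, ct$clone_id, cache)
  list(perf = perf, summary = summary, winner_id = winner_id,
       final_hyper = final_hyper, final_model = final$model)
}

#' Predict clone-level tumor reactivity with a trained model
#'
#' @param model a `TrtModel` from [nested_cv()] or [fit_config] internals.
#' @param cm a [CellMatrix()] with lognorm.
#' @param ct a [CloneTable()] whose clones are present in `cm`.
#' @return the CloneTable with `trt_score` (scaled) and `trt_call` filled in.
#' @export
predict_trt <- function(model, cm, ct) {
  stopifnot(inherits(model, "TrtModel"), inherits(ct, "CloneTable"))
  cache <- list(x = lognorm_dense(cm), cell_clone = cm$cell_meta$clone_id)
  if (model$family == "signature") {
    mu <- rowMeans(cache$x); sd <- apply(cache$x, 1, stats::sd)
    cache$z <- (cache$x - mu) / ifelse(sd == 0, 1, sd)
    class(cache) <- "TrtCache"
    cell_scores <- score_cells_cached(cache, model$signature,
                                      model$hyper$score_method)
    clone_scores <- tapply(cell_scores, cache$cell_clone, max)[ct$clone_id]
    scaled <- (clone_scores - model$mu_t) / model$sigma_t
  } else {
    feats <- apply_recipe(model$recipe, cm)
    probs <- predict_lr(model$enet, feats)
    scaled <- tapply(probs, cache$cell_clone, max)[ct$clone_id]
  }
  ct$trt_score <- as.numeric(scaled)
  ct$trt_call <- as.logical(apply_threshold(model$threshold, scaled))
  ct
}

#' Y-randomization null calibration
#'
#' Repeatedly permutes the clone-level tumor-reactivity labels, reruns the
#' leave-one-patient-out evaluation of a fixed model configuration, and
#' summarizes the resulting MCC and accuracy distributions. A model immune
#' to spurious learning shows a mean MCC near 0 and mean accuracy near 50%.
#'
#' @param spec a [trt_model_spec()].
#' @param hyper one hyperparameter combination (list or 1-row data.frame);
#'   defaults to the first grid row.
#' @param cm,ct cohort data.
#' @param n_reps number of label permutations (default 100).
#' @param seed integer seed.
#' @param cache optional [build_cache()] result.
#' @return list with `mcc_mean`, `mcc_sd`, `accuracy_mean`, `accuracy_sd`
#'   (fold-averaged, across repetitions) and `per_rep` data.frame.
#' @export
y_randomization <- function(spec, hyper = NULL, cm, ct, n_reps = 100,
                            seed = 1L, cache = NULL) {
  if (is.null(hyper)) hyper <- hyper_row(spec$hyper_grid, 1)
  if (is.null(cache)) cache <- build_cache(cm, ct)
  folds <- make_lopo_folds(ct)
  per_rep <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    ct_p <- permute_labels(ct, seed = seed + r)
    res <- suppressWarnings(
      lopo_evaluate(spec, hyper, cm, ct_p, cache, folds))
    data.frame(rep = r, mcc = mean(res$mcc), accuracy = mean(res$accuracy))
  }))
  list(mcc_mean = mean(per_rep$mcc), mcc_sd = stats::sd(per_rep$mcc),
       accuracy_mean = mean(per_rep$accuracy),
       accuracy_sd = stats::sd(per_rep$accuracy), per_rep = per_rep)
}
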
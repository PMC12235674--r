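#' Grid search with stratified cross-validation and weighted F1
#'
#' Exhaustively scores every configuration in the grid by its mean weighted
#' F1 across the folds, breaks ties by first-in-grid order, and refits the
#' winner on all training samples. A fold that loses every instance of some
#' class is scored on the classes present, with a warning.
#'
#' @param x samples x features matrix (already normalized and restricted to
#'   the DEG feature rows).
#' @param y factor of training labels.
#' @param fold_of named integer vector (sample -> fold) from
#'   [assign_folds()].
#' @param family classifier family tag.
#' @param grid list of parameter lists; default [classifier_grid()].
#' @param seed integer seed for the classifier fits.
#' @return list of class `tuned_fit` with `fit` (the refitted winner),
#'   `best_params`, `best_score`, `cv_scores`.
#' @export
tune_and_fit <- function(x, y, fold_of, family, grid = NULL, seed = 1L) {
  if (is.null(grid)) grid <- classifier_grid(family)
  stopifnot(length(grid) >= 1L)
  ids <- rownames(x)
  if (is.null(ids) || !all(ids %in% names(fold_of)))
    stop("x rownames must match fold assignment names", call. = FALSE)
  folds <- fold_of[ids]
  cv_scores <- vapply(seq_along(grid), function(gi) {
    params <- grid[[gi]]
    per_fold <- vapply(sort(unique(folds)), function(f) {
      tr <- folds != f; te <- !tr
      y_tr <- y[tr]
      if (nlevels(droplevels(y_tr)) < 2L) return(NA_real_)
      if (length(setdiff(levels(droplevels(y)), levels(droplevels(y_tr)))))
        warning("fold ", f, " training set lost a class; scored on present classes",
                call. = FALSE)
      fit <- fit_classifier(family, params, x[tr, , drop = FALSE], y_tr,
                            seed = seed + f)
      pred <- predict_label(fit, x[te, , drop = FALSE])
      f1_weighted(y[te], pred, class_order = levels(y))
    }, numeric(1))
    mean(per_fold, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(cv_scores)             # ties -> first in grid order
  fit <- fit_classifier(family, grid[[best]], x, y, seed = seed)
  structure(list(fit = fit, best_params = grid[[best]],
                 best_score = cv_scores[best], cv_scores = cv_scores),
            class = "tuned_fit")
}

#' Run one experiment cell: repeated cross-platform train/test
#'
#' One cell is a (normalization method, DEG/NDEG thresholds, classifier
#' family) combination in one training direction. Gene selection runs once
#' on the training platform's full labelled sample set; then, per repeat:
#' stratified split, per-platform normalization with the training-derived
#' NDEG reference list, grid-search tuning on the training platform's folds
#' (weighted F1), prediction of the cross-platform test set, and the full
#' metric set. Repeats are aggregated into means, SDs and the Evalue.
#'
#' @param train_matrix,test_matrix [expr_matrix] objects for the training
#'   and test platforms, matched gene order.
#' @param labels named factor covering the samples of both matrices.
#' @param method one of [NORMALIZATION_METHODS].
#' @param family classifier family tag.
#' @param tau_deg,tau_ndeg selection thresholds.
#' @param mode `"p"` or `"q"` (FDR-adjusted selection).
#' @param n_repeats number of repeated partitions (default 5).
#' @param base_seed integer.
#' @param k folds for the tuning cross-validation (default 10).
#' @param frac training fraction (default 0.75).
#' @param fast use the reduced classifier grid?
#' @return A [aggregate_repeats()] result with the cell configuration and
#'   selection sizes attached as attributes.
#' @export
run_cell <- function(train_matrix, test_matrix, labels, method = "LOG_RQN",
                     family = "SVM", tau_deg = 0.05, tau_ndeg = 0.95,
                     mode = "p", n_repeats = 5L, base_seed = 1L, k = 10L,
                     frac = 0.75, fast = TRUE) {
  train_ids <- colnames(train_matrix)
  if (!all(train_ids %in% names(labels)))
    stop("unlabelled samples on the training platform", call. = FALSE)
  train_labels <- labels[train_ids]
  needs_ref <- method %in% c("LOG_RQN", "LOG_RQN_Z", "LOG_NPN_Z", "LOG_NICG_Z")

  tab <- anova_table(train_matrix, train_labels, fdr = identical(mode, "q"))
  sel <- select_genes(tab, tau_deg, tau_ndeg, mode = mode,
                      require_ndeg = needs_ref)
  if (!length(sel$deg)) stop("no features: DEG set is empty", call. = FALSE)

  grid <- classifier_grid(family, fast = fast)
  plans <- make_repeats(train_labels, colnames(test_matrix), frac = frac,
                        k = k, n_repeats = n_repeats, base_seed = base_seed)
  genes_used <- if (needs_ref) union(sel$deg, sel$ndeg) else sel$deg

  quantile_mapped <- method %in% c("LOG_RQN", "LOG_RQN_Z", "LOG_NPN_Z")
  metrics <- lapply(plans, function(plan) {
    stopifnot(!any(plan$test_ids %in% plan$train_ids))
    tr_sub <- train_matrix[genes_used, plan$train_ids]
    te_sub <- test_matrix[genes_used, plan$test_ids]
    # the quantile target is fitted once on the training samples and shared,
    # so both platforms land on the same reference distribution
    fitted <- if (quantile_mapped)
      fit_reference_target(log_transform(tr_sub), sel$ndeg) else NULL
    xtr <- normalize_expression(tr_sub, method, reference_genes = sel$ndeg,
                                fitted = fitted)
    xte <- normalize_expression(te_sub, method, reference_genes = sel$ndeg,
                                fitted = fitted)
    ftr <- t(unclass(xtr)[sel$deg, , drop = FALSE])
    fte <- t(unclass(xte)[sel$deg, , drop = FALSE])
    tuned <- tune_and_fit(ftr, labels[plan$train_ids], plan$fold_of, family,
                          grid = grid, seed = plan$seed + 1000L)
    pred <- predict_label(tuned$fit, fte)
    prob <- predict_proba(tuned$fit, fte)
    metric_set(labels[plan$test_ids], pred, prob, class_order = levels(labels))
  })
  out <- aggregate_repeats(metrics)
  attr(out, "cell") <- list(method = method, family = family,
                            tau_deg = tau_deg, tau_ndeg = tau_ndeg,
                            mode = mode, n_deg = length(sel$deg),
                            n_ndeg = length(sel$ndeg), n_repeats = n_repeats,
                            base_seed = base_seed)
  out
}

#' Run a full experiment: the Cartesian product of cells
#'
#' @param train_matrix,test_matrix,labels as in [run_cell()].
#' @param methods character vector of normalization methods.
#' @param taus data.frame (or list) of `tau_deg`/`tau_ndeg` pairs.
#' @param families character vector of classifier families.
#' @param ... further arguments passed to [run_cell()].
#' @return Long-format data.frame, one row per cell, with per-metric means,
#'   SDs and the Evalue.
#' @export
run_experiment <- function(train_matrix, test_matrix, labels,
                           methods = c("RAW", "LOG_RQN"),
                           taus = data.frame(tau_deg = 0.05, tau_ndeg = 0.95),
                           families = "SVM", ...) {
  taus <- as.data.frame(taus)
  rows <- list()
  for (method in methods) for (ti in seq_len(nrow(taus))) for (family in families) {
    message(sprintf("cell: method=%s tau_deg=%g tau_ndeg=%g family=%s",
                    method, taus$tau_deg[ti], taus$tau_ndeg[ti], family))
    ev <- run_cell(train_matrix, test_matrix, labels, method = method,
                   family = family, tau_deg = taus$tau_deg[ti],
                   tau_ndeg = taus$tau_ndeg[ti], ...)
    cell <- attr(ev, "cell")
    rows[[length(rows) + 1L]] <- data.frame(
      method = method, tau_deg = cell$tau_deg, tau_ndeg = cell$tau_ndeg,
      family = family, n_deg = cell$n_deg, n_ndeg = cell$n_ndeg,
      kappa_mean = ev$mean["kappa"], kappa_sd = ev$sd["kappa"],
      ba_mean = ev$mean["balanced_accuracy"], ba_sd = ev$sd["balanced_accuracy"],
      f1_mean = ev$mean["f1_weighted"], auc_mean = ev$mean["auc_weighted"],
      recall_mean = ev$mean["recall_macro"],
      specificity_mean = ev$mean["specificity_macro"],
      evalue = ev$evalue, row.names = NULL)
  }
  do.call(rbind, rows)
}
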
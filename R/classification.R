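#' Rank-statistic AUC
#'
#' Area under the ROC curve computed from the Wilcoxon rank statistic
#' (equivalent to the trapezoidal integral of the empirical ROC curve, with
#' ties handled by midranks).
#'
#' @param scores numeric marker values (larger = more positive-like)
#' @param labels binary labels (logical or 0/1)
#' @return AUC in `[0, 1]`
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) abort("need both classes for an AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# empirical ROC curve (FPR, TPR), thresholds descending
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o]); fp <- cumsum(!labels[o])
  # collapse tied thresholds
  keep <- c(diff(scores[o]) != 0, TRUE)
  tibble(fpr = c(0, fp[keep] / sum(!labels)),
         tpr = c(0, tp[keep] / sum(labels)))
}

#' Combine biomarkers into one score
#'
#' Each marker is z-scored with the supplied (training) mean and sd,
#' oriented so that larger values indicate the positive class on the
#' training data, and the oriented z-scores are summed.  Zero-variance
#' markers are excluded with a warning.
#'
#' @param table data frame of cases by markers
#' @param markers marker column names (>= 2 for a true combination)
#' @param train_table data frame used to estimate means, sds and
#'   orientations (defaults to `table` itself)
#' @param labels binary labels aligned with `train_table` rows
#' @return numeric combined score per row of `table`
#' @export
combine_biomarkers <- function(table, markers, train_table = table,
                               labels = NULL) {
  if (is.null(labels)) labels <- train_table$label
  labels <- as.logical(labels)
  markers <- unique(markers)
  score <- numeric(nrow(table))
  used <- 0
  for (m in markers) {
    x_tr <- train_table[[m]]
    mu <- mean(x_tr); s <- sd(x_tr)
    if (!is.finite(s) || s < 1e-12) {
      warn(sprintf("marker '%s' has zero variance in training data; excluded", m))
      next
    }
    orient <- if (auc_rank(x_tr, labels) >= 0.5) 1 else -1
    score <- score + orient * (table[[m]] - mu) / s
    used <- used + 1
  }
  if (used == 0) abort("no usable markers")
  score
}

#' Cross-validated ROC analysis of biomarkers
#'
#' Stratified seeded k-fold split; per fold, the marker (or the combination
#' fitted on the training cases) is scored on the held-out cases, the
#' orientation being chosen on training data only.  Reports per-fold AUCs,
#' their mean and sd, and the vertically averaged mean ROC curve on a fixed
#' false-positive-rate grid.
#'
#' @param table data frame with one row per case, a logical/0-1 `label`
#'   column, and marker columns
#' @param markers one marker name, or several to combine via
#'   [combine_biomarkers()]
#' @param k_folds folds (default 5)
#' @param seed fold seed
#' @param fpr_grid grid for the mean ROC curve
#' @return object of class `roc_result` with `per_fold` (tibble fold/auc),
#'   `mean_auc`, `sd_auc`, `mean_curve` (tibble fpr/tpr)
#' @export
roc_cv <- function(table, markers, k_folds = 5, seed = 1,
                   fpr_grid = seq(0, 1, by = 0.02)) {
  table <- as_tibble(table)
  if (!"label" %in% names(table)) abort("table needs a `label` column")
  lab <- as.logical(table$label)
  for (m in markers) if (any(is.na(table[[m]])))
    abort(sprintf("marker '%s' has missing values", m))
  if (min(sum(lab), sum(!lab)) < k_folds)
    abort("need at least k_folds cases per class for stratified folding")
  fold <- make_folds(ifelse(lab, "pos", "neg"), k_folds, seed)

  aucs <- numeric(k_folds)
  curves <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- table[fold != f, ]; te <- table[fold == f, ]
    if (length(unique(lab[fold == f])) < 2)
      abort("single-class test fold")
    if (length(markers) == 1) {
      orient <- if (auc_rank(tr[[markers]], lab[fold != f]) >= 0.5) 1 else -1
      sc <- orient * te[[markers]]
    } else {
      sc <- combine_biomarkers(te, markers, train_table = tr,
                               labels = lab[fold != f])
    }
    aucs[f] <- auc_rank(sc, lab[fold == f])
    cv <- roc_curve(sc, lab[fold == f])
    curves[[f]] <- approx(cv$fpr, cv$tpr, xout = fpr_grid, ties = max,
                          yleft = 0, yright = 1)$y
  }
  mc <- rowMeans(do.call(cbind, curves))
  structure(list(per_fold = tibble(fold = seq_len(k_folds), auc = aucs),
                 mean_auc = mean(aucs), sd_auc = sd(aucs),
                 mean_curve = tibble(fpr = fpr_grid, tpr = mc),
                 markers = markers, k_folds = k_folds, seed = seed),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> ", paste(x$markers, collapse = " + "), ": AUC ",
      sprintf("%.3f +/- %.3f", x$mean_auc, x$sd_auc),
      " (", x$k_folds, "-fold CV)\n", sep = "")
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$per_fold

#' @export
glance.roc_result <- function(x, ...) {
  tibble(markers = paste(x$markers, collapse = "+"),
         mean_auc = x$mean_auc, sd_auc = x$sd_auc, k_folds = x$k_folds)
}
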
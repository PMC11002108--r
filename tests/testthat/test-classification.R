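sim_table <- function(n, effect, seed) {
  set.seed(seed)
  tibble::tibble(label = rep(c(TRUE, FALSE), each = n / 2),
                 m1 = rnorm(n) + effect * rep(c(1, 0), each = n / 2),
                 m2 = rnorm(n),
                 m_const = 1)
}

test_that("rank AUC equals the trapezoidal ROC integral on random tables", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    sc <- rnorm(n)
    cv <- lastrain:::roc_curve(sc, lab)
    trapz <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
    expect_equal(auc_rank(sc, lab), trapz, tolerance = 1e-12)
  }
})

test_that("rank AUC matches pROC on a sample problem", {
  skip_if_not_installed("pROC")
  tab <- sim_table(60, 2, seed = 7)
  expect_equal(auc_rank(tab$m1, tab$label),
               as.numeric(pROC::auc(pROC::roc(tab$label, tab$m1,
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("a perfectly separating marker scores AUC 1 in every fold", {
  tab <- sim_table(40, 100, seed = 3)
  res <- roc_cv(tab, "m1", seed = 1)
  expect_true(all(res$per_fold$auc == 1))
  expect_equal(res$mean_auc, 1)
})

test_that("label-independent markers score near 0.5 on 200 cases", {
  # average over ten independent null markers so the check sits several
  # standard errors from its bound
  set.seed(5)
  tab <- tibble::as_tibble(c(list(label = rep(c(TRUE, FALSE), each = 100)),
                             setNames(replicate(10, rnorm(200),
                                                simplify = FALSE),
                                      paste0("null", 1:10))))
  aucs <- vapply(paste0("null", 1:10),
                 function(m) roc_cv(tab, m, seed = 1)$mean_auc, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  expect_true(all(aucs > 0.3 & aucs < 0.7))
})

test_that("marker orientation is handled: negation leaves the AUC unchanged", {
  tab <- sim_table(60, 1.5, seed = 9)
  r1 <- roc_cv(tab, "m1", seed = 2)
  tab$m1 <- -tab$m1
  r2 <- roc_cv(tab, "m1", seed = 2)
  expect_equal(r1$mean_auc, r2$mean_auc, tolerance = 1e-12)
})

test_that("roc_cv is deterministic given table and seed", {
  tab <- sim_table(60, 1, seed = 11)
  r1 <- roc_cv(tab, "m1", seed = 4)
  r2 <- roc_cv(tab, "m1", seed = 4)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$mean_curve, r2$mean_curve)
})

test_that("biomarker combination preserves single-marker ranking", {
  tab <- sim_table(40, 2, seed = 13)
  s1 <- combine_biomarkers(tab, "m1")
  expect_identical(order(s1), order(tab$m1))
  # duplicated marker: same ranking as a single copy
  s2 <- combine_biomarkers(tab, c("m1", "m1"))
  expect_identical(order(s2), order(tab$m1))
  # constant marker excluded with a warning, ranking unchanged
  expect_warning(s3 <- combine_biomarkers(tab, c("m1", "m_const")),
                 "zero variance")
  expect_identical(order(s3), order(tab$m1))
})

test_that("combining an informative with a noise marker still classifies", {
  tab <- sim_table(80, 2, seed = 15)
  rc <- roc_cv(tab, c("m1", "m2"), seed = 1)
  expect_gt(rc$mean_auc, 0.75)
  expect_equal(nrow(rc$per_fold), 5L)
  # mean curve is a valid ROC curve
  expect_true(all(diff(rc$mean_curve$tpr) >= -1e-12))
  expect_equal(range(rc$mean_curve$fpr), c(0, 1))
})

test_that("stratification guards against single-class folds", {
  tab <- sim_table(12, 1, seed = 17)
  tab$label <- c(rep(TRUE, 3), rep(FALSE, 9))
  expect_error(roc_cv(tab, "m1", k_folds = 5), "per class")
})
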
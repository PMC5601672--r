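test_that("fold assignment is balanced, exhaustive and seed-reproducible", {
  assoc <- association_set(sprintf("m%02d", 1:11), rep("d1", 11))
  plan <- kfold_split(assoc, 5, seed = 3)
  sizes <- as.integer(table(plan$assignment$fold))
  expect_length(sizes, 5L)
  expect_lte(diff(range(sizes)), 1L)
  expect_equal(sum(sizes), 11L)
  expect_identical(plan$assignment, kfold_split(assoc, 5, seed = 3)$assignment)

  ten <- association_set(sprintf("m%02d", 1:10), rep("d1", 10))
  expect_equal(as.integer(table(kfold_split(ten, 5, 1)$assignment$fold)),
               rep(2L, 5))
  expect_error(kfold_split(ten, 1, 1), "k must be")
  expect_error(kfold_split(ten, 12, 1), "fewer association pairs")
})

test_that("confusion counts use strictly-greater comparison", {
  scores <- c(a = 0.9, b = 0.2, c = 0.5)
  cc <- confusion_at_threshold(scores, c("a", "b"), 0.4)
  expect_equal(unclass(cc)[c("TP", "FN", "FP", "TN")],
               list(TP = 1L, FN = 1L, FP = 1L, TN = 0L))
  low <- confusion_at_threshold(scores, c("a", "b"), -1)
  expect_equal(low$FN + low$TN, 0L)
  high <- confusion_at_threshold(scores, c("a", "b"), 2)
  expect_equal(high$TP + high$FP, 0L)
  # a score exactly at the threshold is not predicted positive
  at <- confusion_at_threshold(scores, "c", 0.5)
  expect_equal(at$TP, 0L)
})

test_that("TPR and FPR are the exact confusion ratios with named errors", {
  cc <- structure(list(TP = 3L, FP = 0L, TN = 5L, FN = 1L),
                  class = "confusion_counts")
  expect_equal(tpr_fpr(cc), c(tpr = 0.75, fpr = 0))
  no_pos <- structure(list(TP = 0L, FP = 2L, TN = 5L, FN = 0L),
                      class = "confusion_counts")
  expect_error(tpr_fpr(no_pos), "TPR undefined")
  no_neg <- structure(list(TP = 2L, FP = 0L, TN = 0L, FN = 1L),
                      class = "confusion_counts")
  expect_error(tpr_fpr(no_neg), "FPR undefined")
})

test_that("ROC endpoints, monotonicity and degenerate separations hold", {
  perfect <- roc_curve(c(a = 3, b = 2, c = 1, d = 0), c("a", "b"))
  expect_equal(perfect$auc, 1)
  inverted <- roc_curve(c(a = 0, b = 1, c = 2, d = 3), c("a", "b"))
  expect_equal(inverted$auc, 0)
  set.seed(13)
  for (i in 1:50) {
    inst <- random_scores_instance()
    r <- roc_curve(inst$scores, inst$positives)
    expect_equal(r$fpr[1], 0)
    expect_equal(r$tpr[1], 0)
    expect_equal(r$fpr[length(r$fpr)], 1)
    expect_equal(r$tpr[length(r$tpr)], 1)
    expect_true(all(diff(r$fpr) >= 0))
    expect_true(all(diff(r$tpr) >= 0))
  }
  expect_error(roc_curve(c(a = 1, b = 0), character(0)), "no positives")
  expect_error(roc_curve(c(a = 1, b = 0), c("a", "b")), "no negatives")
})

test_that("trapezoidal AUC equals the pairwise-comparison probability", {
  set.seed(29)
  for (i in 1:200) {
    inst <- random_scores_instance()
    r <- roc_curve(inst$scores, inst$positives)
    expect_equal(r$auc, auc_pairwise(inst$scores, inst$positives),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:20) {
    inst <- random_scores_instance(50)
    labels <- as.integer(names(inst$scores) %in% inst$positives)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, unname(inst$scores),
                                          quiet = TRUE, direction = "<")))
    expect_equal(roc_curve(inst$scores, inst$positives)$auc, ref,
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant to candidate order and near 0.5 under the null", {
  set.seed(37)
  inst <- random_scores_instance(80)
  perm <- sample(length(inst$scores))
  expect_equal(roc_curve(inst$scores[perm], inst$positives)$auc,
               roc_curve(inst$scores, inst$positives)$auc)

  aucs <- replicate(100, {
    scores <- stats::setNames(stats::runif(200), sprintf("c%03d", 1:200))
    roc_curve(scores, sample(names(scores), 50))$auc
  })
  expect_gt(mean(aucs), 0.40)
  expect_lt(mean(aucs), 0.60)
})

test_that("cross-validation rebuilds networks without held-out edges", {
  sim <- simulate_rdnet(synth_config(n_mirna = 30, n_disease = 8,
                                     n_modules = 2, seed = 4))
  plan <- kfold_split(sim$associations, 5, seed = 4)
  for (fold in 0:4) {
    train <- training_associations(plan, fold)
    A_train <- build_association_matrix(train, rownames(sim$MM),
                                        rownames(sim$DD))
    held <- plan$assignment[plan$assignment$fold == fold, ]
    expect_true(all(A_train[cbind(held$mirna, held$disease)] == 0))
    # seed vectors place no mass on a held-out miRNA unless training pairs
    # independently support it
    net <- build_hetero_network(sim$MM, sim$DD, A_train)
    for (d in unique(held$disease)) {
      train_pos <- train$pairs$mirna[train$pairs$disease == d]
      if (length(train_pos) == 0) next
      p0 <- seed_vector(d, train, net)
      unsupported <- setdiff(held$mirna[held$disease == d], train_pos)
      expect_true(all(p0[unsupported] == 0))
    }
  }
})

test_that("cross-validation returns per-disease and pooled AUC on planted data", {
  sim <- simulate_rdnet(synth_config(n_mirna = 40, n_disease = 8,
                                     n_modules = 2, seed = 8))
  cv <- suppressWarnings(evaluate_cv(sim$MM, sim$DD, sim$associations,
                                     walk_config(0.7), k = 5, seed = 8))
  expect_s3_class(cv, "cv_result")
  expect_true(all(cv$per_disease$auc >= 0 & cv$per_disease$auc <= 1))
  expect_true(cv$pooled_auc > 0.5)  # planted signal must beat chance
  expect_equal(sort(unique(cv$fold_plan$assignment$fold)), 0:4)
  # pooled AUC is recomputable from the returned score lists
  all_scores <- do.call(rbind, cv$scores)
  r <- roc_curve(stats::setNames(all_scores$score,
                                 sprintf("x%d", seq_len(nrow(all_scores)))),
                 sprintf("x%d", which(all_scores$label == 1)))
  expect_equal(r$auc, cv$pooled_auc)

  # single-disease association set: that disease evaluated in every fold
  one <- association_set(sprintf("m%04d", 1:10), rep("d0001", 10))
  cv1 <- suppressWarnings(evaluate_cv(sim$MM, sim$DD, one, walk_config(0.7),
                                      k = 5, seed = 1))
  expect_equal(nrow(cv1$per_disease), 1L)
  expect_equal(sort(unique(do.call(rbind, cv1$scores)$fold)), 0:4)
})

test_that("evaluation reports round-trip the per-disease and pooled rows", {
  sim <- simulate_rdnet(synth_config(n_mirna = 30, n_disease = 6,
                                     n_modules = 2, seed = 2))
  cv <- suppressWarnings(evaluate_cv(sim$MM, sim$DD, sim$associations,
                                     walk_config(0.7), k = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  roc_path <- withr::local_tempfile(fileext = ".tsv")
  write_cv_report(cv, path, roc_path)
  rep <- utils::read.delim(path)
  expect_equal(names(rep), c("disease", "auc", "n_pos", "n_neg"))
  expect_equal(rep$disease[nrow(rep)], "POOLED")
  expect_equal(rep$auc[nrow(rep)], cv$pooled_auc, tolerance = 1e-6)
  roc <- utils::read.delim(roc_path)
  expect_equal(nrow(roc), length(cv$pooled_roc$fpr))
})
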
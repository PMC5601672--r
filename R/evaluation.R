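# Five-fold cross-validation of the ranking pipeline: fold assignment over
# association pairs, confusion counts at a score threshold, TPR/FPR, ROC
# curves with trapezoidal AUC, and per-disease + pooled aggregation.

#' Assign association pairs to cross-validation folds
#'
#' Uniformly random balanced partition of the known pairs: fold sizes
#' differ by at most one and the assignment is reproducible from `seed`.
#' Pairs (not miRNAs or diseases) are the unit of splitting, matching the
#' protocol of holding out known associations.
#'
#' @param assoc an [association_set()].
#' @param k number of folds (>= 2).
#' @param seed integer RNG seed.
#' @return Object of class `fold_plan`: list with `assignment` (data.frame
#'   `mirna`, `disease`, `fold` in `0..k-1`), `k`, `seed`.
#' @export
kfold_split <- function(assoc, k, seed) {
  stopifnot(inherits(assoc, "association_set"))
  k <- as.integer(k)
  n <- nrow(assoc$pairs)
  if (is.na(k) || k < 2L) stop("k must be >= 2")
  if (n < k) stop("fewer association pairs (", n, ") than folds (", k, ")")
  fold <- with_seed(seed, sample(rep(seq_len(k) - 1L, length.out = n)))
  structure(list(assignment = cbind(assoc$pairs, fold = fold),
                 k = k, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Training associations for one fold
#'
#' Drops the pairs assigned to the held-out fold; what remains rebuilds the
#' network and the seed vectors, so held-out edges leak into neither.
#'
#' @param plan a [kfold_split()] result.
#' @param fold held-out fold index in `0..k-1`.
#' @return An [association_set()] of the training pairs.
#' @export
training_associations <- function(plan, fold) {
  stopifnot(inherits(plan, "fold_plan"))
  keep <- plan$assignment$fold != fold
  if (!any(keep)) stop("fold ", fold, " holds out every pair")
  association_set(plan$assignment$mirna[keep], plan$assignment$disease[keep])
}

#' Confusion counts at a score threshold
#'
#' A candidate counts as predicted-positive when its score is strictly
#' greater than the threshold.
#'
#' @param scores named numeric vector, one score per candidate.
#' @param positives character vector of candidates that are true positives
#'   (must be a subset of `names(scores)`).
#' @param threshold score cut-off.
#' @return List of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at_threshold <- function(scores, positives, threshold) {
  stopifnot(!is.null(names(scores)))
  if (!all(positives %in% names(scores)))
    stop("positives must be a subset of the scored candidates")
  is_pos <- names(scores) %in% positives
  pred <- scores > threshold
  structure(list(TP = sum(pred & is_pos), FP = sum(pred & !is_pos),
                 TN = sum(!pred & !is_pos), FN = sum(!pred & is_pos)),
            class = "confusion_counts")
}

#' True- and false-positive rates from confusion counts
#'
#' `TPR = TP / (TP + FN)` (sensitivity) and `FPR = FP / (FP + TN)`
#' (1 - specificity).
#'
#' @param counts a [confusion_at_threshold()] result.
#' @return Named numeric vector `c(tpr = , fpr = )`.
#' @export
tpr_fpr <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$TP + counts$FN == 0)
    stop("TPR undefined: no positives (TP + FN = 0)")
  if (counts$FP + counts$TN == 0)
    stop("FPR undefined: no negatives (FP + TN = 0)")
  c(tpr = counts$TP / (counts$TP + counts$FN),
    fpr = counts$FP / (counts$FP + counts$TN))
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the threshold over every distinct score value (plus sentinels)
#' to trace the full step curve from (0, 0) to (1, 1); tied scores move as
#' one block, producing the diagonal segment that makes the trapezoidal
#' area equal to the pairwise probability
#' `P(score_pos > score_neg) + 0.5 * P(tie)`.
#'
#' @param scores named numeric vector of candidate scores.
#' @param positives character vector naming the true positives.
#' @return Object of class `roc_result`: list with `fpr`, `tpr` (parallel
#'   non-decreasing sequences) and `auc`.
#' @export
roc_curve <- function(scores, positives) {
  stopifnot(!is.null(names(scores)))
  if (!all(positives %in% names(scores)))
    stop("positives must be a subset of the scored candidates")
  is_pos <- names(scores) %in% positives
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L) stop("ROC undefined: no positives")
  if (n_neg == 0L) stop("ROC undefined: no negatives")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  lab <- is_pos[ord]
  # block boundaries: last index of each distinct score
  last <- which(c(s[-length(s)] != s[-1L], TRUE))
  tp <- cumsum(lab)[last]
  fp <- cumsum(!lab)[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Cross-validated evaluation of the ranking pipeline
#'
#' Runs k-fold cross-validation over the known association pairs. For each
#' fold the network is rebuilt from the training pairs only (held-out
#' edges contribute neither to association edges nor to seed vectors);
#' each query disease is then scored by the random walk, the held-out
#' pairs of that disease are the positives and the miRNAs never associated
#' with it anywhere in the full data are the negatives. Score/label lists
#' are pooled across folds per disease and globally.
#'
#' Diseases with no training positive in a fold are skipped for that fold
#' with a warning; miRNAs held out for the same disease in a *different*
#' fold are neither positive nor negative and are excluded from that
#' disease's candidate list.
#'
#' @param MM,DD miRNA and disease [similarity_matrix()] objects.
#' @param assoc the full [association_set()].
#' @param config a [walk_config()].
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold split.
#' @param tau similarity threshold for network assembly.
#' @param diseases optional character vector restricting evaluation to a
#'   subset of diseases.
#' @return Object of class `cv_result`: list with `per_disease`
#'   (data.frame `disease`, `auc`, `n_pos`, `n_neg`), `pooled_auc`,
#'   `mean_disease_auc`, `scores` (per-disease data.frames of `mirna`,
#'   `score`, `label`, `fold`), `fold_plan`, `config`.
#' @export
evaluate_cv <- function(MM, DD, assoc, config = walk_config(), k = 5L,
                        seed = 1L, tau = 0, diseases = NULL) {
  stopifnot(inherits(assoc, "association_set"))
  plan <- kfold_split(assoc, k, seed)
  mirna_labels <- rownames(MM)
  disease_labels <- rownames(DD)
  ever <- split(assoc$pairs$mirna, assoc$pairs$disease)
  eval_diseases <- if (is.null(diseases)) assoc$disease_labels
                   else intersect(diseases, assoc$disease_labels)
  collected <- list()
  for (fold in seq_len(plan$k) - 1L) {
    train <- training_associations(plan, fold)
    held <- plan$assignment[plan$assignment$fold == fold, , drop = FALSE]
    A_train <- build_association_matrix(train, mirna_labels, disease_labels)
    network <- build_hetero_network(MM, DD, A_train, tau)
    for (d in intersect(eval_diseases, unique(held$disease))) {
      test_pos <- held$mirna[held$disease == d]
      train_pos <- train$pairs$mirna[train$pairs$disease == d]
      if (length(train_pos) == 0L) {
        warning(sprintf("fold %d: disease %s has no training positives; skipped",
                        fold, d))
        next
      }
      negatives <- setdiff(mirna_labels, ever[[d]])
      if (length(negatives) == 0L) next
      p0 <- seed_vector(d, train, network)
      steady <- random_walk(network, p0, config)
      cand <- c(test_pos, negatives)
      collected[[length(collected) + 1L]] <- data.frame(
        disease = d,
        mirna = cand,
        score = unname(steady$values[cand]),
        label = c(rep(1L, length(test_pos)), rep(0L, length(negatives))),
        fold = fold,
        stringsAsFactors = FALSE)
    }
  }
  if (length(collected) == 0L)
    stop("cross-validation produced no evaluable disease/fold combinations")
  all_scores <- do.call(rbind, collected)
  per_disease_scores <- split(all_scores, all_scores$disease)
  per_disease <- do.call(rbind, lapply(per_disease_scores, function(df) {
    if (!any(df$label == 1L) || !any(df$label == 0L)) return(NULL)
    r <- roc_curve(stats::setNames(df$score, paste0("x", seq_len(nrow(df)))),
                   paste0("x", which(df$label == 1L)))
    data.frame(disease = df$disease[1L], auc = r$auc,
               n_pos = sum(df$label == 1L), n_neg = sum(df$label == 0L),
               stringsAsFactors = FALSE)
  }))
  rownames(per_disease) <- NULL
  pooled <- roc_curve(stats::setNames(all_scores$score,
                                      paste0("x", seq_len(nrow(all_scores)))),
                      paste0("x", which(all_scores$label == 1L)))
  structure(list(per_disease = per_disease,
                 pooled_auc = pooled$auc,
                 mean_disease_auc = mean(per_disease$auc),
                 pooled_roc = pooled,
                 scores = per_disease_scores,
                 fold_plan = plan,
                 config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold, pooled AUC = %.4f, mean per-disease AUC = %.4f (%d diseases)\n",
              x$fold_plan$k, x$pooled_auc, x$mean_disease_auc,
              nrow(x$per_disease)))
  invisible(x)
}

#' Write a cross-validation report
#'
#' Per-disease rows `disease  auc  n_pos  n_neg` plus a pooled summary row,
#' tab-delimited. Optionally dumps the pooled ROC points for plotting.
#'
#' @param cv a [evaluate_cv()] result.
#' @param path output TSV path.
#' @param roc_path optional path for a `fpr  tpr` point dump.
#' @export
write_cv_report <- function(cv, path, roc_path = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  lines <- c("disease\tauc\tn_pos\tn_neg",
             sprintf("%s\t%.6f\t%d\t%d", cv$per_disease$disease,
                     cv$per_disease$auc, cv$per_disease$n_pos,
                     cv$per_disease$n_neg),
             sprintf("POOLED\t%.6f\t%d\t%d", cv$pooled_auc,
                     cv$pooled_roc$n_pos, cv$pooled_roc$n_neg))
  writeLines(lines, path)
  if (!is.null(roc_path))
    writeLines(c("fpr\ttpr", sprintf("%.8g\t%.8g", cv$pooled_roc$fpr,
                                     cv$pooled_roc$tpr)), roc_path)
  invisible(path)
}
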
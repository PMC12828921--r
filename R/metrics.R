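#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with midrank tie correction:
#' `AUC = (sum of positive ranks - n1(n1+1)/2) / (n1 * n0)`. Invariant
#' under any strictly monotone transform of the scores.
#'
#' @param probs Numeric scores.
#' @param labels Binary labels (0/1).
#' @return Scalar AUC, or `NA` when only one class is present.
#' @export
auc_score <- function(probs, labels) {
  y <- as.numeric(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

f1_score <- function(decisions, labels) {
  d <- as.numeric(decisions); y <- as.numeric(labels)
  tp <- sum(d == 1 & y == 1); fp <- sum(d == 1 & y == 0); fn <- sum(d == 0 & y == 1)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Per-label and macro classification metrics
#'
#' AUC (rank statistic on the probabilities), F1 and MCC (from the
#' thresholded decisions), exact-match accuracy of the whole 8-bit decision
#' vector, and the majority baseline (frequency of the modal reference
#' vector). Labels with a single observed class have undefined AUC and are
#' excluded from the macro average with a note.
#'
#' @param probs n x L probability matrix.
#' @param decisions n x L binary decision matrix.
#' @param labels n x L binary reference matrix.
#' @return A `classification_metrics` object (list with `per_label`,
#'   `macro`, `exact_match`, `majority_baseline`, `n`).
#' @export
classification_metrics <- function(probs, decisions, labels) {
  P <- as.matrix(probs); Dc <- as.matrix(decisions); L <- as.matrix(labels) * 1
  if (nrow(L) < 2) abort("classification_metrics: need n >= 2")
  lab_names <- colnames(L)
  if (is.null(lab_names)) lab_names <- plan_labels()[seq_len(ncol(L))]
  per_label <- purrr::map_dfr(seq_len(ncol(L)), function(j) {
    tibble(label = lab_names[j],
           auc = auc_score(P[, j], L[, j]),
           f1 = f1_score(Dc[, j], L[, j]),
           mcc = mcc_score(Dc[, j], L[, j]),
           n_pos = sum(L[, j]))
  })
  undefined <- per_label$label[is.na(per_label$auc)]
  macro <- summarise(per_label,
                     auc = mean(.data$auc, na.rm = TRUE),
                     f1 = mean(.data$f1, na.rm = TRUE),
                     mcc = mean(.data$mcc, na.rm = TRUE))
  key <- apply(L, 1, paste0, collapse = "")
  structure(list(per_label = per_label, macro = macro,
                 exact_match = mean(apply(Dc == L, 1, all)),
                 majority_baseline = max(table(key)) / nrow(L),
                 undefined_auc = undefined, n = nrow(L)),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat("<classification_metrics> n =", x$n, "\n")
  print(x$per_label)
  cat(sprintf("  macro AUC %.3f | macro F1 %.3f | macro MCC %.3f\n",
              x$macro$auc, x$macro$f1, x$macro$mcc))
  cat(sprintf("  exact match %.1f%% (majority baseline %.1f%%)\n",
              100 * x$exact_match, 100 * x$majority_baseline))
  if (length(x$undefined_auc)) {
    cat("  AUC undefined (single class):", paste(x$undefined_auc, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.classification_metrics <- function(x, ...) {
  bind_rows(x$per_label,
            bind_cols(tibble(label = "macro"), x$macro,
                      tibble(n_pos = NA_integer_)))
}

#' @export
glance.classification_metrics <- function(x, ...) {
  bind_cols(rename(x$macro, macro_auc = "auc", macro_f1 = "f1",
                   macro_mcc = "mcc"),
            tibble(exact_match = x$exact_match,
                   majority_baseline = x$majority_baseline, n = x$n))
}

#' Dose-regression metrics
#'
#' MAE, RMSE, `R^2 = 1 - SSE/SST` (about the mean of the true doses) and
#' the fraction of predictions within `tolerance` mm.
#'
#' @param pred,true Aligned numeric vectors of doses (mm).
#' @param tolerance Acceptability tolerance, mm.
#' @return One-row tibble `(n, mae, rmse, r2, frac_within)`.
#' @export
regression_metrics <- function(pred, true, tolerance = 0.30) {
  stopifnot(length(pred) == length(true))
  e <- pred - true
  sst <- sum((true - mean(true))^2)
  r2 <- if (sst == 0) {
    warn("regression_metrics: zero-variance truth; R^2 undefined")
    NA_real_
  } else 1 - sum(e^2) / sst
  tibble(n = length(e), mae = mean(abs(e)), rmse = sqrt(mean(e^2)),
         r2 = r2, frac_within = mean(abs(e) <= tolerance))
}

#' Bland-Altman agreement summary
#'
#' Differences `d = pred - true`; bias is their mean and the 95% limits of
#' agreement are `bias +/- 1.96 * SD(d)` (sample SD).
#'
#' @param pred,true Aligned numeric vectors.
#' @return One-row tibble `(bias, loa_lower, loa_upper, sd_diff, n)`.
#' @export
bland_altman <- function(pred, true) {
  stopifnot(length(pred) == length(true), length(pred) >= 2)
  d <- pred - true
  s <- sd(d)
  tibble(bias = mean(d), loa_lower = mean(d) - 1.96 * s,
         loa_upper = mean(d) + 1.96 * s, sd_diff = s, n = length(d))
}

#' Tiered whole-plan agreement
#'
#' Tier 1: identical decision vector and every operated dose within the
#' planning quantum (surgeons plan in 0.5 mm steps). Tier 2: identical
#' decision vector, exactly one operated muscle deviating by more than the
#' quantum but at most `tier2_max` mm, all others within the quantum.
#' "Clinically acceptable" is tier 1 + tier 2. The majority baseline is the
#' frequency of the modal reference decision vector.
#'
#' @param decisions n x 8 predicted decision matrix.
#' @param doses_pred n x 8 predicted dose matrix (mm).
#' @param labels n x 8 reference label matrix.
#' @param doses_true n x 8 reference dose matrix (mm).
#' @param quantum Dose rounding quantum, mm.
#' @param tier2_max Tier-2 dose deviation cap, mm.
#' @return One-row tibble `(n, tier1, tier2, acceptable,
#'   exact_decision_match, majority_baseline)`; rates are fractions.
#' @export
plan_agreement <- function(decisions, doses_pred, labels, doses_true,
                           quantum = 0.5, tier2_max = 1) {
  Dc <- as.matrix(decisions) * 1; L <- as.matrix(labels) * 1
  Dp <- as.matrix(doses_pred); Dt <- as.matrix(doses_true)
  n <- nrow(L)
  dec_match <- apply(Dc == L, 1, all)
  dev <- abs(Dp - Dt)
  dev[L == 0] <- 0                       # only operated slots count
  n_over_q <- rowSums(dev > quantum)
  n_over_max <- rowSums(dev > tier2_max)
  in_tier1 <- dec_match & n_over_q == 0
  in_tier2 <- dec_match & n_over_q == 1 & n_over_max == 0
  key <- apply(L, 1, paste0, collapse = "")
  tibble(n = n, tier1 = mean(in_tier1), tier2 = mean(in_tier2),
         acceptable = mean(in_tier1 | in_tier2),
         exact_decision_match = mean(dec_match),
         majority_baseline = max(table(key)) / n)
}

#' Decision-curve analysis
#'
#' Net benefit at threshold probability `p_t`:
#' `NB = TP/n - (FP/n) * p_t / (1 - p_t)` with decisions `p >= p_t`;
#' compared against treating every muscle (all-positive) and none
#' (NB = 0).
#'
#' @param probs Pooled predicted probabilities.
#' @param labels Pooled binary labels.
#' @param thresholds Grid of threshold probabilities in (0, 1); values at
#'   or above 1 are dropped.
#' @return Tibble `(threshold, nb_model, nb_all, nb_none)`.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  y <- as.numeric(labels)
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  n <- length(y)
  purrr::map_dfr(thresholds, function(pt) {
    w <- pt / (1 - pt)
    d <- probs >= pt
    tibble(threshold = pt,
           nb_model = sum(d & y == 1) / n - sum(d & y == 0) / n * w,
           nb_all = sum(y == 1) / n - sum(y == 0) / n * w,
           nb_none = 0)
  })
}

#' Metrics stratified by subgroup
#'
#' Recomputes the classification and dose metrics within each level of
#' `group` (typically strabismus type) and reports the absolute gap
#' between the two largest groups per metric.
#'
#' @param probs,decisions,labels n x 8 matrices as in
#'   [classification_metrics()].
#' @param doses_pred,doses_true n x 8 dose matrices (mm).
#' @param group Length-n grouping vector.
#' @param dose_tolerance Tolerance for `frac_within`, mm.
#' @return Tibble with one row per group plus a `"gap"` row of absolute
#'   differences.
#' @export
subgroup_report <- function(probs, decisions, labels, doses_pred, doses_true,
                            group, dose_tolerance = 0.30) {
  group <- as.character(group)
  levels <- names(sort(table(group), decreasing = TRUE))
  if (length(levels) < 2) warn("subgroup_report: fewer than two subgroups")
  rows <- purrr::map_dfr(levels, function(g) {
    i <- which(group == g)
    if (length(i) < 2) {
      warn(paste0("subgroup_report: stratum `", g, "` too small; skipped"))
      return(tibble())
    }
    cm <- classification_metrics(probs[i, , drop = FALSE],
                                 decisions[i, , drop = FALSE],
                                 labels[i, , drop = FALSE])
    op <- as.matrix(labels)[i, , drop = FALSE] == 1
    rm_op <- regression_metrics(as.matrix(doses_pred)[i, , drop = FALSE][op],
                                as.matrix(doses_true)[i, , drop = FALSE][op],
                                tolerance = dose_tolerance)
    tibble(group = g, n = length(i), macro_auc = cm$macro$auc,
           macro_f1 = cm$macro$f1, macro_mcc = cm$macro$mcc,
           exact_match = cm$exact_match,
           mae_operated = rm_op$mae, rmse_operated = rm_op$rmse)
  })
  if (nrow(rows) >= 2) {
    gap <- rows[1, ] %>%
      mutate(group = "gap", n = NA_integer_,
             across(c("macro_auc", "macro_f1", "macro_mcc", "exact_match",
                      "mae_operated", "rmse_operated"),
                    ~ abs(rows[[dplyr::cur_column()]][1] -
                            rows[[dplyr::cur_column()]][2])))
    rows <- bind_rows(rows, gap)
  }
  rows
}

#' Permutation feature importance
#'
#' Model-agnostic attribution: each feature column is permuted `n_repeats`
#' times and the degradation of the evaluation metric (macro-AUC for the
#' selection head, operated-muscle dose MAE for the regression head) is
#' recorded. Larger degradation = more important feature.
#'
#' @param fit A fitted `strabnet_fit`.
#' @param features Tibble/matrix of standardised features.
#' @param labels n x 8 reference label matrix.
#' @param doses n x 8 reference dose matrix (mm).
#' @param metric `"macro_auc"` or `"dose_mae"`.
#' @param n_repeats Permutations per feature.
#' @param seed Integer seed.
#' @return Tibble `(feature, importance_mean, importance_sd)` sorted by
#'   descending mean importance, with the baseline metric as attribute
#'   `baseline`.
#' @export
permutation_importance <- function(fit, features, labels, doses,
                                   metric = c("macro_auc", "dose_mae"),
                                   n_repeats = 5L, seed = 1L) {
  metric <- match.arg(metric)
  if (n_repeats < 1) abort("permutation_importance: n_repeats must be >= 1")
  X <- as_feature_matrix(features)
  L <- as.matrix(labels) * 1; D <- as.matrix(doses)
  score <- function(Xm) {
    pr <- predict(fit, Xm)
    if (metric == "macro_auc") {
      P <- as.matrix(pr[paste0("prob_", plan_labels())])
      mean(purrr::map_dbl(1:8, ~ auc_score(P[, .x], L[, .x])), na.rm = TRUE)
    } else {
      DH <- as.matrix(pr[paste0("dose_", plan_labels())])
      mean(abs(DH[L == 1] - D[L == 1]))
    }
  }
  baseline <- score(X)
  sign <- if (metric == "macro_auc") 1 else -1   # degradation is always >= 0-ish
  out <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(ncol(X)), function(j) {
      deg <- purrr::map_dbl(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, j] <- X[sample.int(nrow(X)), j]
        sign * (baseline - score(Xp))
      })
      tibble(feature = colnames(X)[j],
             importance_mean = mean(deg), importance_sd = sd(deg))
    })
  })
  out <- arrange(out, dplyr::desc(.data$importance_mean))
  attr(out, "baseline") <- baseline
  attr(out, "metric") <- metric
  out
}
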
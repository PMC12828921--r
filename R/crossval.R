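#' Multilabel-stratified k-fold assignment with a prevalence certificate
#'
#' Iterative stratification (rarest-label-first): repeatedly take the label
#' with the fewest unassigned positive cases and deal its cases to the
#' eligible fold (capacity not exhausted, so fold sizes differ by at most
#' one) where that label is most under-represented, breaking ties by fold
#' fill and then by seeded randomness. The certificate records, for every
#' (fold, label) cell, the absolute difference between the fold prevalence
#' and the overall prevalence in percentage points; if its maximum exceeds
#' `tolerance`, the split is retried with derived sub-seeds up to
#' `retry_budget` times and the best split found is returned (with a
#' warning flag if still above tolerance).
#'
#' @param labels n x L binary matrix (or tibble) of labels.
#' @param k Number of folds (2 <= k <= n).
#' @param tolerance Maximum acceptable certificate value, percentage points.
#' @param seed Integer seed.
#' @param retry_budget Maximum number of re-splits.
#' @return A `fold_spec`: tibble `(row, fold)` with attributes
#'   `certificate` (tibble `fold`, `label`, `deviation_pp`), `max_deviation_pp`,
#'   `k`, `within_tolerance`.
#' @export
multilabel_stratified_kfold <- function(labels, k, tolerance = 2, seed = 1L,
                                        retry_budget = 50L) {
  L <- as.matrix(labels) * 1
  n <- nrow(L)
  if (k < 2) abort("multilabel_stratified_kfold: k must be >= 2")
  if (n < k) abort("multilabel_stratified_kfold: need n >= k")

  best <- NULL
  for (attempt in seq_len(max(1L, retry_budget))) {
    assign <- stratify_once(L, k, derive_seed(seed, attempt))
    assign <- refine_assignment(assign, L, tolerance,
                                seed = derive_seed(seed, attempt, 99L))
    cert <- fold_certificate(assign, L)
    mx <- max(cert$deviation_pp)
    if (is.null(best) || mx < best$mx) best <- list(assign = assign, cert = cert, mx = mx)
    if (mx <= tolerance) break
  }
  ok <- best$mx <= tolerance
  if (!ok) {
    warn(sprintf(paste0("multilabel_stratified_kfold: certificate maximum ",
                        "%.2f pp exceeds tolerance %.2f pp after %d attempts"),
                 best$mx, tolerance, retry_budget))
  }
  out <- tibble(row = seq_len(n), fold = best$assign)
  structure(out, certificate = best$cert, max_deviation_pp = best$mx,
            k = k, within_tolerance = ok,
            class = c("fold_spec", class(out)))
}

stratify_once <- function(L, k, seed) {
  n <- nrow(L); nl <- ncol(L)
  withr::with_seed(seed, {
    cap <- rep(floor(n / k), k)
    extra <- n %% k
    if (extra > 0) {                # remainder rows go to a random fold subset
      bump <- sample.int(k, extra)
      cap[bump] <- cap[bump] + 1
    }
    desired <- outer(colSums(L) / n, cap)          # nl x k desired label counts
    assign <- rep(NA_integer_, n)
    remaining <- rep(TRUE, n)
    repeat {
      pos_left <- colSums(L[remaining, , drop = FALSE])
      if (all(pos_left == 0) || !any(remaining)) break
      l <- which(pos_left == min(pos_left[pos_left > 0]) & pos_left > 0)[1]
      rows <- which(remaining & L[, l] == 1)
      rows <- rows[sample.int(length(rows))]
      for (r in rows) {
        elig <- which(cap > 0)
        d <- desired[l, elig]
        elig <- elig[d == max(d)]
        if (length(elig) > 1) {                    # tie: most room left
          elig <- elig[cap[elig] == max(cap[elig])]
          if (length(elig) > 1) elig <- elig[sample.int(length(elig), 1)]
        }
        f <- elig[1]
        assign[r] <- f
        remaining[r] <- FALSE
        cap[f] <- cap[f] - 1
        desired[, f] <- desired[, f] - L[r, ]
      }
    }
    for (r in which(remaining)) {                  # label-free rows
      elig <- which(cap == max(cap))
      f <- if (length(elig) > 1) elig[sample.int(length(elig), 1)] else elig
      assign[r] <- f
      cap[f] <- cap[f] - 1
    }
    assign
  })
}

# Local-search refinement: greedily swap patients between the fold where a
# label is most over-represented and one where it is under-represented,
# keeping fold sizes fixed, until the certificate maximum is within
# tolerance or no improving swap is found.
refine_assignment <- function(assign, L, tolerance, seed, max_swaps = 400L) {
  k <- max(assign)
  n_f <- tabulate(assign, k)
  C <- t(sapply(seq_len(k), function(f) colSums(L[assign == f, , drop = FALSE])))
  p <- colMeans(L)
  devmat <- function(C) abs(sweep(C / n_f, 2, p)) * 100
  obj <- function(D) c(max(D), sum(D^2))
  better <- function(a, b) a[1] < b[1] - 1e-12 ||
    (abs(a[1] - b[1]) < 1e-12 && a[2] < b[2] - 1e-12)

  withr::with_seed(seed, {
    for (it in seq_len(max_swaps)) {
      D <- devmat(C)
      cur <- obj(D)
      if (cur[1] <= tolerance) break
      worst <- which(D == max(D), arr.ind = TRUE)[1, ]
      f <- worst[1]; j <- worst[2]
      excess <- C[f, j] / n_f[f] > p[j]
      # donors hold label j in the over-represented fold (or lack it in the
      # under-represented one); receivers are the opposite
      if (excess) {
        cand_a <- which(assign == f & L[, j] == 1)
        g_ord <- order(C[, j] / n_f - p[j])
      } else {
        cand_a <- which(assign == f & L[, j] == 0)
        g_ord <- order(-(C[, j] / n_f - p[j]))
      }
      g_ord <- setdiff(g_ord, f)
      found <- FALSE
      for (g in g_ord[1:min(3, length(g_ord))]) {
        cand_b <- if (excess) which(assign == g & L[, j] == 0) else which(assign == g & L[, j] == 1)
        if (length(cand_a) == 0 || length(cand_b) == 0) next
        aa <- sample(cand_a, min(12, length(cand_a)))
        bb <- sample(cand_b, min(12, length(cand_b)))
        best_sw <- NULL
        for (a in aa) for (b in bb) {
          C2 <- C
          C2[f, ] <- C2[f, ] - L[a, ] + L[b, ]
          C2[g, ] <- C2[g, ] + L[a, ] - L[b, ]
          o2 <- obj(devmat(C2))
          if (better(o2, cur) && (is.null(best_sw) || better(o2, best_sw$o))) {
            best_sw <- list(a = a, b = b, g = g, C = C2, o = o2)
          }
        }
        if (!is.null(best_sw)) {
          assign[best_sw$a] <- best_sw$g
          assign[best_sw$b] <- f
          C <- best_sw$C
          found <- TRUE
          break
        }
      }
      if (!found) break
    }
  })
  assign
}

#' Recompute the prevalence certificate of a fold assignment
#'
#' @param assignment Integer fold index per row.
#' @param labels n x L binary matrix.
#' @return Tibble `(fold, label, deviation_pp)`: absolute difference between
#'   fold and overall prevalence, in percentage points.
#' @export
fold_certificate <- function(assignment, labels) {
  L <- as.matrix(labels) * 1
  overall <- colMeans(L)
  lab_names <- colnames(L)
  if (is.null(lab_names)) lab_names <- paste0("label", seq_len(ncol(L)))
  purrr::map_dfr(sort(unique(assignment)), function(f) {
    prev <- colMeans(L[assignment == f, , drop = FALSE])
    tibble(fold = f, label = lab_names,
           deviation_pp = abs(prev - overall) * 100)
  })
}

#' @export
print.fold_spec <- function(x, ...) {
  cat("<fold_spec> k =", attr(x, "k"),
      "| certificate max =", sprintf("%.2f pp", attr(x, "max_deviation_pp")),
      if (isTRUE(attr(x, "within_tolerance"))) "(within tolerance)" else "(ABOVE tolerance)",
      "\n")
  NextMethod()
}

#' Write fold indices to CSV
#' @param folds A `fold_spec`.
#' @param path File path.
#' @export
write_folds <- function(folds, path) {
  readr::write_csv(as_tibble(folds), path)
  invisible(path)
}

# ---- cross-validated pipeline ----------------------------------------------

#' Run leakage-free multilabel-stratified cross-validation
#'
#' For each outer fold: preprocessing statistics are fitted on the training
#' rows only; the training rows are further split (multilabel-stratified)
#' into an inner training set and an inner validation set; the network is
#' trained on the inner training set with early stopping on the inner
#' validation loss; temperature and beta calibration and the MCC-optimal
#' thresholds are fitted on the inner validation predictions (out-of-sample
#' with respect to the network weights); finally the calibrated model
#' predicts the held-out outer fold. Every patient is predicted exactly
#' once out-of-fold. All seeds derive deterministically from `seed`.
#'
#' @param cohort Cohort tibble (see [simulate_cohort()] for the schema).
#' @param config A [model_config()].
#' @param k Number of outer folds.
#' @param seed Integer seed.
#' @param tolerance Stratification certificate tolerance (percentage
#'   points).
#' @param inner_k The training fold is split 1/`inner_k` for the inner
#'   validation set.
#' @param calib_min_positives Labels with fewer inner-validation positives
#'   share a pooled calibration.
#' @return A `strabnet_cv` object: `oof` (out-of-fold predictions:
#'   `patient_id`, `fold`, raw `rawprob_*`, calibrated `prob_*`, `dec_*`,
#'   `dosehat_*`), `folds` (the `fold_spec`), `fold_artifacts` (per fold:
#'   preprocessing stats, calibration, thresholds, fit summary, row
#'   provenance), `config`, `seed`.
#' @export
run_cv <- function(cohort, config = model_config(), k = 10L, seed = 1L,
                   tolerance = 2, inner_k = 5L, calib_min_positives = 20L) {
  L <- as_label_matrix(cohort)
  D <- as_label_matrix(cohort, dose_cols())
  folds <- multilabel_stratified_kfold(L, k, tolerance = tolerance,
                                       seed = derive_seed(seed, 1L))
  assign <- folds$fold

  oof <- vector("list", k)
  artifacts <- vector("list", k)
  for (f in seq_len(k)) {
    va <- which(assign == f)
    tr <- which(assign != f)
    # inner split for early stopping + calibration + thresholds
    if (length(tr) >= 2 * inner_k) {
      inner <- multilabel_stratified_kfold(L[tr, , drop = FALSE], inner_k,
                                           tolerance = 100,
                                           seed = derive_seed(seed, 2L, f),
                                           retry_budget = 1L)
      cal_local <- which(inner$fold == 1L)
    } else {
      cal_local <- seq_len(max(1L, floor(length(tr) / inner_k)))
    }
    tr_in <- tr[-cal_local]
    tr_cal <- tr[cal_local]

    prep <- fit_preprocess(cohort[tr, , drop = FALSE])
    Xin <- apply_preprocess(cohort[tr_in, , drop = FALSE], prep)
    Xcal <- apply_preprocess(cohort[tr_cal, , drop = FALSE], prep)
    Xva <- apply_preprocess(cohort[va, , drop = FALSE], prep)

    cfg <- config
    cfg$seed <- derive_seed(seed, 3L, f)
    fit <- fit_strabnet(Xin, L[tr_in, , drop = FALSE], D[tr_in, , drop = FALSE],
                        Xcal, L[tr_cal, , drop = FALSE], D[tr_cal, , drop = FALSE],
                        config = cfg)

    pred_cal <- predict(fit, Xcal)
    logits_cal <- as.matrix(pred_cal[paste0("logit_", plan_labels())])
    calibration <- fit_calibration(logits_cal, L[tr_cal, , drop = FALSE],
                                   min_positives = calib_min_positives)
    probs_cal <- apply_calibration(logits_cal, calibration)
    thresholds <- optimise_thresholds(probs_cal, L[tr_cal, , drop = FALSE])

    pred_va <- predict(fit, Xva)
    logits_va <- as.matrix(pred_va[paste0("logit_", plan_labels())])
    raw_va <- sigmoid(logits_va)
    cprobs_va <- apply_calibration(logits_va, calibration)
    doses_va <- as.matrix(pred_va[paste0("dose_", plan_labels())])
    plan <- assemble_plan(cprobs_va, doses_va, thresholds)

    colnames(raw_va) <- paste0("rawprob_", plan_labels())
    rawdose_va <- doses_va
    colnames(rawdose_va) <- paste0("rawdose_", plan_labels())
    oof[[f]] <- bind_cols(
      tibble(patient_id = cohort$patient_id[va], fold = f),
      as_tibble(raw_va), as_tibble(rawdose_va), plan
    )
    artifacts[[f]] <- list(prep = prep, calibration = calibration,
                           thresholds = thresholds, fit_summary = glance(fit),
                           best_epoch = fit$best_epoch,
                           idx_train = tr, idx_inner_train = tr_in,
                           idx_calibration = tr_cal, idx_validation = va)
  }
  oof <- bind_rows(oof) %>% arrange(.data$patient_id)
  structure(list(oof = oof, folds = folds, fold_artifacts = artifacts,
                 config = config, seed = seed,
                 n_params = strabnet_n_params(config, length(strabnet_features()))),
            class = "strabnet_cv")
}

#' @export
print.strabnet_cv <- function(x, ...) {
  cat("<strabnet_cv>", attr(x$folds, "k"), "folds,",
      nrow(x$oof), "out-of-fold predictions,",
      x$n_params, "model parameters\n")
  cat("  stratification certificate max:",
      sprintf("%.2f pp\n", attr(x$folds, "max_deviation_pp")))
  invisible(x)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples rows (patients) with replacement `B` times, recomputes the
#' statistic, and takes the 2.5/97.5 percentiles (for `conf = 0.95`). A
#' resample on which the statistic is undefined (error or `NA`, e.g. a
#' single-class AUC) is redrawn and counted.
#'
#' @param data Data frame (resampled by row) or vector.
#' @param statistic Function `data -> scalar`.
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return Tibble `(point, lower, upper, B, n_redrawn)`.
#' @export
bootstrap_ci <- function(data, statistic, B = 1000L, seed = 1L, conf = 0.95) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n == 0) abort("bootstrap_ci: empty data")
  if (B < 1) abort("bootstrap_ci: B must be >= 1")
  take <- function(d, idx) if (is.data.frame(d)) d[idx, , drop = FALSE] else d[idx]
  point <- statistic(data)
  redrawn <- 0L
  stats_out <- numeric(B)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      val <- NA_real_
      for (try in 1:100) {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(statistic(take(data, idx)), error = function(e) NA_real_)
        if (is.finite(val)) break
        redrawn <- redrawn + 1L
      }
      stats_out[b] <- val
    }
  })
  alpha <- (1 - conf) / 2
  qs <- quantile(stats_out, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  tibble(point = point, lower = qs[1], upper = qs[2], B = B,
         n_redrawn = redrawn)
}
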
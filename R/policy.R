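#' MCC-optimal per-label decision thresholds
#'
#' For each label, scans the midpoints between consecutive sorted unique
#' calibrated probabilities (plus the all-positive and all-negative
#' cut-points) and keeps the threshold maximising the Matthews correlation
#' coefficient of the decision `p >= tau`. Ties break toward the higher
#' threshold (fewer positive calls). Labels with a single observed class
#' fall back to `tau = 0.5` with a flag.
#'
#' @param probs n x 8 matrix of calibrated probabilities.
#' @param labels n x 8 binary matrix.
#' @return A `threshold_set`: tibble with `label`, `threshold`, `mcc`,
#'   `fallback`.
#' @export
optimise_thresholds <- function(probs, labels) {
  probs <- as.matrix(probs); labels <- as.matrix(labels)
  out <- purrr::map_dfr(seq_len(ncol(probs)), function(j) {
    p <- probs[, j]; y <- labels[, j]
    if (length(unique(y)) < 2) {
      return(tibble(label = plan_labels()[j], threshold = 0.5,
                    mcc = NA_real_, fallback = TRUE))
    }
    u <- sort(unique(p))
    cand <- c(u[1] / 2, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
              (u[length(u)] + 1) / 2)
    scores <- purrr::map_dbl(cand, ~ mcc_score(p >= .x, y))
    best <- max(scores)
    tau <- max(cand[scores >= best - 1e-12])   # tie -> higher threshold
    tibble(label = plan_labels()[j], threshold = tau, mcc = best,
           fallback = FALSE)
  })
  class(out) <- c("threshold_set", class(out))
  out
}

#' Matthews correlation coefficient of binary decisions
#'
#' @param decisions Logical/0-1 vector of predicted decisions.
#' @param labels Binary reference labels.
#' @return Scalar in `[-1, 1]`; 0 when a confusion-matrix margin is empty.
#' @export
mcc_score <- function(decisions, labels) {
  d <- as.numeric(decisions); y <- as.numeric(labels)
  tp <- sum(d == 1 & y == 1); tn <- sum(d == 0 & y == 0)
  fp <- sum(d == 1 & y == 0); fn <- sum(d == 0 & y == 1)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  clamp((tp * tn - fp * fn) / den, -1, 1)   # guard fp rounding past +/-1
}

#' Resolve recession/resection conflicts into a feasible plan
#'
#' A muscle can be recessed or resected, never both. For each of the four
#' muscle pairs, if both members are selected the higher-probability label
#' prevails and the alternative's decision and dose are zeroed (an exact
#' probability tie keeps the recession). Doses of all unselected labels are
#' set to 0; a selected label's dose is kept inside the feasible 0.5-10 mm
#' range (a dose below the minimum is floored at 0.5 mm and flagged).
#'
#' @param decisions n x 8 binary matrix of threshold decisions.
#' @param probs n x 8 matrix of calibrated probabilities.
#' @param doses n x 8 matrix of predicted doses (mm).
#' @return A tibble with `dec_*`, `prob_*` and `dosehat_*` columns plus
#'   `n_dose_floored`, satisfying the feasibility invariants.
#' @export
resolve_conflicts <- function(decisions, probs, doses) {
  Dc <- as.matrix(decisions) * 1; P <- as.matrix(probs); Dm <- as.matrix(doses)
  for (pair in muscle_pairs()) {
    rec <- pair[1]; res <- pair[2]
    both <- Dc[, rec] == 1 & Dc[, res] == 1
    if (any(both)) {
      keep_res <- both & (P[, res] > P[, rec])    # tie keeps recession
      Dc[both & !keep_res, res] <- 0
      Dc[keep_res, rec] <- 0
    }
  }
  Dm[Dc == 0] <- 0
  floored <- Dc == 1 & Dm < 0.5
  Dm[floored] <- 0.5
  Dm[Dc == 1 & Dm > 10] <- 10
  colnames(Dc) <- paste0("dec_", plan_labels())
  colnames(P) <- paste0("prob_", plan_labels())
  colnames(Dm) <- paste0("dosehat_", plan_labels())
  out <- bind_cols(as_tibble(P), as_tibble(Dc), as_tibble(Dm))
  out$n_dose_floored <- rowSums(floored)
  out
}

#' Assemble a feasible surgical plan from calibrated outputs
#'
#' Thresholds probabilities (`p >= tau`, inclusive), then applies
#' [resolve_conflicts()]. Idempotent: re-assembling an assembled plan with
#' the same thresholds changes nothing.
#'
#' @param probs n x 8 matrix of calibrated probabilities.
#' @param doses n x 8 matrix of predicted doses (mm).
#' @param thresholds A [optimise_thresholds()] `threshold_set` (or numeric
#'   vector of 8 thresholds).
#' @return Plan tibble as returned by [resolve_conflicts()].
#' @export
assemble_plan <- function(probs, doses, thresholds) {
  tau <- if (is.data.frame(thresholds)) thresholds$threshold else as.numeric(thresholds)
  stopifnot(length(tau) == ncol(as.matrix(probs)))
  P <- as.matrix(probs)
  Dc <- sweep(P, 2, tau, ">=") * 1
  resolve_conflicts(Dc, P, as.matrix(doses))
}
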
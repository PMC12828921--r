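#' Fit a temperature-scaling parameter
#'
#' Finds the scalar `T > 0` minimising the negative log-likelihood of
#' `sigmoid(logit / T)` against binary labels, by 1-D bounded optimisation
#' on `[0.05, 20]`. Dividing logits by a positive constant is strictly
#' monotone, so temperature scaling never changes the probability ranking.
#'
#' @param logits Numeric vector of raw logits.
#' @param labels Binary labels (0/1).
#' @return Fitted temperature (scalar).
#' @export
fit_temperature <- function(logits, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) {
    abort("fit_temperature: both classes must be present")
  }
  nll <- function(T) {
    p <- clamp(plogis(logits / T), 1e-12, 1 - 1e-12)
    -sum(labels * log(p) + (1 - labels) * log(1 - p))
  }
  optimize(nll, interval = c(0.05, 20), tol = 1e-6)$minimum
}

#' Apply temperature scaling
#' @param logits Raw logits.
#' @param temperature Fitted temperature.
#' @return Calibrated probabilities.
#' @export
temperature_scale <- function(logits, temperature) plogis(logits / temperature)

#' Fit a beta-calibration map
#'
#' Fits the three-parameter family
#' `m(p) = sigmoid(c + a*log(p) - b*log(1 - p))` by logistic regression of
#' the labels on features `(log p, -log(1 - p))`. Non-negativity of `a` and
#' `b` (which makes the map monotone) is enforced by dropping a feature
#' whose coefficient comes out negative and refitting. `(a, b, c) =
#' (1, 1, 0)` is the identity map.
#'
#' @param probs Probabilities in (0, 1) (clamped internally).
#' @param labels Binary labels (0/1).
#' @return A `beta_calibration` object: list with `a`, `b`, `c`.
#' @export
fit_beta_calibration <- function(probs, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) {
    abort("fit_beta_calibration: both classes must be present")
  }
  p <- clamp(probs, 1e-6, 1 - 1e-6)
  if (diff(range(p)) < 1e-12) {
    warn("fit_beta_calibration: degenerate (constant) probabilities; identity map returned")
    return(structure(list(a = 1, b = 1, c = 0), class = "beta_calibration"))
  }
  x1 <- log(p); x2 <- -log(1 - p)
  fit <- suppressWarnings(glm(labels ~ x1 + x2, family = binomial()))
  a <- unname(coef(fit)["x1"]); b <- unname(coef(fit)["x2"]); cc <- unname(coef(fit)[1])
  if (is.na(a) || a < 0) {
    fit <- suppressWarnings(glm(labels ~ x2, family = binomial()))
    a <- 0; b <- unname(coef(fit)["x2"]); cc <- unname(coef(fit)[1])
  }
  if (is.na(b) || b < 0) {
    fit <- suppressWarnings(glm(labels ~ x1, family = binomial()))
    x1b <- unname(coef(fit)["x1"])
    a <- if (is.na(x1b) || x1b < 0) 0 else x1b
    b <- 0; cc <- unname(coef(fit)[1])
  }
  if (a == 0 && b == 0) {
    # both slopes rejected (no usable signal): keep the map strictly
    # monotone by falling back to an intercept-shifted identity
    off <- x1 + x2   # = logit(p)
    fit <- suppressWarnings(glm(labels ~ 1 + offset(off), family = binomial()))
    a <- 1; b <- 1; cc <- unname(coef(fit)[1])
  }
  structure(list(a = a, b = b, c = cc), class = "beta_calibration")
}

#' Apply a beta-calibration map
#' @param probs Probabilities in (0, 1).
#' @param params A `beta_calibration` (or list with `a`, `b`, `c`).
#' @return Calibrated probabilities.
#' @export
beta_calibrate <- function(probs, params) {
  p <- clamp(probs, 1e-6, 1 - 1e-6)
  plogis(params$c + params$a * log(p) - params$b * log(1 - p))
}

#' @export
print.beta_calibration <- function(x, ...) {
  cat(sprintf("<beta_calibration> a = %.4f, b = %.4f, c = %.4f\n", x$a, x$b, x$c))
  invisible(x)
}

# Fit the full per-label calibration stack (temperature, then beta on the
# temperature-scaled output) on held-out logits. Labels with fewer than
# `min_positives` positives (or a single class) share a pooled calibration
# fitted across all labels.
fit_calibration <- function(logits, labels, min_positives = 20L) {
  stopifnot(is.matrix(logits), is.matrix(labels), ncol(logits) == ncol(labels))
  pool_T <- tryCatch(fit_temperature(as.vector(logits), as.vector(labels)),
                     error = function(e) 1)
  pool_beta <- tryCatch(
    fit_beta_calibration(temperature_scale(as.vector(logits), pool_T),
                         as.vector(labels)),
    error = function(e) structure(list(a = 1, b = 1, c = 0),
                                  class = "beta_calibration"))
  per_label <- purrr::map(seq_len(ncol(logits)), function(j) {
    y <- labels[, j]
    if (sum(y) < min_positives || sum(1 - y) < 1 || length(unique(y)) < 2) {
      return(list(temperature = pool_T, beta = pool_beta, pooled = TRUE))
    }
    T_j <- fit_temperature(logits[, j], y)
    b_j <- fit_beta_calibration(temperature_scale(logits[, j], T_j), y)
    list(temperature = T_j, beta = b_j, pooled = FALSE)
  })
  structure(list(per_label = per_label, pool_temperature = pool_T,
                 pool_beta = pool_beta), class = "strabnet_calibration")
}

# Apply the calibration stack to a logit matrix.
apply_calibration <- function(logits, calibration) {
  out <- logits
  for (j in seq_len(ncol(logits))) {
    cl <- calibration$per_label[[j]]
    out[, j] <- beta_calibrate(temperature_scale(logits[, j], cl$temperature),
                               cl$beta)
  }
  out
}

#' @export
tidy.strabnet_calibration <- function(x, ...) {
  purrr::map_dfr(seq_along(x$per_label), function(j) {
    cl <- x$per_label[[j]]
    tibble(label = plan_labels()[j], temperature = cl$temperature,
           beta_a = cl$beta$a, beta_b = cl$beta$b, beta_c = cl$beta$c,
           pooled = cl$pooled)
  })
}

#' Expected calibration error over equal-count bins
#'
#' Splits predictions into `n_bins` equal-count (decile) bins by predicted
#' probability and returns the count-weighted mean absolute gap between the
#' bin's mean predicted probability and its observed event rate.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary labels (0/1).
#' @param n_bins Number of bins (default deciles).
#' @return Scalar in `[0, 1]`.
#' @export
ece <- function(probs, labels, n_bins = 10L) {
  stopifnot_prob(probs, "probs")
  n <- length(probs)
  if (n < n_bins) abort("ece: need at least `n_bins` observations")
  tb <- reliability_table(probs, labels, n_bins = n_bins)
  sum(tb$n / n * abs(tb$p_mean - tb$event_rate))
}

#' Reliability table (equal-count bins)
#'
#' Per-bin mean predicted probability, observed event rate and count; the
#' tabular form behind a reliability diagram.
#'
#' @inheritParams ece
#' @return Tibble with columns `bin`, `n`, `p_mean`, `event_rate`,
#'   `p_lower`, `p_upper`.
#' @export
reliability_table <- function(probs, labels, n_bins = 10L) {
  stopifnot_prob(probs, "probs")
  labels <- as.numeric(labels)
  ord <- order(probs)
  bin <- integer(length(probs))
  bin[ord] <- ceiling(seq_along(ord) * n_bins / length(ord))
  tibble(bin = bin, p = probs, y = labels) %>%
    group_by(.data$bin) %>%
    summarise(n = dplyr::n(), p_mean = mean(.data$p),
              event_rate = mean(.data$y),
              p_lower = min(.data$p), p_upper = max(.data$p),
              .groups = "drop") %>%
    arrange(.data$bin)
}

#' Calibration slope
#'
#' Coefficient of `logit(p)` in a univariate logistic regression of the
#' outcome on the logit of the predicted probability; 1 indicates ideal
#' calibration-in-the-slope, below 1 overconfidence.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary labels (0/1).
#' @param eps Probability clamp.
#' @return Scalar slope; `Inf` when the fit separates.
#' @export
calibration_slope <- function(probs, labels, eps = 1e-6) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2) abort("calibration_slope: both classes must be present")
  lp <- qlogis(clamp(probs, eps, 1 - eps))
  fit <- suppressWarnings(glm(labels ~ lp, family = binomial()))
  slope <- unname(coef(fit)["lp"])
  if (!fit$converged || abs(slope) > 1e3) return(Inf)
  slope
}
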
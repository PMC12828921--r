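#' The eight muscle-procedure labels, in canonical order
#'
#' Fixed output ordering of the planner: right eye then left eye, medial
#' rectus (MR) then lateral rectus (LR), recession then resection.
#' Consecutive pairs `(1,2), (3,4), (5,6), (7,8)` address the same muscle and
#' are mutually exclusive in any feasible plan.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' plan_labels()
plan_labels <- function() {
  c("rmr_recess", "rmr_resect", "rlr_recess", "rlr_resect",
    "lmr_recess", "lmr_resect", "llr_recess", "llr_resect")
}

label_cols <- function() paste0("label_", plan_labels())
dose_cols  <- function() paste0("dose_",  plan_labels())

# indices of the (recession, resection) pair per muscle
muscle_pairs <- function() list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(7L, 8L))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Deterministic 32-bit-safe child seed from a parent seed and integer tags.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (t in c(1, tags)) {
    s <- (s * 69069 + as.numeric(t) + 1) %% 2147483647
  }
  as.integer(s)
}

# extract a numeric matrix of labels / doses from a cohort tibble
as_label_matrix <- function(data, cols = label_cols()) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("columns not found: ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(data[cols])
  storage.mode(m) <- "double"
  colnames(m) <- sub("^(label|dose|prob|dec|dosehat)_", "", cols)
  m
}

stopifnot_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0 | x > 1)) {
    abort(paste0("`", name, "` must contain finite values in [0, 1]"))
  }
}
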
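#' Model feature set
#'
#' The standardised inputs of the planner, in fixed order: age, deviating-eye
#' code (0=OD/1=OS), signed deviation angle, mean axial length, inter-ocular
#' axial-length difference (signed OD - OS), mean spherical equivalent and
#' difference, per-eye BCVA, the equal-vision flag, and the configured
#' expansions of the deviation measurement: its magnitude
#' (`abs_deviation`), direction (`is_exotropia`), and surgical-table bin
#' indicators `dev_gt_k` (deviation magnitude exceeding k prism dioptres,
#' k = 10, 15, ..., 50 -- the 5-dioptre grid on which published dosing
#' tables are laid out). The expansions let the network express dose rules
#' that act on the size of the deviation separately from the operated side
#' and change slope between table bins.
#'
#' @param expansions Include the derived expansion features.
#' @param bin_knots Cut points (prism dioptres) of the deviation-bin
#'   indicators.
#' @return Character vector of feature names.
#' @export
strabnet_features <- function(expansions = TRUE, bin_knots = seq(10, 50, by = 5)) {
  base <- c("age", "deviating_eye", "deviation_angle", "al_mean", "al_diff",
            "se_mean", "se_diff", "bcva_od", "bcva_os", "equal_vision")
  if (expansions) {
    c(base, "abs_deviation", "is_exotropia", paste0("dev_gt_", bin_knots))
  } else {
    base
  }
}

#' Derive model features from raw patient records
#'
#' Computes the inter-ocular means/differences from per-eye values where
#' they are not already present and returns the feature columns in
#' [strabnet_features()] order. The pipeline is complete-case: any missing
#' value raises an error.
#'
#' @param data Tibble of patient records.
#' @param features Feature names to return.
#' @return Tibble of (unstandardised) feature columns.
#' @export
derive_features <- function(data, features = strabnet_features()) {
  data <- as_tibble(data)
  if (!("al_mean" %in% names(data)) && all(c("al_od", "al_os") %in% names(data))) {
    data$al_mean <- (data$al_od + data$al_os) / 2
    data$al_diff <- data$al_od - data$al_os
  }
  if (!("se_mean" %in% names(data)) && all(c("se_od", "se_os") %in% names(data))) {
    data$se_mean <- (data$se_od + data$se_os) / 2
    data$se_diff <- data$se_od - data$se_os
  }
  if (!("abs_deviation" %in% names(data)) && "deviation_angle" %in% names(data)) {
    data$abs_deviation <- abs(data$deviation_angle)
    data$is_exotropia <- as.numeric(data$deviation_angle > 0)
  }
  bin_feats <- grep("^dev_gt_", features, value = TRUE)
  for (bf in setdiff(bin_feats, names(data))) {
    k <- as.numeric(sub("^dev_gt_", "", bf))
    data[[bf]] <- as.numeric(abs(data$deviation_angle) > k)
  }
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing data: feature column(s) not present: ",
                 paste(missing, collapse = ", ")))
  }
  out <- data[features]
  if (any(!purrr::map_lgl(out, is.numeric))) {
    abort("all feature columns must be numeric")
  }
  if (any(purrr::map_lgl(out, ~ any(is.na(.x))))) {
    abort("missing data: the pipeline is complete-case; NA values found")
  }
  out
}

#' Screen patient records against clinical bounds
#'
#' Quality check used before modelling: age 2-65 y, per-eye axial length
#' 18-32 mm, |deviation| <= 140 prism dioptres.
#'
#' @param records Tibble of patient records.
#' @return Tibble of violations (`row`, `field`, `value`, `lower`, `upper`);
#'   zero rows means every record is admissible.
#' @export
check_bounds <- function(records) {
  records <- as_tibble(records)
  bounds <- tibble(
    field = c("age", "al_od", "al_os", "deviation_angle"),
    lower = c(2, 18, 18, -140),
    upper = c(65, 32, 32, 140)
  )
  out <- purrr::pmap_dfr(bounds, function(field, lower, upper) {
    if (!field %in% names(records)) {
      abort(paste0("missing data: field `", field, "` not present"))
    }
    x <- records[[field]]
    if (any(is.na(x))) abort(paste0("missing data: NA in field `", field, "`"))
    bad <- which(x < lower | x > upper)
    tibble(row = bad, field = field, value = x[bad],
           lower = lower, upper = upper)
  })
  arrange(out, .data$row, .data$field)
}

#' Fit winsorisation bounds and standardisation statistics
#'
#' Computes, per feature and from training rows only, the 1st/99th
#' percentile winsor bounds (linear interpolation between order statistics,
#' `stats::quantile` type 7) and the mean/SD of the column after clipping to
#' those bounds. A constant column gets SD 1 (with a warning) so its
#' standardised values are 0.
#'
#' @param train Tibble of training-fold records (raw or feature columns).
#' @param features Feature names.
#' @param probs Lower/upper winsor percentiles.
#' @return A `prep_stats` object; see [apply_preprocess()].
#' @export
fit_preprocess <- function(train, features = strabnet_features(),
                           probs = c(0.01, 0.99)) {
  X <- derive_features(train, features)
  if (nrow(X) < 2) abort("fit_preprocess: need at least 2 training rows")
  stats <- purrr::map_dfr(features, function(f) {
    x <- X[[f]]
    q <- unname(quantile(x, probs, type = 7, names = FALSE))
    xc <- clamp(x, q[1], q[2])
    s <- sd(xc)
    if (!is.finite(s) || s == 0) {
      warn(paste0("fit_preprocess: constant column `", f, "`; SD set to 1"))
      s <- 1
    }
    tibble(feature = f, lower = q[1], upper = q[2], mean = mean(xc), sd = s)
  })
  structure(list(stats = stats, features = features, n_train = nrow(X)),
            class = "prep_stats")
}

#' @export
print.prep_stats <- function(x, ...) {
  cat("<prep_stats> fitted on", x$n_train, "training rows\n")
  print(x$stats, ...)
  invisible(x)
}

#' @export
tidy.prep_stats <- function(x, ...) x$stats

#' Winsorise and standardise records with fitted training statistics
#'
#' Clips each feature to the training-fold winsor bounds, then centres and
#' scales with the training-fold mean/SD — never recomputing statistics on
#' the data being transformed, so validation folds cannot leak.
#'
#' @param data Tibble of records (raw or feature columns).
#' @param stats A fitted [fit_preprocess()] object.
#' @return Tibble of standardised feature columns.
#' @export
apply_preprocess <- function(data, stats) {
  stopifnot(inherits(stats, "prep_stats"))
  X <- derive_features(data, stats$features)
  st <- stats$stats
  out <- purrr::map2_dfc(X, seq_along(stats$features), function(x, i) {
    (clamp(x, st$lower[i], st$upper[i]) - st$mean[i]) / st$sd[i]
  })
  names(out) <- stats$features
  out
}

as_feature_matrix <- function(features_tbl) {
  m <- as.matrix(features_tbl)
  storage.mode(m) <- "double"
  m
}
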
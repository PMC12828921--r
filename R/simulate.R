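#' Simulate a synthetic strabismus-surgery cohort
#'
#' Generates `config$n_patients` patient records (the 14 routine
#' pre-operative predictors) together with ground-truth surgical plans
#' (8 binary muscle-procedure labels and 8 doses in mm), using rejection
#' sampling to keep every record inside the clinical bounds (age 2-65 y,
#' axial length 18-32 mm, |deviation| <= 140 prism dioptres) and a
#' deterministic expert rule plus the classical dose nomogram to assign
#' plans. Identical `(config, seed)` yields a bit-identical cohort.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per patient: `patient_id`, predictors
#'   (`age`, `deviating_eye` 0=OD/1=OS, `deviation_angle` signed, + =
#'   exotropia, `al_od`, `al_os`, `al_mean`, `al_diff`, `se_od`, `se_os`,
#'   `se_mean`, `se_diff`, `bcva_od`, `bcva_os`, `equal_vision`), 8
#'   `label_*` columns and 8 `dose_*` columns in [plan_labels()] order.
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_config(n_patients = 50, seed = 1))
#' dplyr::count(cohort, exo = deviation_angle > 0)
simulate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  n <- config$n_patients
  if (n == 0L) return(empty_cohort())

  withr::with_seed(config$seed, {
    for (attempt in 1:10) {
      cohort <- simulate_cohort_once(config)
      prev <- colMeans(as_label_matrix(cohort))
      # only enforce the floor where it is statistically meaningful
      if (n * config$min_label_prevalence < 1 || all(prev >= config$min_label_prevalence)) {
        return(cohort)
      }
    }
    warn(paste0("simulate_cohort: label prevalence floor ",
                config$min_label_prevalence,
                " not attained after 10 attempts; returning last cohort"))
    cohort
  })
}

empty_cohort <- function() {
  cols <- c("patient_id", "age", "deviating_eye", "deviation_angle",
            "al_od", "al_os", "al_mean", "al_diff",
            "se_od", "se_os", "se_mean", "se_diff",
            "bcva_od", "bcva_os", "equal_vision",
            label_cols(), dose_cols())
  out <- as_tibble(setNames(rep(list(numeric(0)), length(cols)), cols))
  out$patient_id <- integer(0)
  out
}

# one full draw under the current RNG state
simulate_cohort_once <- function(config) {
  n <- config$n_patients
  exo <- runif(n) < config$p_exotropia
  type <- ifelse(exo, "exotropia", "esotropia")

  # truncated draws via resampling of rejected values (no boundary spikes)
  draw_trunc <- function(mean, sd, lo, hi) {
    x <- rnorm(length(mean), mean, sd)
    while (any(bad <- x < lo | x > hi)) {
      x[bad] <- rnorm(sum(bad), mean[bad], sd[bad])
    }
    x
  }
  age <- rlnorm(n, config$age_meanlog, config$age_sdlog)
  while (any(bad <- age < 2 | age > 65)) {
    age[bad] <- rlnorm(sum(bad), config$age_meanlog, config$age_sdlog)
  }

  adev <- draw_trunc(config$deviation_mean[type], config$deviation_sd[type],
                     .Machine$double.eps, 140)
  deviation <- ifelse(exo, adev, -adev)
  deviating_eye <- as.integer(runif(n) < 0.5)          # 0 = OD, 1 = OS

  al_mean <- draw_trunc(config$axial_length_mean[type],
                        config$axial_length_sd[type], 18.25, 31.75)
  al_diff <- rnorm(n, 0, config$al_diff_sd)
  while (any(bad <- al_mean + abs(al_diff) / 2 > 32 |
               al_mean - abs(al_diff) / 2 < 18)) {
    al_diff[bad] <- rnorm(sum(bad), 0, config$al_diff_sd)
  }
  se_mean <- rnorm(n, config$se_mean[type], config$se_sd[type])
  se_diff <- rnorm(n, 0, config$se_diff_sd)

  base <- function() pmax(0, rnorm(n, config$bcva_base_mean, config$bcva_base_sd))
  bcva_od <- base(); bcva_os <- base()
  amb <- runif(n) < config$p_amblyopia
  deficit <- runif(n, config$amblyopia_range[1], config$amblyopia_range[2])
  bcva_od <- bcva_od + ifelse(amb & deviating_eye == 0L, deficit, 0)
  bcva_os <- bcva_os + ifelse(amb & deviating_eye == 1L, deficit, 0)
  equal_vision <- as.integer(abs(bcva_od - bcva_os) <= config$equal_vision_margin)

  records <- tibble(
    patient_id = seq_len(n),
    age = age,
    deviating_eye = deviating_eye,
    deviation_angle = deviation,
    al_od = al_mean + al_diff / 2,
    al_os = al_mean - al_diff / 2,
    al_mean = al_mean, al_diff = al_diff,
    se_od = se_mean + se_diff / 2,
    se_os = se_mean - se_diff / 2,
    se_mean = se_mean, se_diff = se_diff,
    bcva_od = bcva_od, bcva_os = bcva_os,
    equal_vision = equal_vision
  )
  plans <- assign_plan(records, config)
  bind_cols(records, plans)
}

#' Assign ground-truth surgical plans to patient records
#'
#' Deterministic expert rule emulating standard practice: the primary
#' procedure is recession of the lateral rectus (exotropia) or medial rectus
#' (esotropia). Deviations up to `thr_single` get a single-muscle recession
#' on the deviating eye; between `thr_single` and `thr_three`, patients with
#' equal vision get a bilateral recession while unequal vision favours a
#' recess-resect on the deviating eye; above `thr_three` three muscles are
#' operated (bilateral recession plus resection of the deviating eye's
#' antagonist). Doses follow [dose_from_deviation()] with the correction
#' shared equally across operated muscles. Finally label noise is
#' injected: each active label is independently dropped with probability
#' `label_flip_rate` (emulating expert disagreement about marginal
#' procedures), and doses are re-zeroed wherever the label is 0, so the
#' dose-label consistency and mutual-exclusivity invariants hold after
#' noise as well.
#'
#' Random draws (dose noise, label flips) consume the session RNG stream;
#' [simulate_cohort()] wraps the call in a fixed seed.
#'
#' @param records Tibble of patient records (as from [simulate_cohort()]).
#' @param config A [generator_config()].
#' @return Tibble with the 8 `label_*` and 8 `dose_*` columns.
#' @export
assign_plan <- function(records, config = generator_config()) {
  n <- nrow(records)
  if (n == 0L) {
    return(as_tibble(setNames(rep(list(numeric(0)), 16),
                              c(label_cols(), dose_cols()))))
  }
  dev <- records$deviation_angle
  if (any(dev == 0)) abort("assign_plan: deviation_angle must be non-zero")
  exo <- dev > 0
  adev <- abs(dev)
  os <- records$deviating_eye == 1L
  eqv <- records$equal_vision == 1L

  # column indices into plan_labels() order
  prim_r <- ifelse(exo, 3L, 1L)  # recession, right eye (LR if exo, MR if eso)
  prim_l <- ifelse(exo, 7L, 5L)
  anta_r <- ifelse(exo, 2L, 4L)  # resection of the antagonist, right eye
  anta_l <- ifelse(exo, 6L, 8L)
  dev_prim <- ifelse(os, prim_l, prim_r)
  dev_anta <- ifelse(os, anta_l, anta_r)

  tier <- ifelse(adev <= config$thr_single, 1L,
                 ifelse(adev > config$thr_three, 3L, 2L))
  L <- matrix(0L, n, 8)
  idx <- seq_len(n)
  set1 <- function(rows, cols) L[cbind(rows, cols)] <<- 1L
  t1 <- tier == 1L
  set1(idx[t1], dev_prim[t1])
  t2b <- tier == 2L & eqv                      # bilateral recession
  set1(idx[t2b], prim_r[t2b]); set1(idx[t2b], prim_l[t2b])
  t2u <- tier == 2L & !eqv                     # recess-resect, deviating eye
  set1(idx[t2u], dev_prim[t2u]); set1(idx[t2u], dev_anta[t2u])
  t3 <- tier == 3L                             # bilateral recession + resect
  set1(idx[t3], prim_r[t3]); set1(idx[t3], prim_l[t3]); set1(idx[t3], dev_anta[t3])

  shares <- rowSums(L)
  D <- matrix(0, n, 8)
  for (j in 1:8) {
    rows <- which(L[, j] == 1L)
    if (length(rows) > 0) {
      D[rows, j] <- dose_from_deviation(dev[rows], shares[rows], config)
    }
  }

  # label noise: deactivation-only flips (a planned procedure is dropped
  # with probability label_flip_rate); keeps dose > 0 <=> label = 1 and
  # mutual exclusivity, and leaves the dose task's noise floor at the
  # nomogram noise rather than at the scale of a full dose
  if (config$label_flip_rate > 0) {
    flips <- matrix(runif(n * 8) < config$label_flip_rate, n, 8)
    L[flips & L == 1L] <- 0L
    D[L == 0L] <- 0
  }

  out <- bind_cols(
    as_tibble(setNames(as.data.frame(L), label_cols())),
    as_tibble(setNames(as.data.frame(D), dose_cols()))
  )
  out
}

#' Surgical dose from the deviation nomogram
#'
#' Converts a deviation angle into a per-muscle dose via the classical
#' linear nomogram: `|deviation| / (slope * n_muscles_sharing)` mm, plus
#' Gaussian surgeon-level noise, clipped to the feasible range 0.5-10 mm.
#'
#' @param deviation Deviation angle(s), prism dioptres, non-zero.
#' @param n_muscles_sharing Number of muscles sharing the correction (>= 1).
#' @param config A [generator_config()] supplying `nomogram_slope` and
#'   `dose_noise_sd`.
#' @return Dose(s) in mm, in `[0.5, 10]`.
#' @export
#' @examples
#' cfg <- generator_config(dose_noise_sd = 0)
#' dose_from_deviation(28, 2, cfg)  # 28 / (2 * 2) = 7 mm
dose_from_deviation <- function(deviation, n_muscles_sharing,
                                config = generator_config()) {
  if (any(n_muscles_sharing < 1)) {
    abort("dose_from_deviation: `n_muscles_sharing` must be >= 1")
  }
  if (any(deviation == 0)) {
    abort("dose_from_deviation: `deviation` must be non-zero")
  }
  raw <- abs(deviation) / (config$nomogram_slope * n_muscles_sharing)
  if (config$dose_noise_sd > 0) {
    raw <- raw + rnorm(length(raw), 0, config$dose_noise_sd)
  }
  clamp(raw, 0.5, 10)
}

#' Strabismus type from the signed deviation angle
#' @param deviation_angle Signed deviation (+ exotropia, - esotropia).
#' @return Character vector `"exotropia"` / `"esotropia"`.
#' @export
strabismus_type <- function(deviation_angle) {
  ifelse(deviation_angle > 0, "exotropia", "esotropia")
}

#' Read / write a cohort as CSV
#'
#' One row per patient: the 14 predictor columns, 8 label columns and 8
#' dose columns produced by [simulate_cohort()].
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  int_cols <- intersect(c("patient_id", "deviating_eye", "equal_vision",
                          label_cols()), names(out))
  out[int_cols] <- lapply(out[int_cols], as.integer)
  out
}
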
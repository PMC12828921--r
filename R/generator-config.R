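#' Configuration of the synthetic cohort simulator
#'
#' Defaults are calibrated to the published baseline characteristics of a
#' 634-patient horizontal-strabismus surgery cohort: 53.2% exotropia, mean
#' pre-operative deviation 28 +/- 10 prism dioptres (31 +/- 11 in exotropes,
#' 24 +/- 9 in esotropes), mean axial length 24.0 +/- 1.2 mm, mean spherical
#' equivalent -1.3 +/- 2.4 D, median age 15 years (IQR 11-23), and recession
#' doses clustering in the 6-7 mm bin under the classical 2 prism-dioptres
#' per mm nomogram.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; identical `(config, seed)` gives a bit-identical
#'   cohort.
#' @param p_exotropia Probability that a patient is exotropic (positive
#'   deviation); the remainder are esotropic.
#' @param age_meanlog,age_sdlog Log-normal age parameters (years); the
#'   defaults give median 15 y, mean 17.4 y, SD 10.3 y before truncation to
#'   the clinical bounds 2-65 y.
#' @param deviation_mean,deviation_sd Named numeric vectors
#'   `c(exotropia=, esotropia=)`: mean and SD of the absolute deviation angle
#'   (prism dioptres) per strabismus type.
#' @param axial_length_mean,axial_length_sd Per-type mean/SD of the
#'   per-patient mean axial length (mm).
#' @param al_diff_sd SD of the inter-ocular axial-length difference (mm).
#' @param se_mean,se_sd Per-type mean/SD of the mean spherical equivalent (D).
#' @param se_diff_sd SD of the inter-ocular spherical-equivalent
#'   difference (D).
#' @param bcva_base_mean,bcva_base_sd Parameters of the latent per-eye
#'   best-corrected visual acuity (logMAR), realised as
#'   `max(0, Normal(mean, sd))` so acuity clusters at 0.00 logMAR.
#' @param p_amblyopia Probability that the deviating eye carries an
#'   additional acuity deficit.
#' @param amblyopia_range Uniform range (logMAR) of that deficit.
#' @param equal_vision_margin Two eyes are flagged "equal vision" when their
#'   BCVA differs by at most this margin (logMAR).
#' @param nomogram_slope Prism dioptres corrected per mm of total surgery
#'   (classical nomogram: 2).
#' @param dose_noise_sd SD (mm) of surgeon-level dose variability around the
#'   nomogram.
#' @param label_flip_rate Per-label probability that a ground-truth label is
#'   flipped, emulating irreducible disagreement in expert plans.
#' @param min_label_prevalence Required minimum prevalence of each of the 8
#'   labels in an emitted cohort.
#' @param thr_single,thr_three Absolute-deviation cut-points (prism
#'   dioptres): at most `thr_single` a single-muscle recession is planned;
#'   above `thr_three` a three-muscle plan (bilateral recession plus
#'   resection of the deviating eye's antagonist); in between, two muscles.
#'
#' @return An object of class `generator_config` (a named list).
#' @seealso [simulate_cohort()]
#' @export
generator_config <- function(n_patients = 634L,
                             seed = 20260121L,
                             p_exotropia = 0.532,
                             age_meanlog = log(15),
                             age_sdlog = 0.55,
                             deviation_mean = c(exotropia = 31, esotropia = 24),
                             deviation_sd = c(exotropia = 11, esotropia = 9),
                             axial_length_mean = c(exotropia = 24.1, esotropia = 23.9),
                             axial_length_sd = c(exotropia = 1.3, esotropia = 1.1),
                             al_diff_sd = 0.30,
                             se_mean = c(exotropia = -1.4, esotropia = -1.2),
                             se_sd = c(exotropia = 2.3, esotropia = 2.5),
                             se_diff_sd = 0.5,
                             bcva_base_mean = -0.03,
                             bcva_base_sd = 0.18,
                             p_amblyopia = 0.35,
                             amblyopia_range = c(0.2, 0.8),
                             equal_vision_margin = 0.1,
                             nomogram_slope = 2,
                             dose_noise_sd = 0.3,
                             label_flip_rate = 0.02,
                             min_label_prevalence = 0.05,
                             thr_single = 15,
                             thr_three = 34) {
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    p_exotropia = p_exotropia,
    age_meanlog = age_meanlog, age_sdlog = age_sdlog,
    deviation_mean = deviation_mean, deviation_sd = deviation_sd,
    axial_length_mean = axial_length_mean, axial_length_sd = axial_length_sd,
    al_diff_sd = al_diff_sd,
    se_mean = se_mean, se_sd = se_sd, se_diff_sd = se_diff_sd,
    bcva_base_mean = bcva_base_mean, bcva_base_sd = bcva_base_sd,
    p_amblyopia = p_amblyopia, amblyopia_range = amblyopia_range,
    equal_vision_margin = equal_vision_margin,
    nomogram_slope = nomogram_slope, dose_noise_sd = dose_noise_sd,
    label_flip_rate = label_flip_rate,
    min_label_prevalence = min_label_prevalence,
    thr_single = thr_single, thr_three = thr_three
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1)) {
      abort(paste0("generator_config: `", nm, "` must be a probability in [0, 1]"))
    }
  }
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      abort(paste0("generator_config: `", nm, "` must be > 0"))
    }
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 0) {
    abort("generator_config: `n_patients` must be a non-negative integer")
  }
  chk_prob(cfg$p_exotropia, "p_exotropia")
  chk_prob(cfg$label_flip_rate, "label_flip_rate")
  chk_prob(cfg$min_label_prevalence, "min_label_prevalence")
  chk_prob(cfg$p_amblyopia, "p_amblyopia")
  chk_pos(cfg$age_sdlog, "age_sdlog")
  chk_pos(cfg$deviation_sd, "deviation_sd")
  chk_pos(cfg$axial_length_sd, "axial_length_sd")
  chk_pos(cfg$al_diff_sd, "al_diff_sd")
  chk_pos(cfg$se_sd, "se_sd")
  chk_pos(cfg$se_diff_sd, "se_diff_sd")
  chk_pos(cfg$bcva_base_sd, "bcva_base_sd")
  chk_pos(cfg$nomogram_slope, "nomogram_slope")
  if (!is.numeric(cfg$dose_noise_sd) || cfg$dose_noise_sd < 0) {
    abort("generator_config: `dose_noise_sd` must be >= 0")
  }
  if (cfg$thr_single <= 0 || cfg$thr_three <= cfg$thr_single) {
    abort("generator_config: need 0 < `thr_single` < `thr_three`")
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  n_patients:", x$n_patients, " seed:", x$seed, "\n")
  cat(sprintf("  p_exotropia: %.3f  label_flip_rate: %.3f  dose_noise_sd: %.2f mm\n",
              x$p_exotropia, x$label_flip_rate, x$dose_noise_sd))
  cat(sprintf("  deviation: exo %g +/- %g, eso %g +/- %g (prism dioptres)\n",
              x$deviation_mean[["exotropia"]], x$deviation_sd[["exotropia"]],
              x$deviation_mean[["esotropia"]], x$deviation_sd[["esotropia"]]))
  cat(sprintf("  nomogram: %g prism dioptres per mm; surgical tiers at %g / %g\n",
              x$nomogram_slope, x$thr_single, x$thr_three))
  invisible(x)
}

#' Read / write a generator configuration as YAML
#'
#' @param config A [generator_config()] object.
#' @param path File path.
#' @return `write_generator_config()` returns `path` invisibly;
#'   `read_generator_config()` returns a `generator_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml drops names of length-2 vectors written as maps; restore types
  for (nm in c("deviation_mean", "deviation_sd", "axial_length_mean",
               "axial_length_sd", "se_mean", "se_sd")) {
    raw[[nm]] <- unlist(raw[[nm]])
    if (is.null(names(raw[[nm]])) || !all(c("exotropia", "esotropia") %in% names(raw[[nm]]))) {
      names(raw[[nm]]) <- c("exotropia", "esotropia")
    }
  }
  raw$amblyopia_range <- unlist(raw$amblyopia_range)
  do.call(generator_config, raw)
}
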
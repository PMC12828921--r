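#' Align out-of-fold predictions with the cohort's reference plans
#'
#' @param cv A `strabnet_cv`.
#' @param cohort The cohort the CV was run on.
#' @return List of aligned n x 8 matrices (`raw`, `prob`, `dec`, `dosehat`,
#'   `label`, `dose`) plus `type` (strabismus type per patient) and
#'   `patient_id`.
#' @export
oof_matrices <- function(cv, cohort) {
  stopifnot(inherits(cv, "strabnet_cv"))
  joined <- left_join(cv$oof,
                      cohort[c("patient_id", "deviation_angle",
                               label_cols(), dose_cols())],
                      by = "patient_id")
  if (any(is.na(joined[label_cols()]))) {
    abort("oof_matrices: cohort does not match the cross-validated cohort")
  }
  grab <- function(prefix) {
    m <- as.matrix(joined[paste0(prefix, "_", plan_labels())])
    colnames(m) <- plan_labels()
    m
  }
  list(raw = grab("rawprob"), prob = grab("prob"), dec = grab("dec"),
       rawdose = grab("rawdose"), dosehat = grab("dosehat"),
       label = grab("label"), dose = grab("dose"),
       type = strabismus_type(joined$deviation_angle),
       patient_id = joined$patient_id, fold = joined$fold)
}

#' Evaluate a cross-validated run
#'
#' Computes the full metrics report from pooled out-of-fold predictions:
#' per-label and macro discrimination, exact-match accuracy against the
#' majority baseline, calibration (pre- and post-calibration ECE, slope,
#' reliability table), dose regression both over all 8 outputs and over
#' operated muscles only, Bland-Altman agreement, tiered plan agreement,
#' decision curve, subgroup (strabismus-type) fairness, and optional
#' patient-level bootstrap CIs for the headline metrics.
#'
#' @param cv A `strabnet_cv`.
#' @param cohort The cohort the CV was run on.
#' @param dose_tolerance Tolerance for the fraction-within metric, mm.
#' @param quantum Plan-agreement dose quantum, mm.
#' @param bootstrap_B Bootstrap resamples for the CIs (0 skips them).
#' @param seed Seed for the bootstrap.
#' @return A `strabnet_report`.
#' @export
evaluate_cv <- function(cv, cohort, dose_tolerance = 0.30, quantum = 0.5,
                        bootstrap_B = 0L, seed = 1L) {
  m <- oof_matrices(cv, cohort)
  n <- nrow(m$label)

  cls <- classification_metrics(m$prob, m$dec, m$label)
  pooled_prob <- as.vector(m$prob)
  pooled_raw <- as.vector(m$raw)
  pooled_y <- as.vector(m$label)
  calib <- list(
    ece = ece(pooled_prob, pooled_y),
    ece_raw = ece(pooled_raw, pooled_y),
    slope = calibration_slope(pooled_prob, pooled_y),
    reliability = reliability_table(pooled_prob, pooled_y)
  )
  # dose-regression accuracy is a property of the regression head; plan
  # gating (decision x dose) is assessed separately via plan agreement
  operated <- m$label == 1
  reg <- list(
    all = regression_metrics(as.vector(m$dosehat), as.vector(m$dose),
                             tolerance = dose_tolerance),
    operated = regression_metrics(m$rawdose[operated], m$dose[operated],
                                  tolerance = dose_tolerance)
  )
  ba <- bland_altman(m$rawdose[operated], m$dose[operated])
  agreement <- plan_agreement(m$dec, m$dosehat, m$label, m$dose,
                              quantum = quantum)
  dc <- decision_curve(pooled_prob, pooled_y)
  subgroup <- subgroup_report(m$prob, m$dec, m$label, m$rawdose, m$dose,
                              m$type, dose_tolerance = dose_tolerance)

  cis <- NULL
  if (bootstrap_B > 0) {
    per_patient <- tibble(id = seq_len(n))
    stat_tbl <- list(
      macro_auc = function(d) {
        i <- d$id
        mean(purrr::map_dbl(1:8, ~ auc_score(m$prob[i, .x], m$label[i, .x])))
      },
      mae_operated = function(d) {
        i <- d$id
        op <- m$label[i, , drop = FALSE] == 1
        mean(abs(m$rawdose[i, , drop = FALSE][op] - m$dose[i, , drop = FALSE][op]))
      },
      ece = function(d) {
        i <- d$id
        ece(as.vector(m$prob[i, , drop = FALSE]),
            as.vector(m$label[i, , drop = FALSE]))
      },
      exact_match = function(d) {
        i <- d$id
        mean(apply(m$dec[i, , drop = FALSE] == m$label[i, , drop = FALSE], 1, all))
      }
    )
    cis <- purrr::imap_dfr(stat_tbl, function(f, nm) {
      bind_cols(tibble(metric = nm),
                bootstrap_ci(per_patient, f, B = bootstrap_B,
                             seed = derive_seed(seed, 11L)))
    })
  }

  structure(list(classification = cls, calibration = calib, regression = reg,
                 bland_altman = ba, agreement = agreement,
                 decision_curve = dc, subgroup = subgroup, cis = cis,
                 n = n, k = attr(cv$folds, "k"),
                 certificate_max = attr(cv$folds, "max_deviation_pp"),
                 n_params = cv$n_params,
                 dose_tolerance = dose_tolerance, quantum = quantum),
            class = "strabnet_report")
}

#' @export
print.strabnet_report <- function(x, ...) {
  cat("<strabnet_report>", x$n, "patients,", x$k, "folds,",
      x$n_params, "model parameters\n")
  g <- glance(x)
  cat(sprintf("  selection : macro-AUC %.3f | macro-F1 %.3f | macro-MCC %.3f | exact match %.1f%% (baseline %.1f%%)\n",
              g$macro_auc, g$macro_f1, g$macro_mcc, 100 * g$exact_match,
              100 * g$majority_baseline))
  cat(sprintf("  calibration: ECE %.4f (raw %.4f) | slope %.2f\n",
              g$ece, x$calibration$ece_raw, g$slope))
  cat(sprintf("  dose       : MAE %.3f mm (operated) / %.3f mm (all) | RMSE %.3f | R2 %.3f | within %.2f mm: %.1f%%\n",
              g$mae_operated, g$mae_all, g$rmse_operated, g$r2_operated,
              x$dose_tolerance, 100 * g$frac_within_operated))
  cat(sprintf("  agreement  : tier-1 %.1f%% | tier-2 %.1f%% | acceptable %.1f%%\n",
              100 * x$agreement$tier1, 100 * x$agreement$tier2,
              100 * x$agreement$acceptable))
  invisible(x)
}

#' @export
glance.strabnet_report <- function(x, ...) {
  tibble(
    n = x$n, k = x$k, n_params = x$n_params,
    macro_auc = x$classification$macro$auc,
    macro_f1 = x$classification$macro$f1,
    macro_mcc = x$classification$macro$mcc,
    exact_match = x$classification$exact_match,
    majority_baseline = x$classification$majority_baseline,
    ece = x$calibration$ece, slope = x$calibration$slope,
    mae_all = x$regression$all$mae,
    mae_operated = x$regression$operated$mae,
    rmse_operated = x$regression$operated$rmse,
    r2_operated = x$regression$operated$r2,
    frac_within_operated = x$regression$operated$frac_within,
    bias = x$bland_altman$bias,
    tier1 = x$agreement$tier1, acceptable = x$agreement$acceptable,
    certificate_max = x$certificate_max
  )
}

#' @export
tidy.strabnet_report <- function(x, ...) tidy(x$classification)

#' Serialise a metrics report
#'
#' Writes `metrics.json` (the full report), `report.md` (human-readable
#' summary), `reliability.csv` and `decision_curve.csv` into `dir`.
#'
#' @param report A `strabnet_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  blocks <- list(
    summary = as.list(glance(report)),
    per_label = report$classification$per_label,
    calibration = list(ece = report$calibration$ece,
                       ece_raw = report$calibration$ece_raw,
                       slope = report$calibration$slope),
    regression = list(all = report$regression$all,
                      operated = report$regression$operated),
    bland_altman = report$bland_altman,
    agreement = report$agreement,
    subgroup = report$subgroup,
    bootstrap_cis = report$cis
  )
  jsonlite::write_json(blocks, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_csv(report$calibration$reliability,
                   file.path(dir, "reliability.csv"))
  readr::write_csv(report$decision_curve, file.path(dir, "decision_curve.csv"))

  g <- glance(report)
  md <- c(
    "# Surgical-plan model report", "",
    sprintf("- Patients: %d; folds: %d; model parameters: %d", report$n,
            report$k, report$n_params),
    sprintf("- Stratification certificate max: %.2f percentage points",
            report$certificate_max),
    "", "## Muscle selection", "",
    sprintf("- Macro-AUC %.3f, macro-F1 %.3f, macro-MCC %.3f", g$macro_auc,
            g$macro_f1, g$macro_mcc),
    sprintf("- Exact plan match %.1f%% (majority baseline %.1f%%)",
            100 * g$exact_match, 100 * g$majority_baseline),
    sprintf("- ECE %.4f after calibration (%.4f before); slope %.2f",
            g$ece, report$calibration$ece_raw, g$slope),
    "", "## Dose regression", "",
    sprintf("- Operated muscles: MAE %.3f mm, RMSE %.3f mm, R2 %.3f, within %.2f mm: %.1f%%",
            g$mae_operated, g$rmse_operated, g$r2_operated,
            report$dose_tolerance, 100 * g$frac_within_operated),
    sprintf("- All outputs: MAE %.3f mm", g$mae_all),
    sprintf("- Bland-Altman bias %.3f mm, limits of agreement %.3f to %.3f mm",
            report$bland_altman$bias, report$bland_altman$loa_lower,
            report$bland_altman$loa_upper),
    "", "## Plan agreement", "",
    sprintf("- Tier 1 (all doses within %.1f mm): %.1f%%", report$quantum,
            100 * report$agreement$tier1),
    sprintf("- Tier 2 (one dose off by <= 1 mm): %.1f%%",
            100 * report$agreement$tier2),
    sprintf("- Clinically acceptable: %.1f%%", 100 * report$agreement$acceptable)
  )
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
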
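test_that("simulation is deterministic and handles the empty cohort", {
  cfg <- generator_config(n_patients = 120, seed = 42)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  empty <- simulate_cohort(generator_config(n_patients = 0))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("age", label_cols <- paste0("label_", plan_labels())) %in% names(empty)))
})

test_that("invalid configurations name the offending field", {
  expect_error(generator_config(p_exotropia = 1.4), "p_exotropia")
  expect_error(generator_config(dose_noise_sd = -1), "dose_noise_sd")
  expect_error(generator_config(nomogram_slope = 0), "nomogram_slope")
  expect_error(generator_config(thr_single = 40, thr_three = 30), "thr_single")
})

test_that("every simulated record satisfies the clinical bounds", {
  co <- simulate_cohort(generator_config(n_patients = 10000, seed = 7))
  expect_true(all(co$age >= 2 & co$age <= 65))
  expect_true(all(co$al_od >= 18 & co$al_od <= 32))
  expect_true(all(co$al_os >= 18 & co$al_os <= 32))
  expect_true(all(abs(co$deviation_angle) <= 140 & co$deviation_angle != 0))
  expect_equal(nrow(check_bounds(co)), 0)
})

test_that("plans satisfy dose-label consistency and mutual exclusivity", {
  # noiseless plans: dose > 0 <=> label = 1
  co <- simulate_cohort(quiet_config(n = 10000, seed = 13))
  L <- label_matrix(co); D <- dose_matrix(co)
  expect_true(all((D > 0) == (L == 1)))
  expect_true(all(D >= 0 & D <= 10))
  # no muscle simultaneously recessed and resected, with and without noise
  for (flip in c(0, 0.02)) {
    coi <- simulate_cohort(quiet_config(n = 5000, seed = 14, label_flip_rate = flip))
    Li <- label_matrix(coi)
    for (pair in list(c(1, 2), c(3, 4), c(5, 6), c(7, 8))) {
      expect_true(all(Li[, pair[1]] + Li[, pair[2]] <= 1))
    }
    # label noise only deactivates, so consistency survives it
    expect_true(all((dose_matrix(coi) > 0) == (label_matrix(coi) == 1)))
  }
  # every label attains the configured prevalence floor
  cfg <- generator_config(n_patients = 634, seed = 1)
  prev <- colMeans(label_matrix(simulate_cohort(cfg)))
  expect_true(all(prev >= cfg$min_label_prevalence))
})

test_that("the expert rule forces type-consistent procedures", {
  rec <- tibble::tibble(
    patient_id = 1:4, age = 20,
    deviating_eye = c(0L, 1L, 0L, 1L),
    deviation_angle = c(40, 40, -12, -12),
    al_od = 24, al_os = 24, al_mean = 24, al_diff = 0,
    se_od = -1, se_os = -1, se_mean = -1, se_diff = 0,
    bcva_od = 0, bcva_os = 0, equal_vision = 1L
  )
  plan <- assign_plan(rec, quiet_config())
  L <- as.matrix(plan[paste0("label_", plan_labels())])
  # exotropes: only lateral-rectus recession and/or medial-rectus resection
  exo_allowed <- c("rlr_recess", "llr_recess", "rmr_resect", "lmr_resect")
  expect_true(all(L[1:2, !plan_labels() %in% exo_allowed] == 0))
  expect_true(all(rowSums(L[1:2, , drop = FALSE]) > 0))
  # small-angle esotrope: unilateral medial-rectus recession on deviating eye
  expect_equal(unname(L[3, ]), c(1, 0, 0, 0, 0, 0, 0, 0))  # OD deviating
  expect_equal(unname(L[4, ]), c(0, 0, 0, 0, 1, 0, 0, 0))  # OS deviating
})

test_that("doses follow the nomogram closed form and clip range", {
  cfg <- quiet_config()
  expect_equal(dose_from_deviation(28, 2, cfg), 7.0)
  expect_equal(dose_from_deviation(-28, 2, cfg), 7.0)
  expect_equal(dose_from_deviation(4, 1, cfg), 2.0)
  expect_equal(dose_from_deviation(1, 1, cfg), 0.5)    # lower clip
  expect_equal(dose_from_deviation(100, 1, cfg), 10)   # upper clip
  expect_error(dose_from_deviation(28, 0, cfg), "n_muscles_sharing")
  expect_error(dose_from_deviation(0, 1, cfg), "non-zero")
})

test_that("label prevalences match the rule's analytic marginals", {
  cfg <- generator_config(n_patients = 10000, seed = 21)
  co <- simulate_cohort(cfg)
  prev <- colMeans(label_matrix(co))

  # independent oracle: integrate the deterministic rule over the generative
  # distribution of (type, deviating eye, equal vision, |deviation| tier)
  tier_probs <- function(mean, sd) {
    z <- function(q) stats::pnorm(q, mean, sd)
    tot <- z(140) - z(0)
    c(t1 = (z(cfg$thr_single) - z(0)) / tot,
      t2 = (z(cfg$thr_three) - z(cfg$thr_single)) / tot,
      t3 = (z(140) - z(cfg$thr_three)) / tot)
  }
  # P(equal vision) by direct Monte Carlo of the acuity mixture
  set.seed(1)
  m <- 2e5
  b1 <- pmax(0, rnorm(m, cfg$bcva_base_mean, cfg$bcva_base_sd))
  b2 <- pmax(0, rnorm(m, cfg$bcva_base_mean, cfg$bcva_base_sd))
  amb <- runif(m) < cfg$p_amblyopia
  b1 <- b1 + ifelse(amb, runif(m, cfg$amblyopia_range[1], cfg$amblyopia_range[2]), 0)
  p_eq <- mean(abs(b1 - b2) <= cfg$equal_vision_margin)

  marginal <- function(type) {
    tp <- if (type == "exotropia") {
      tier_probs(cfg$deviation_mean[["exotropia"]], cfg$deviation_sd[["exotropia"]])
    } else {
      tier_probs(cfg$deviation_mean[["esotropia"]], cfg$deviation_sd[["esotropia"]])
    }
    p_type <- if (type == "exotropia") cfg$p_exotropia else 1 - cfg$p_exotropia
    keep <- 1 - cfg$label_flip_rate
    # per-eye primary recession: always when deviating (any tier), plus
    # bilateral tiers when the other eye deviates
    p_recess <- p_type * keep *
      (0.5 * 1 + 0.5 * (tp["t2"] * p_eq + tp["t3"]))
    # antagonist resection on the deviating eye: tier-2 unequal or tier-3
    p_resect <- p_type * keep * 0.5 * (tp["t2"] * (1 - p_eq) + tp["t3"])
    c(recess = unname(p_recess), resect = unname(p_resect))
  }
  exo <- marginal("exotropia"); eso <- marginal("esotropia")
  expected <- c(rmr_recess = eso["recess"], rmr_resect = exo["resect"],
                rlr_recess = exo["recess"], rlr_resect = eso["resect"],
                lmr_recess = eso["recess"], lmr_resect = exo["resect"],
                llr_recess = exo["recess"], llr_resect = eso["resect"])
  se <- sqrt(expected * (1 - expected) / cfg$n_patients)
  # 3 SE of the simulation plus a small allowance for the oracle's own
  # Monte-Carlo estimate of the equal-vision probability
  expect_true(all(abs(prev - unname(expected)) <= 3 * se + 0.01))
})

test_that("recession doses cluster in the 6-7 mm bin", {
  co <- simulate_cohort(generator_config(n_patients = 10000, seed = 31))
  L <- label_matrix(co); D <- dose_matrix(co)
  recess_cols <- grepl("recess", plan_labels())
  doses <- D[, recess_cols][L[, recess_cols] == 1]
  h <- hist(doses, breaks = 0:11, plot = FALSE)$counts
  expect_equal(which.max(h), 7L)  # the (6, 7] bin
})

test_that("cohort moments converge to the configured population values", {
  cfg <- generator_config(n_patients = 10000, seed = 51)
  co <- simulate_cohort(cfg)
  n <- nrow(co)
  exo <- co$deviation_angle > 0

  expect_lt(abs(mean(exo) - cfg$p_exotropia),
            3 * sqrt(cfg$p_exotropia * (1 - cfg$p_exotropia) / n))

  trunc_mean <- function(mu, sd) {   # E[X | 0 < X < 140], X ~ N(mu, sd)
    a <- (0 - mu) / sd; b <- (140 - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
  }
  m_exo <- trunc_mean(cfg$deviation_mean[["exotropia"]], cfg$deviation_sd[["exotropia"]])
  m_eso <- trunc_mean(cfg$deviation_mean[["esotropia"]], cfg$deviation_sd[["esotropia"]])
  m_all <- cfg$p_exotropia * m_exo + (1 - cfg$p_exotropia) * m_eso
  expect_lt(abs(mean(abs(co$deviation_angle)) - m_all),
            3 * sd(abs(co$deviation_angle)) / sqrt(n))
  expect_lt(abs(mean(abs(co$deviation_angle[exo])) - m_exo),
            3 * sd(abs(co$deviation_angle[exo])) / sqrt(sum(exo)))

  m_al <- cfg$p_exotropia * cfg$axial_length_mean[["exotropia"]] +
    (1 - cfg$p_exotropia) * cfg$axial_length_mean[["esotropia"]]
  expect_lt(abs(mean(co$al_mean) - m_al), 3 * sd(co$al_mean) / sqrt(n))

  # median age ~ exp(meanlog) = 15 y
  expect_lt(abs(median(co$age) - exp(cfg$age_meanlog)), 0.5)
})

test_that("cohorts and configs round-trip through their file formats", {
  co <- simulate_cohort(generator_config(n_patients = 40, seed = 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, csv)
  back <- read_cohort(csv)
  expect_equal(as.data.frame(back), as.data.frame(co), tolerance = 1e-12)

  # YAML serialises doubles to 15 significant digits, so the round trip is
  # equal to that precision and the regenerated cohort matches accordingly
  yml <- withr::local_tempfile(fileext = ".yaml")
  cfg <- generator_config(n_patients = 55, seed = 9, p_exotropia = 0.6)
  write_generator_config(cfg, yml)
  cfg2 <- read_generator_config(yml)
  expect_equal(cfg2, cfg, tolerance = 1e-12)
  expect_equal(simulate_cohort(cfg2), simulate_cohort(cfg), tolerance = 1e-9)
})
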
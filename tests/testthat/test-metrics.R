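test_that("AUC equals the concordant-pair count and survives monotone maps", {
  # 4-point toy: brute-force pair counting oracle
  p <- c(0.1, 0.4, 0.35, 0.8)
  y <- c(0, 0, 1, 1)
  pairs <- expand.grid(pos = which(y == 1), neg = which(y == 0))
  oracle <- mean(ifelse(p[pairs$pos] > p[pairs$neg], 1,
                        ifelse(p[pairs$pos] == p[pairs$neg], 0.5, 0)))
  expect_equal(auc_score(p, y), oracle)
  expect_equal(auc_score(p, y), 0.75)

  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_true(is.na(auc_score(p, c(1, 1, 1, 1))))

  # invariance under a strictly monotone transform, with ties
  set.seed(8)
  ps <- round(runif(200), 1)
  ys <- rbinom(200, 1, ps)
  expect_equal(auc_score(plogis(5 * ps - 2), ys), auc_score(ps, ys))
})

test_that("classification metrics reduce correctly in the identity case", {
  set.seed(9)
  L <- matrix(rbinom(160, 1, 0.4), 20, 8)
  L[1, ] <- 1; L[2, ] <- 0            # ensure both classes per label? not guaranteed
  for (j in 1:8) { L[1, j] <- 1; L[2, j] <- 0 }
  P <- ifelse(L == 1, 0.9, 0.1)
  cm <- classification_metrics(P, L, L)
  expect_equal(cm$macro$auc, 1)
  expect_equal(cm$macro$f1, 1)
  expect_equal(cm$macro$mcc, 1)
  expect_equal(cm$exact_match, 1)
  g <- glance(cm)
  expect_equal(g$macro_auc, 1)
  # macro equals the unweighted mean of the per-label values
  expect_equal(cm$macro$auc, mean(cm$per_label$auc, na.rm = TRUE))
  td <- tidy(cm)
  expect_equal(nrow(td), 9)
  expect_equal(td$label[9], "macro")
})

test_that("regression metrics match hand arithmetic", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(regression_metrics(x, x),
               tibble::tibble(n = 5L, mae = 0, rmse = 0, r2 = 1, frac_within = 1),
               ignore_attr = TRUE)
  shifted <- regression_metrics(x + 0.5, x, tolerance = 0.30)
  expect_equal(shifted$mae, 0.5)
  expect_equal(shifted$rmse, 0.5)
  expect_equal(shifted$frac_within, 0)

  pred <- c(1.2, 2.1, 2.7, 4.4, 4.9)
  e <- pred - x
  m <- regression_metrics(pred, x, tolerance = 0.30)
  expect_equal(m$mae, mean(abs(e)))
  expect_equal(m$rmse, sqrt(mean(e^2)))
  expect_equal(m$r2, 1 - sum(e^2) / sum((x - 3)^2))
  expect_equal(m$frac_within, mean(abs(e) <= 0.30))
  expect_warning(z <- regression_metrics(c(1, 2), c(3, 3)), "zero-variance")
  expect_true(is.na(z$r2))
})

test_that("Bland-Altman matches its closed forms", {
  x <- c(2, 4, 6)
  expect_equal(bland_altman(x, x)$bias, 0)
  expect_equal(bland_altman(x, x)$loa_lower, 0)
  expect_equal(bland_altman(x + 1, x)$bias, 1)
  expect_equal(bland_altman(x + 1, x)$loa_upper, 1)
  # differences {-0.2, 0, 0.2}: sd = 0.2, limits = +/- 1.96 * 0.2
  ba <- bland_altman(x + c(-0.2, 0, 0.2), x)
  expect_equal(ba$bias, 0, tolerance = 1e-12)
  expect_equal(ba$loa_upper, 1.96 * 0.2, tolerance = 1e-12)
  expect_equal(ba$loa_lower, -1.96 * 0.2, tolerance = 1e-12)
})

test_that("plan agreement tiers match an exhaustive manual classification", {
  L <- matrix(0, 10, 8); L[, 1] <- 1; L[6:10, 3] <- 1
  Dt <- matrix(0, 10, 8); Dt[L == 1] <- 6
  dec <- L; Dp <- Dt
  # plans 1-3 exact; plan 4 one dose off by 0.8 (tier 2); plan 5 one dose
  # off by 1.4 (neither); plan 6 two doses off by 0.8 (neither);
  # plan 7 wrong decision vector; plans 8-10 exact
  Dp[4, 1] <- 6.8
  Dp[5, 1] <- 7.4
  Dp[6, 1] <- 6.8; Dp[6, 3] <- 5.2
  dec[7, 2] <- 1; dec[7, 1] <- 0
  pa <- plan_agreement(dec, Dp, L, Dt, quantum = 0.5, tier2_max = 1)
  expect_equal(pa$tier1, 6 / 10)
  expect_equal(pa$tier2, 1 / 10)
  expect_equal(pa$acceptable, 7 / 10)
  expect_equal(pa$exact_decision_match, 9 / 10)
  # majority baseline: modal reference vector (rows 1-5) has frequency 5/10
  expect_equal(pa$majority_baseline, 5 / 10)
  # all identical: tier 1 only
  pa2 <- plan_agreement(L, Dt, L, Dt)
  expect_equal(pa2$tier1, 1)
  expect_equal(pa2$tier2, 0)
})

test_that("decision curves match their closed forms", {
  set.seed(10)
  y <- rbinom(400, 1, 0.3)
  p <- runif(400)
  dc <- decision_curve(p, y, thresholds = c(0.2, 0.5, 0.8))
  expect_true(all(dc$nb_none == 0))
  pi_hat <- mean(y)
  expect_equal(dc$nb_all,
               pi_hat - (1 - pi_hat) * dc$threshold / (1 - dc$threshold))

  # TP = 30, FP = 10, n = 100 at p_t = 0.5 -> NB = 0.30 - 0.10 = 0.20
  y2 <- c(rep(1, 30), rep(0, 70))
  p2 <- c(rep(0.9, 30), rep(0.9, 10), rep(0.1, 60))
  dc2 <- decision_curve(p2, y2, thresholds = 0.5)
  expect_equal(dc2$nb_model, 0.20)
  # thresholds at 1 are excluded
  expect_equal(nrow(decision_curve(p2, y2, thresholds = c(0.5, 1))), 1)
})

test_that("subgroup gaps equal hand arithmetic and merge consistently", {
  set.seed(11)
  n <- 60
  L <- matrix(rbinom(n * 8, 1, 0.5), n, 8)
  P <- ifelse(L == 1, 0.9, 0.1)
  P[1:10, ] <- 0.5                       # degrade group A only
  dec <- (P >= 0.5) * 1
  Dp <- ifelse(L == 1, 6.4, 0); Dt <- ifelse(L == 1, 6, 0)
  grp <- rep(c("exotropia", "esotropia"), each = n / 2)
  sg <- subgroup_report(P, dec, L, Dp, Dt, grp)
  expect_setequal(sg$group, c("exotropia", "esotropia", "gap"))
  a <- sg[sg$group == "exotropia", ]; b <- sg[sg$group == "esotropia", ]
  gap <- sg[sg$group == "gap", ]
  expect_equal(gap$macro_auc, abs(a$macro_auc - b$macro_auc))
  expect_equal(gap$mae_operated, abs(a$mae_operated - b$mae_operated))
  expect_equal(b$mae_operated, 0.4, tolerance = 1e-12)
  # a merged recomputation equals the pooled metric
  pooled <- classification_metrics(P, dec, L)
  i1 <- grp == "exotropia"
  expect_equal(pooled$exact_match,
               mean(c(apply(dec[i1, ] == L[i1, ], 1, all),
                      apply(dec[!i1, ] == L[!i1, ], 1, all))))
})

test_that("permutation importance isolates predictive features", {
  payload <- shared_sim_fit()
  fit <- payload$fit
  Xva <- payload$X[payload$va, ]
  Lva <- payload$L[payload$va, ]
  Dva <- payload$D[payload$va, ]
  imp <- permutation_importance(fit, Xva, Lva, Dva, metric = "dose_mae",
                                n_repeats = 3, seed = 2)
  expect_equal(nrow(imp), ncol(Xva))
  # the dose is a pure function of the deviation: its magnitude must rank first
  expect_true(imp$feature[1] %in% c("abs_deviation", "deviation_angle"))

  # a feature whose first-layer weights are zeroed carries no importance
  fit0 <- fit
  j <- which(colnames(Xva) == "se_diff")
  fit0$params$trunk[[1]]$W[j, ] <- 0
  imp0 <- permutation_importance(fit0, Xva, Lva, Dva, metric = "macro_auc",
                                 n_repeats = 3, seed = 3)
  expect_lt(abs(imp0$importance_mean[imp0$feature == "se_diff"]), 1e-12)
  expect_error(permutation_importance(fit, Xva, Lva, Dva, n_repeats = 0),
               "n_repeats")
})
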
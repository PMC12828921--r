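test_that("initialisation is Xavier-uniform, reproducible, and counted", {
  cfg <- tiny_model(seed = 4L)
  expect_identical(init_params(cfg, 5L), init_params(cfg, 5L))

  # bound forced by the formula for a square 3x3 layer
  p3 <- init_params(model_config(trunk_widths = 3L, seed = 1L), 3L)
  expect_true(all(abs(p3$trunk[[1]]$W) <= 1))
  expect_true(all(p3$trunk[[1]]$b == 0))

  # empirical variance of ~1e5 weights matches 2 / (fan_in + fan_out)
  pw <- init_params(model_config(trunk_widths = 500L, seed = 2L), 200L)
  w <- as.vector(pw$trunk[[1]]$W)
  expect_lt(abs(var(w) / (2 / 700) - 1), 0.05)

  # parameter count: hand count for a tiny shape
  # 4 -> 3 (W 12 + b 3 + bn 6) -> heads 2 * (3*8 + 8) = 21 + 64
  expect_equal(strabnet_n_params(model_config(trunk_widths = 3L), 4L), 85L)
})

test_that("forward pass respects output ranges and eval-mode determinism", {
  co <- simulate_cohort(generator_config(n_patients = 80, seed = 6))
  prep <- fit_preprocess(co)
  X <- as.matrix(apply_preprocess(co, prep))
  L <- label_matrix(co); D <- dose_matrix(co)
  fit <- fit_strabnet(X[1:60, ], L[1:60, ], D[1:60, ], X[61:80, ], L[61:80, ],
                      D[61:80, ], tiny_model(seed = 2L))
  pr <- predict(fit, X)
  P <- as.matrix(pr[paste0("prob_", plan_labels())])
  DH <- as.matrix(pr[paste0("dose_", plan_labels())])
  expect_true(all(P >= 0 & P <= 1))
  expect_true(all(DH >= 0 & DH <= 10))
  expect_identical(pr, predict(fit, X))
  expect_error(predict(fit, X[, 1:3]), "width")

  # all-zero parameters: probabilities exactly 0.5 and raw doses exactly 0
  fit0 <- fit
  fit0$params <- rapply(fit$params, function(x) x * 0, how = "replace")
  fit0$params$trunk <- purrr::map(fit0$params$trunk, function(l) {
    l$run_var <- rep(1, length(l$run_var)); l
  })
  fit0$dose_center <- rep(0, 8); fit0$dose_scale <- rep(1, 8)
  pr0 <- predict(fit0, X)
  expect_true(all(as.matrix(pr0[paste0("prob_", plan_labels())]) == 0.5))
  expect_true(all(as.matrix(pr0[paste0("dose_", plan_labels())]) == 0))
})

test_that("the multi-task loss matches closed forms and a scalar oracle", {
  # perfect predictions: loss -> 0 as the clamp vanishes
  y <- matrix(c(1, 0), 2, 8)
  d <- matrix(runif(16), 2, 8)
  expect_lt(multitask_loss(y, d, y, d, eps = 1e-12), 1e-10)

  # single observation, p = 0.5 everywhere, no dose error, unit weights
  expect_equal(multitask_loss(matrix(0.5, 1, 8), d[1, , drop = FALSE],
                              matrix(1, 1, 8), d[1, , drop = FALSE]),
               -log(0.5), tolerance = 1e-10)

  # random batch against an independent elementwise recomputation
  set.seed(3)
  n <- 7
  p <- matrix(runif(n * 8, 0.05, 0.95), n, 8)
  dh <- matrix(rnorm(n * 8), n, 8)
  yy <- matrix(rbinom(n * 8, 1, 0.5), n, 8)
  dt <- matrix(rnorm(n * 8), n, 8)
  w <- runif(8, 1, 5); lam <- 2.5
  acc <- 0
  for (i in 1:n) for (j in 1:8) {
    acc <- acc - (w[j] * yy[i, j] * log(p[i, j]) +
                    (1 - yy[i, j]) * log(1 - p[i, j]))
    acc <- acc + lam * (dh[i, j] - dt[i, j])^2
  }
  expect_equal(multitask_loss(p, dh, yy, dt, pos_weights = w, lambda = lam),
               acc / (n * 8), tolerance = 1e-12)
  expect_error(multitask_loss(p * NA, dh, yy, dt), "non-finite")
})

test_that("backpropagation matches finite differences", {
  for (bn in c(TRUE, FALSE)) {
    cfg <- model_config(trunk_widths = c(6L, 4L), dropout = 0, seed = 11L,
                        batch_norm = bn, lambda = 1.7, dose_loss = "huber",
                        huber_delta = 0.5)
    set.seed(21)
    d <- 5; m <- 9
    X <- matrix(rnorm(m * d), m, d)
    Y <- matrix(rbinom(m * 8, 1, 0.4), m, 8)
    Dz <- matrix(rnorm(m * 8), m, 8)
    pw <- runif(8, 1, 3)
    params <- strabnet:::init_params(cfg, d)
    fw <- strabnet:::mlp_forward(params, X, cfg, training = TRUE)
    g <- strabnet:::mlp_backward(params, fw, X, Y, Dz, pw, cfg)
    lossfun <- function(p) {
      strabnet:::loss_from_forward(
        strabnet:::mlp_forward(p, X, cfg, training = TRUE), Y, Dz, pw, cfg)
    }
    eps <- 1e-6
    for (probe in list(c("trunk", "1", "W"), c("trunk", "2", "gamma"),
                       c("head_reg", "W"), c("head_cls", "b"))) {
      get <- function(p) purrr::reduce(probe, function(o, k) {
        if (grepl("^[0-9]+$", k)) o[[as.integer(k)]] else o[[k]]
      }, .init = p)
      gmat <- get(g)
      if (is.null(gmat)) next
      v <- get(params)
      for (i in sample(length(v), min(4, length(v)))) {
        bump <- function(sign) {
          p2 <- params
          if (length(probe) == 3) {
            p2[[probe[1]]][[as.integer(probe[2])]][[probe[3]]][i] <-
              v[i] + sign * eps
          } else {
            p2[[probe[1]]][[probe[2]]][i] <- v[i] + sign * eps
          }
          p2
        }
        num <- (lossfun(bump(1)) - lossfun(bump(-1))) / (2 * eps)
        expect_equal(gmat[i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("gradient clipping rescales to the requested global norm", {
  g <- list(trunk = list(list(W = matrix(c(3, 4), 1), b = 0,
                              gamma = 0, beta = 0)),
            head_cls = list(W = matrix(0, 1, 1), b = 0),
            head_reg = list(W = matrix(0, 1, 1), b = 0))
  expect_equal(strabnet:::global_grad_norm(g), 5)
  gc <- strabnet:::clip_global_norm(g, 1.0)
  expect_equal(strabnet:::global_grad_norm(gc), 1.0, tolerance = 1e-12)
  expect_equal(gc$trunk[[1]]$W, matrix(c(3, 4) / 5, 1))
  # a gradient of norm 10 clipped at 1 comes out with norm exactly 1
  g$trunk[[1]]$W <- matrix(c(6, 8), 1)
  expect_equal(strabnet:::global_grad_norm(strabnet:::clip_global_norm(g, 1)), 1,
               tolerance = 1e-12)
  # below the clip, gradients pass through untouched
  expect_identical(strabnet:::clip_global_norm(g, 100), g)
})

test_that("early stopping halts after `patience` epochs without improvement", {
  # strictly increasing validation loss from epoch 1
  tr <- strabnet:::early_stop_trace(seq(1, 3, length.out = 50), patience = 20)
  expect_equal(tr$best_epoch, 1L)
  expect_equal(tr$stop_epoch, 21L)
  # improvement resets the counter
  tr2 <- strabnet:::early_stop_trace(c(5, 4, 4.5, 3, 3.1, 3.2), patience = 2)
  expect_equal(tr2$best_epoch, 4L)
  expect_equal(tr2$stop_epoch, 6L)
})

test_that("training learns a separable toy task", {
  set.seed(10)
  n <- 200
  X <- matrix(rnorm(n * 2), n, 2)
  y <- as.numeric(X[, 1] > 0)
  L <- matrix(y, n, 8)
  D <- matrix(y * 4, n, 8)
  fit <- fit_strabnet(X[1:160, ], L[1:160, ], D[1:160, ], X[161:200, ],
                      L[161:200, ], D[161:200, ],
                      model_config(trunk_widths = c(16L, 8L), seed = 2L,
                                   max_epochs = 200L, patience = 50L))
  expect_lt(dplyr::last(fit$log$train_loss), fit$log$train_loss[1])
  pr <- predict(fit, X[161:200, ])
  expect_gt(auc_score(pr$prob_rmr_recess, y[161:200]), 0.95)
  expect_error(fit_strabnet(X[0, ], L[0, ], D[0, ], X, L, D, tiny_model()),
               "empty")
})

test_that("random search is reproducible and picks the dominant config", {
  co <- simulate_cohort(generator_config(n_patients = 90, seed = 17))
  prep <- fit_preprocess(co)
  X <- as.matrix(apply_preprocess(co, prep))
  L <- label_matrix(co); D <- dose_matrix(co)
  base <- tiny_model(max_epochs = 15L, patience = 5L)

  expect_error(random_search(X, L, D, list(), budget = 2, base_config = base),
               "empty")
  expect_error(random_search(X, L, D, list(dropout = c(0, 0.3)), budget = 0,
                             base_config = base), "budget")

  # degenerate budget: the single sampled config is returned
  one <- random_search(X, L, D, list(dropout = c(0.1, 0.3)), budget = 1,
                       k_inner = 2L, seed = 5, base_config = base)
  expect_equal(nrow(one$results), 1)
  expect_equal(one$best_config$dropout, one$results$dropout[1])

  # a clearly superior learning rate dominates an absurd one
  dom <- random_search(X, L, D, list(learning_rate = c(0.9e-2, 1.1e-2)),
                       budget = 3, k_inner = 2L, seed = 6, base_config = base)
  bad <- base; bad$learning_rate <- 1e3
  # score the absurd config the same way; it must lose to the selected one
  expect_true(all(dom$results$learning_rate < 1))
  expect_equal(which.min(dom$results$mean_val_loss),
               dom$results$candidate[dom$results$learning_rate ==
                                       dom$best_config$learning_rate])

  # replay: identical seed reproduces the selection and all scores
  again <- random_search(X, L, D, list(learning_rate = c(0.9e-2, 1.1e-2)),
                         budget = 3, k_inner = 2L, seed = 6, base_config = base)
  expect_equal(again$results, dom$results)
  expect_equal(again$best_config, dom$best_config)
})
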
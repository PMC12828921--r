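#' Hyper-parameters of the multi-task network
#'
#' A fully connected shared trunk (default widths 109 then 35, each layer
#' batch-normalised with ReLU activation and dropout) feeding two heads: an
#' 8-unit sigmoid classification head (muscle-procedure selection) and an
#' 8-unit linear regression head (dose, trained on a per-output standardised
#' scale and clipped to 0-10 mm at prediction time).
#'
#' @param trunk_widths Integer vector of trunk layer widths.
#' @param dropout Dropout probability in `[0, 1)`.
#' @param learning_rate Adam learning rate.
#' @param weight_decay Decoupled weight decay applied to weight matrices.
#' @param batch_size Mini-batch size.
#' @param clip_norm Global gradient-norm clip.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param lr_patience Epochs without validation improvement before the
#'   learning rate is multiplied by `lr_decay` (plateau-triggered decay;
#'   set `lr_decay = 1` to disable).
#' @param val_smooth Window (epochs) of the trailing moving average applied
#'   to the validation loss before early-stopping decisions; damps
#'   small-validation-set noise. 1 disables smoothing.
#' @param ema_decay Decay of the exponential moving average of the
#'   parameters (Polyak averaging). The averaged parameters are what gets
#'   validated and returned; 0 disables averaging.
#' @param lr_decay Multiplicative learning-rate decay factor in (0, 1].
#' @param min_lr Learning-rate floor.
#' @param max_epochs Training epoch cap.
#' @param lambda Task-mixing coefficient between the classification and
#'   regression loss terms.
#' @param dose_loss Dose-term loss: `"mse"` (squared error) or `"huber"`
#'   (quadratic within `huber_delta`, linear beyond; robust to the rare
#'   large dose residuals near surgical-rule boundaries).
#' @param huber_delta Huber transition point on the standardised dose
#'   scale.
#' @param pos_weight_cap Cap on the per-label positive-class weight
#'   `(n - n_j) / n_j` used for class-balanced loss weighting.
#' @param mask_unoperated If `TRUE`, the dose term is computed on operated
#'   muscles only instead of regressing unoperated slots to 0 mm.
#' @param batch_norm Apply batch normalisation to each trunk layer.
#' @param bn_momentum Momentum of the batch-norm running statistics.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return A `model_config` object.
#' @export
model_config <- function(trunk_widths = c(109L, 35L),
                         dropout = 0.20,
                         learning_rate = 1e-2,
                         weight_decay = 1e-4,
                         batch_size = 512L,
                         clip_norm = 1.0,
                         patience = 200L,
                         lr_patience = 50L,
                         lr_decay = 1,
                         min_lr = 1e-5,
                         val_smooth = 5L,
                         ema_decay = 0.98,
                         max_epochs = 4000L,
                         lambda = 40,
                         dose_loss = c("mse", "huber"),
                         huber_delta = 0.3,
                         pos_weight_cap = 20,
                         mask_unoperated = TRUE,
                         batch_norm = TRUE,
                         bn_momentum = 0.9,
                         seed = 1L) {
  cfg <- list(trunk_widths = as.integer(trunk_widths), dropout = dropout,
              learning_rate = learning_rate, weight_decay = weight_decay,
              batch_size = as.integer(batch_size), clip_norm = clip_norm,
              patience = as.integer(patience),
              lr_patience = as.integer(lr_patience), lr_decay = lr_decay,
              min_lr = min_lr, val_smooth = as.integer(max(1, val_smooth)),
              ema_decay = ema_decay, max_epochs = as.integer(max_epochs),
              lambda = lambda, dose_loss = match.arg(dose_loss),
              huber_delta = huber_delta, pos_weight_cap = pos_weight_cap,
              mask_unoperated = isTRUE(mask_unoperated),
              batch_norm = isTRUE(batch_norm),
              bn_momentum = bn_momentum, seed = as.integer(seed))
  class(cfg) <- "model_config"
  if (any(cfg$trunk_widths < 1)) abort("model_config: trunk widths must be >= 1")
  if (cfg$dropout < 0 || cfg$dropout >= 1) abort("model_config: dropout must be in [0, 1)")
  if (cfg$learning_rate <= 0) abort("model_config: learning_rate must be > 0")
  if (cfg$patience < 1) abort("model_config: patience must be >= 1")
  if (cfg$batch_size < 2) abort("model_config: batch_size must be >= 2")
  cfg
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> trunk", paste(x$trunk_widths, collapse = " -> "),
      "| dropout", x$dropout, "| lr", x$learning_rate,
      "| batch", x$batch_size, "| patience", x$patience, "\n")
  invisible(x)
}

# ---- initialisation ---------------------------------------------------------

xavier_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialise network parameters
#'
#' Weight matrices are drawn Xavier-uniform,
#' `U(-sqrt(6/(fan_in+fan_out)), +sqrt(6/(fan_in+fan_out)))`; biases are
#' zero; batch-norm scale/shift start at 1/0. Deterministic given
#' `config$seed`.
#'
#' @param config A [model_config()].
#' @param input_width Number of input features.
#' @return A parameter list (trunk layers plus two heads).
#' @export
init_params <- function(config, input_width) {
  withr::with_seed(config$seed, {
    widths <- c(input_width, config$trunk_widths)
    trunk <- purrr::map(seq_along(config$trunk_widths), function(l) {
      h <- widths[l + 1]
      list(W = xavier_uniform(widths[l], h), b = numeric(h),
           gamma = rep(1, h), beta = numeric(h),
           run_mean = numeric(h), run_var = rep(1, h))
    })
    top <- widths[length(widths)]
    list(trunk = trunk,
         head_cls = list(W = xavier_uniform(top, 8L), b = numeric(8L)),
         head_reg = list(W = xavier_uniform(top, 8L), b = numeric(8L)))
  })
}

#' Number of trainable parameters of a configuration
#'
#' Counts weights, biases and batch-norm scale/shift parameters of the
#' trunk plus both heads.
#'
#' @param config A [model_config()].
#' @param input_width Number of input features.
#' @return Integer parameter count.
#' @export
strabnet_n_params <- function(config, input_width = length(strabnet_features())) {
  widths <- c(input_width, config$trunk_widths)
  n <- 0L
  for (l in seq_along(config$trunk_widths)) {
    h <- widths[l + 1]
    n <- n + widths[l] * h + h + 2L * h      # W, b, gamma, beta
  }
  top <- widths[length(widths)]
  n + 2L * (top * 8L + 8L)
}

# ---- forward / backward -----------------------------------------------------

bn_eps <- 1e-5

# Forward pass. training=TRUE uses batch statistics and dropout and returns a
# cache for backprop; inference uses running statistics, no dropout.
mlp_forward <- function(params, X, config, training = FALSE) {
  if (ncol(X) != nrow(params$trunk[[1]]$W)) {
    abort(sprintf("forward: feature width %d does not match model input width %d",
                  ncol(X), nrow(params$trunk[[1]]$W)))
  }
  m <- nrow(X)
  H <- X
  cache <- list()
  for (l in seq_along(params$trunk)) {
    p <- params$trunk[[l]]
    Z <- H %*% p$W
    Z <- sweep(Z, 2, p$b, "+")
    if (!config$batch_norm) {
      mu <- NULL; va <- NULL; inv_sd <- NULL; Zhat <- Z
      A <- Z
    } else {
      if (training) {
        mu <- colMeans(Z)
        va <- colMeans(sweep(Z, 2, mu)^2)
      } else {
        mu <- p$run_mean
        va <- p$run_var
      }
      inv_sd <- 1 / sqrt(va + bn_eps)
      Zhat <- sweep(sweep(Z, 2, mu), 2, inv_sd, "*")
      A <- sweep(sweep(Zhat, 2, p$gamma, "*"), 2, p$beta, "+")
    }
    R <- pmax(A, 0)
    if (training && config$dropout > 0) {
      M <- matrix((runif(length(R)) >= config$dropout) / (1 - config$dropout),
                  nrow(R), ncol(R))
      Hn <- R * M
    } else {
      M <- NULL
      Hn <- R
    }
    cache[[l]] <- list(X_in = H, Z = Z, mu = mu, va = va, inv_sd = inv_sd,
                       Zhat = Zhat, relu_mask = (A > 0), drop_mask = M)
    H <- Hn
  }
  logits <- sweep(H %*% params$head_cls$W, 2, params$head_cls$b, "+")
  dose_z <- sweep(H %*% params$head_reg$W, 2, params$head_reg$b, "+")
  list(logits = logits, dose_z = dose_z, H_top = H,
       cache = if (training) cache else NULL)
}

# Gradient of the multi-task loss wrt all parameters, for one mini-batch.
mlp_backward <- function(params, fw, X, Y, Dz, pos_w, config) {
  m <- nrow(X)
  P <- sigmoid(fw$logits)
  W_pos <- matrix(pos_w, m, 8, byrow = TRUE)
  # d loss / d logits for mean-over-(samples x labels) weighted BCE
  d_logits <- ((1 - Y) * P - W_pos * Y * (1 - P)) / (8 * m)
  resid <- fw$dose_z - Dz
  d_dose <- if (identical(config$dose_loss, "huber")) {
    dl <- config$huber_delta
    config$lambda * clamp(resid, -dl, dl) / (8 * m)
  } else {
    config$lambda * 2 * resid / (8 * m)
  }
  if (config$mask_unoperated) d_dose <- d_dose * Y

  g <- list(trunk = vector("list", length(params$trunk)),
            head_cls = list(W = crossprod(fw$H_top, d_logits),
                            b = colSums(d_logits)),
            head_reg = list(W = crossprod(fw$H_top, d_dose),
                            b = colSums(d_dose)))
  dH <- d_logits %*% t(params$head_cls$W) + d_dose %*% t(params$head_reg$W)
  for (l in rev(seq_along(params$trunk))) {
    cc <- fw$cache[[l]]
    p <- params$trunk[[l]]
    if (!is.null(cc$drop_mask)) dH <- dH * cc$drop_mask
    dA <- dH * cc$relu_mask
    if (!config$batch_norm) {
      d_gamma <- numeric(ncol(dA)); d_beta <- numeric(ncol(dA))
      dZ <- dA
    } else {
      d_gamma <- colSums(dA * cc$Zhat)
      d_beta <- colSums(dA)
      dZhat <- sweep(dA, 2, p$gamma, "*")
      # batch-norm backward (batch statistics)
      s1 <- colSums(dZhat)
      s2 <- colSums(dZhat * cc$Zhat)
      dZ <- sweep(dZhat, 2, s1 / m) - sweep(cc$Zhat, 2, s2 / m, "*")
      dZ <- sweep(dZ, 2, cc$inv_sd, "*")
    }
    g$trunk[[l]] <- list(W = crossprod(cc$X_in, dZ), b = colSums(dZ),
                         gamma = d_gamma, beta = d_beta)
    dH <- dZ %*% t(p$W)
  }
  g
}

# ---- loss -------------------------------------------------------------------

#' Multi-task training loss
#'
#' Mean over the 8 outputs and all rows of the class-weighted binary
#' cross-entropy (positive class of label j weighted by `pos_weights[j]`)
#' plus `lambda` times the mean squared error of the dose outputs. Dose
#' targets are 0 for unoperated muscles unless `mask_unoperated`.
#'
#' @param probs n x 8 matrix of predicted probabilities.
#' @param doses n x 8 matrix of predicted doses (any consistent scale).
#' @param labels n x 8 binary matrix of reference labels.
#' @param dose_targets n x 8 matrix of reference doses (same scale as
#'   `doses`).
#' @param pos_weights Length-8 positive-class weights.
#' @param lambda Task-mixing coefficient.
#' @param mask_unoperated Restrict the dose term to operated slots.
#' @param dose_loss `"mse"` or `"huber"`.
#' @param huber_delta Huber transition point.
#' @param eps Probability clamp.
#' @return Non-negative scalar.
#' @export
multitask_loss <- function(probs, doses, labels, dose_targets,
                           pos_weights = rep(1, 8), lambda = 1,
                           mask_unoperated = FALSE, dose_loss = "mse",
                           huber_delta = 0.3, eps = 1e-7) {
  if (any(!is.finite(probs)) || any(!is.finite(doses))) {
    abort("multitask_loss: non-finite prediction")
  }
  p <- clamp(probs, eps, 1 - eps)
  W <- matrix(pos_weights, nrow(p), 8, byrow = TRUE)
  bce <- -(W * labels * log(p) + (1 - labels) * log(1 - p))
  r <- doses - dose_targets
  sq <- if (identical(dose_loss, "huber")) {
    ifelse(abs(r) <= huber_delta, r^2 / 2, huber_delta * (abs(r) - huber_delta / 2))
  } else {
    r^2
  }
  if (mask_unoperated) sq <- sq * labels
  mean(bce) + lambda * mean(sq)
}

loss_from_forward <- function(fw, Y, Dz, pos_w, config) {
  multitask_loss(sigmoid(fw$logits), fw$dose_z, Y, Dz,
                 pos_weights = pos_w, lambda = config$lambda,
                 mask_unoperated = config$mask_unoperated,
                 dose_loss = config$dose_loss,
                 huber_delta = config$huber_delta)
}

# ---- optimiser helpers ------------------------------------------------------

grad_leaves <- function(g) {
  out <- list()
  for (l in seq_along(g$trunk)) for (nm in names(g$trunk[[l]])) {
    out[[paste0("t", l, ".", nm)]] <- g$trunk[[l]][[nm]]
  }
  for (h in c("head_cls", "head_reg")) for (nm in names(g[[h]])) {
    out[[paste0(h, ".", nm)]] <- g[[h]][[nm]]
  }
  out
}

global_grad_norm <- function(g) {
  sqrt(sum(purrr::map_dbl(grad_leaves(g), ~ sum(.x^2))))
}

clip_global_norm <- function(g, clip_norm) {
  nrm <- global_grad_norm(g)
  if (is.finite(nrm) && nrm > clip_norm) {
    sc <- clip_norm / nrm
    g <- rapply(g, function(x) x * sc, how = "replace")
  }
  g
}

# elementwise a * w + b * (1 - w) over two parameter trees
tree_lerp <- function(a, b, w) {
  for (i in seq_along(a)) {
    if (is.list(a[[i]])) a[[i]] <- tree_lerp(a[[i]], b[[i]], w)
    else a[[i]] <- a[[i]] * w + b[[i]] * (1 - w)
  }
  a
}

adam_init <- function(params) {
  zero <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  list(m = rapply(params, zero, how = "replace"),
       v = rapply(params, zero, how = "replace"), t = 0L)
}

# One Adam step with decoupled weight decay on weight matrices.
adam_step <- function(params, g, state, config,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  lr <- config$learning_rate
  walk <- function(obj_params, obj_g, obj_m, obj_v) {
    # leaves are matched by name where names exist (e.g. run_mean/run_var
    # carry no gradient and are skipped); the trunk layer list is unnamed
    # and matches by position
    keys <- names(obj_params)
    idx <- if (is.null(keys)) seq_along(obj_params) else keys
    for (i in idx) {
      if (is.null(obj_g[[i]])) next
      if (is.list(obj_params[[i]])) {
        res <- walk(obj_params[[i]], obj_g[[i]], obj_m[[i]], obj_v[[i]])
        obj_params[[i]] <- res$p; obj_m[[i]] <- res$m; obj_v[[i]] <- res$v
      } else {
        p <- obj_params[[i]]; gr <- obj_g[[i]]
        mm <- beta1 * obj_m[[i]] + (1 - beta1) * gr
        vv <- beta2 * obj_v[[i]] + (1 - beta2) * gr^2
        step <- lr * (mm / bc1) / (sqrt(vv / bc2) + eps)
        decay <- if (is.matrix(p)) lr * config$weight_decay * p else 0
        obj_params[[i]] <- p - step - decay
        obj_m[[i]] <- mm; obj_v[[i]] <- vv
      }
    }
    list(p = obj_params, m = obj_m, v = obj_v)
  }
  res <- walk(params, g, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

# Early-stopping bookkeeping on a sequence of validation losses: best epoch
# and the epoch at which training halts (patience epochs without improvement).
early_stop_trace <- function(val_losses, patience, tol = 1e-9) {
  best <- Inf; best_epoch <- 0L; wait <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best - tol) {
      best <- val_losses[e]; best_epoch <- e; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(list(best_epoch = best_epoch, stop_epoch = e))
    }
  }
  list(best_epoch = best_epoch, stop_epoch = length(val_losses))
}

# ---- training ---------------------------------------------------------------

#' Fit the multi-task network
#'
#' Trains with Adam (decoupled weight decay), global gradient-norm clipping
#' and early stopping on the validation loss, returning the parameters of
#' the best validation epoch. Per-label positive-class weights
#' `(n - n_j) / n_j` (capped) are computed from the training labels; dose
#' targets are z-scored per output with training statistics.
#'
#' @param x n x d matrix (or tibble) of standardised features.
#' @param labels n x 8 binary matrix of muscle-procedure labels.
#' @param doses n x 8 matrix of doses (mm).
#' @param x_val,labels_val,doses_val Validation split (required; drives
#'   early stopping).
#' @param config A [model_config()].
#' @return A `strabnet_fit` object with elements `params`, `config`,
#'   `dose_center`, `dose_scale`, `pos_weights`, `log` (per-epoch losses),
#'   `best_epoch`, `n_params`.
#' @export
fit_strabnet <- function(x, labels, doses, x_val, labels_val, doses_val,
                         config = model_config()) {
  X <- as_feature_matrix(x); Xv <- as_feature_matrix(x_val)
  Y <- as.matrix(labels); Yv <- as.matrix(labels_val)
  D <- as.matrix(doses); Dv <- as.matrix(doses_val)
  if (nrow(X) == 0 || nrow(Xv) == 0) abort("fit_strabnet: empty train or validation set")

  n <- nrow(X)
  npos <- colSums(Y)
  pos_w <- ifelse(npos > 0, (n - npos) / pmax(npos, 1), config$pos_weight_cap)
  pos_w <- pmin(pmax(pos_w, 1), config$pos_weight_cap)

  dose_center <- colMeans(D)
  dose_scale <- apply(D, 2, sd)
  dose_scale[!is.finite(dose_scale) | dose_scale == 0] <- 1
  Dz <- sweep(sweep(D, 2, dose_center), 2, dose_scale, "/")
  Dvz <- sweep(sweep(Dv, 2, dose_center), 2, dose_scale, "/")

  params <- init_params(config, ncol(X))
  state <- adam_init(params)
  ema <- params
  use_ema <- config$ema_decay > 0
  best_params <- params
  best <- Inf; best_epoch <- 0L; wait <- 0L; lr_wait <- 0L
  lr_cfg <- config
  log <- tibble(epoch = integer(0), train_loss = numeric(0),
                val_loss = numeric(0), lr = numeric(0))

  withr::with_seed(derive_seed(config$seed, 7L), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      train_loss_acc <- 0; nb <- 0L
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        if (length(idx) < 2) next     # batch-norm needs >= 2 rows
        fw <- mlp_forward(params, X[idx, , drop = FALSE], config, training = TRUE)
        if (any(!is.finite(fw$logits)) || any(!is.finite(fw$dose_z))) {
          abort(sprintf("fit_strabnet: divergent (non-finite) loss at epoch %d", epoch))
        }
        train_loss_acc <- train_loss_acc +
          loss_from_forward(fw, Y[idx, , drop = FALSE], Dz[idx, , drop = FALSE],
                            pos_w, config)
        nb <- nb + 1L
        g <- mlp_backward(params, fw, X[idx, , drop = FALSE],
                          Y[idx, , drop = FALSE], Dz[idx, , drop = FALSE],
                          pos_w, config)
        g <- clip_global_norm(g, config$clip_norm)
        res <- adam_step(params, g, state, lr_cfg)
        params <- res$params; state <- res$state
        # batch-norm running statistics
        if (config$batch_norm) for (l in seq_along(params$trunk)) {
          cc <- fw$cache[[l]]
          mom <- config$bn_momentum
          params$trunk[[l]]$run_mean <- mom * params$trunk[[l]]$run_mean + (1 - mom) * cc$mu
          params$trunk[[l]]$run_var <- mom * params$trunk[[l]]$run_var + (1 - mom) * cc$va
        }
      }
      if (use_ema) {
        d <- config$ema_decay
        ema <- tree_lerp(ema, params, d)
      } else {
        ema <- params
      }
      fw_val <- mlp_forward(ema, Xv, config, training = FALSE)
      val_loss_raw <- loss_from_forward(fw_val, Yv, Dvz, pos_w, config)
      if (!is.finite(val_loss_raw)) {
        abort(sprintf("fit_strabnet: divergent validation loss at epoch %d", epoch))
      }
      log <- bind_rows(log, tibble(epoch = epoch,
                                   train_loss = train_loss_acc / max(nb, 1L),
                                   val_loss = val_loss_raw,
                                   lr = lr_cfg$learning_rate))
      w <- min(config$val_smooth, epoch)
      val_loss <- mean(log$val_loss[(epoch - w + 1):epoch])
      if (val_loss < best - 1e-9) {
        best <- val_loss; best_epoch <- epoch; wait <- 0L; lr_wait <- 0L
        best_params <- ema
      } else {
        wait <- wait + 1L
        lr_wait <- lr_wait + 1L
        if (wait >= config$patience) break
        if (config$lr_decay < 1 && lr_wait >= config$lr_patience &&
            lr_cfg$learning_rate * config$lr_decay >= config$min_lr) {
          lr_cfg$learning_rate <- lr_cfg$learning_rate * config$lr_decay
          lr_wait <- 0L
        }
      }
    }
  })

  structure(list(params = best_params, config = config,
                 input_width = ncol(X), feature_names = colnames(X),
                 dose_center = dose_center, dose_scale = dose_scale,
                 pos_weights = pos_w, log = log, best_epoch = best_epoch,
                 n_params = strabnet_n_params(config, ncol(X))),
            class = "strabnet_fit")
}

#' @export
print.strabnet_fit <- function(x, ...) {
  cat("<strabnet_fit>", x$input_width, "->",
      paste(x$config$trunk_widths, collapse = " -> "), "-> (8 + 8)\n")
  cat("  parameters:", x$n_params,
      "| best epoch:", x$best_epoch, "of", nrow(x$log), "run\n")
  cat(sprintf("  best validation loss: %.5f\n", min(x$log$val_loss)))
  invisible(x)
}

#' Predict probabilities, logits and doses for new records
#'
#' Inference is deterministic: batch-norm uses frozen running statistics
#' and dropout is disabled. Dose outputs are mapped back to mm and clipped
#' to 0-10.
#'
#' @param object A `strabnet_fit`.
#' @param newdata Matrix/tibble of standardised features.
#' @param ... Unused.
#' @return Tibble with `logit_*`, `prob_*` and `dose_*` columns per label.
#' @export
predict.strabnet_fit <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  fw <- mlp_forward(object$params, X, object$config, training = FALSE)
  probs <- sigmoid(fw$logits)
  doses <- clamp(sweep(sweep(fw$dose_z, 2, object$dose_scale, "*"),
                       2, object$dose_center, "+"), 0, 10)
  colnames(fw$logits) <- paste0("logit_", plan_labels())
  colnames(probs) <- paste0("prob_", plan_labels())
  colnames(doses) <- paste0("dose_", plan_labels())
  bind_cols(as_tibble(fw$logits), as_tibble(probs), as_tibble(doses))
}

#' @export
tidy.strabnet_fit <- function(x, ...) x$log

#' @export
glance.strabnet_fit <- function(x, ...) {
  tibble(n_params = x$n_params, epochs_run = nrow(x$log),
         best_epoch = x$best_epoch, best_val_loss = min(x$log$val_loss))
}

# ---- random search ----------------------------------------------------------

#' Random-search hyper-parameter tuning
#'
#' Samples `budget` configurations uniformly from `space` (trunk widths and
#' batch size uniform over integers/choices, dropout uniform, learning rate
#' log-uniform), scores each by the mean best-epoch validation loss over
#' `k_inner` seeded inner folds, and returns the argmin. Fully reproducible
#' from `seed`.
#'
#' @param x,labels,doses Training data (standardised features, 8-label
#'   matrix, dose matrix in mm).
#' @param space Named list of ranges: `trunk1 = c(lo, hi)`,
#'   `trunk2 = c(lo, hi)`, `dropout = c(lo, hi)`,
#'   `learning_rate = c(lo, hi)`, `batch_size = <choices>`. Omitted entries
#'   fall back to the value in `base_config`.
#' @param budget Number of sampled configurations (>= 1).
#' @param k_inner Number of inner folds.
#' @param seed Integer seed.
#' @param base_config Defaults for fields not searched.
#' @return List with `best_config` (a [model_config()]) and `results` (one
#'   row per candidate with its mean inner validation loss).
#' @export
random_search <- function(x, labels, doses, space, budget,
                          k_inner = 3L, seed = 1L,
                          base_config = model_config()) {
  if (budget < 1) abort("random_search: budget must be >= 1")
  if (!is.list(space) || length(space) == 0) {
    abort("random_search: empty search space")
  }
  X <- as_feature_matrix(x); Y <- as.matrix(labels); D <- as.matrix(doses)
  n <- nrow(X)
  if (n < 2 * k_inner) abort("random_search: too few rows for the inner folds")

  draw_config <- function() {
    tw <- base_config$trunk_widths
    if (!is.null(space$trunk1)) {
      tw[1] <- sample(space$trunk1[1]:space$trunk1[2], 1L)
    }
    if (!is.null(space$trunk2) && length(tw) >= 2) {
      tw[2] <- sample(space$trunk2[1]:space$trunk2[2], 1L)
    }
    dr <- if (!is.null(space$dropout)) runif(1, space$dropout[1], space$dropout[2]) else base_config$dropout
    lr <- if (!is.null(space$learning_rate)) {
      exp(runif(1, log(space$learning_rate[1]), log(space$learning_rate[2])))
    } else base_config$learning_rate
    bs <- if (!is.null(space$batch_size)) sample(space$batch_size, 1L) else base_config$batch_size
    modifyList(base_config,
               list(trunk_widths = as.integer(tw), dropout = dr,
                    learning_rate = lr, batch_size = as.integer(bs)))
  }

  withr::with_seed(seed, {
    candidates <- purrr::map(seq_len(budget), ~ draw_config())
    fold_of <- sample(rep(seq_len(k_inner), length.out = n))
    scores <- purrr::map_dbl(seq_len(budget), function(i) {
      cfg <- candidates[[i]]
      cfg$seed <- derive_seed(seed, i)
      losses <- purrr::map_dbl(seq_len(k_inner), function(f) {
        tr <- fold_of != f; va <- !tr
        fit <- fit_strabnet(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                            D[tr, , drop = FALSE], X[va, , drop = FALSE],
                            Y[va, , drop = FALSE], D[va, , drop = FALSE],
                            config = cfg)
        min(fit$log$val_loss)
      })
      mean(losses)
    })
  })
  results <- tibble(
    candidate = seq_len(budget),
    trunk1 = purrr::map_int(candidates, ~ .x$trunk_widths[1]),
    trunk2 = purrr::map_int(candidates, ~ .x$trunk_widths[min(2, length(.x$trunk_widths))]),
    dropout = purrr::map_dbl(candidates, "dropout"),
    learning_rate = purrr::map_dbl(candidates, "learning_rate"),
    batch_size = purrr::map_int(candidates, "batch_size"),
    mean_val_loss = scores
  )
  best <- candidates[[which.min(scores)]]
  class(best) <- "model_config"
  list(best_config = best, results = results)
}
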
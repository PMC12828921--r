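# shared fixtures, all generated in code

# small noiseless generator for invariant checks
quiet_config <- function(n = 200, seed = 101,
                         label_flip_rate = 0, dose_noise_sd = 0) {
  generator_config(n_patients = n, seed = seed,
                   label_flip_rate = label_flip_rate,
                   dose_noise_sd = dose_noise_sd)
}

# a tiny model configuration that trains in well under a second
tiny_model <- function(...) {
  args <- utils::modifyList(
    list(trunk_widths = c(16L, 8L), max_epochs = 60L, patience = 15L,
         batch_size = 64L),
    list(...))
  do.call(model_config, args)
}

label_matrix <- function(cohort) as.matrix(cohort[paste0("label_", plan_labels())])
dose_matrix <- function(cohort) as.matrix(cohort[paste0("dose_", plan_labels())])

# one moderately trained fit on a small simulated cohort, shared across
# tests (memoised; built on first use)
shared_fit_env <- new.env(parent = emptyenv())
shared_sim_fit <- function() {
  if (!is.null(shared_fit_env$fit)) return(shared_fit_env$payload)
  co <- simulate_cohort(generator_config(n_patients = 300, seed = 77))
  prep <- fit_preprocess(co)
  X <- as.matrix(apply_preprocess(co, prep))
  L <- label_matrix(co); D <- dose_matrix(co)
  tr <- 1:240; va <- 241:300
  fit <- fit_strabnet(X[tr, ], L[tr, ], D[tr, ], X[va, ], L[va, ], D[va, ],
                      model_config(max_epochs = 600L, patience = 60L, seed = 5L))
  shared_fit_env$fit <- fit
  shared_fit_env$payload <- list(fit = fit, cohort = co, prep = prep,
                                 X = X, L = L, D = D, tr = tr, va = va)
  shared_fit_env$payload
}
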
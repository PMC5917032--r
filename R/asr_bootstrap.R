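## Six-step bootstrap propagating mark-recapture sampling uncertainty into
## the equilibrium adult sex ratio: resample histories, refit the CJS model
## set, take the lowest-AICc survival estimates, rebuild the two-sex matrix,
## project to equilibrium, record ASR.

#' Bootstrap the equilibrium adult sex ratio
#'
#' Each iteration (i) resamples the encounter histories with replacement,
#' stratified by stage at marking, (ii) refits every candidate CJS model,
#' (iii) selects the fit with the lowest AICc, (iv) assembles the two-sex
#' parameters from that fit's joint survival estimates together with the fixed
#' reproduction inputs, (v) projects the nonlinear model over `steps` time
#' steps, and (vi) records ASR from the terminal stable structure. Carrying
#' each resample's joint survival estimates into a single matrix preserves the
#' parameter correlations, and the repeated model selection keeps
#' model-selection uncertainty inside the interval.
#'
#' @param histories An [as_encounter_histories] table.
#' @param params_fixed Named list with the reproduction inputs held at their
#'   point estimates: `rho`, `k`, `h`.
#' @param model_set List of [cjs_model_spec] objects (default: all 8 detection
#'   models).
#' @param B Number of bootstrap iterations.
#' @param steps Projection horizon per iteration.
#' @param seed Integer seed (iteration i uses a child seed derived from it).
#' @param n_starts Optimisation starts per CJS fit (1 is enough in resamples:
#'   each fit starts from the full-data estimates).
#' @return A list of class `asr_bootstrap` with `replicates` (length `B`),
#'   `mean`, `ci` (percentile 2.5/97.5%), `per_replicate_model` (winning
#'   detection-model label per iteration), `model_freq`, `n_failed`
#'   (iterations redrawn after fit failure), `seed`.
#' @export
bootstrap_asr <- function(histories, params_fixed, model_set = cjs_model_set(),
                          B = 1000, steps = 1000, seed = 1L, n_starts = 1) {
  histories <- as_encounter_histories(histories)
  stopifnot(B >= 1)
  if (!all(c("rho", "k", "h") %in% names(params_fixed)))
    stop("params_fixed must supply rho, k and h", call. = FALSE)

  ## full-data fits provide warm starts for every resample
  base_fits <- lapply(model_set, function(sp)
    tryCatch(fit_cjs(histories, sp, n_starts = 5, seed = seed),
             error = function(e) NULL))
  starts <- lapply(base_fits, function(f) if (is.null(f)) NULL else f$beta)

  replicates <- numeric(B)
  winners <- character(B)
  n_failed <- 0L
  max_failures <- max(1, ceiling(0.1 * B))
  b <- 1L
  attempt <- 0L
  while (b <= B) {
    attempt <- attempt + 1L
    it_seed <- child_seed(seed, "bootstrap", attempt)
    res <- tryCatch({
      hb <- resample_histories(histories, seed = it_seed)
      fits <- Map(function(sp, st)
        tryCatch(fit_cjs(hb, sp, n_starts = n_starts, seed = it_seed,
                         start = st),
                 error = function(e) NULL),
        model_set, starts)
      fits <- Filter(Negate(is.null), fits)
      best <- select_best_model(fits)
      sv <- survival_parameters(best)
      if (any(vapply(sv, function(z) length(z) != 1L || !is.finite(z),
                     logical(1))))
        stop("missing survival cell in resample")
      p <- two_sex_params(sv$phi_fj, sv$phi_mj, sv$phi_fa, sv$phi_ma,
                          rho = params_fixed$rho, k = params_fixed$k,
                          h = params_fixed$h)
      st <- suppressWarnings(stable_structure(p, steps = steps))
      list(asr = st$asr, model = best$spec$label)
    }, error = function(e) NULL)
    if (is.null(res) || !is.finite(res$asr)) {
      n_failed <- n_failed + 1L
      if (n_failed > max_failures)
        stop("more than 10% of bootstrap iterations failed (",
             n_failed, " failures)", call. = FALSE)
      next
    }
    replicates[b] <- res$asr
    winners[b] <- res$model
    b <- b + 1L
  }
  ci <- unname(stats::quantile(replicates, c(0.025, 0.975), type = 7))
  structure(list(replicates = replicates, mean = mean(replicates),
                 ci_low = ci[1], ci_high = ci[2],
                 per_replicate_model = winners,
                 model_freq = sort(table(winners), decreasing = TRUE),
                 n_failed = n_failed, B = B, seed = seed),
            class = "asr_bootstrap")
}

#' @export
print.asr_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap ASR: mean %.3f [%.3f, %.3f] (B = %d, %d redrawn)\n",
              x$mean, x$ci_low, x$ci_high, x$B, x$n_failed))
  cat("  winning detection models:\n")
  print(x$model_freq)
  invisible(x)
}
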
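## Cormack-Jolly-Seber estimation of sex- and stage-specific apparent survival.
##
## Histories are annual detection records conditioned on first capture.
## Survival is modelled on the logit scale with a fixed phi ~ sex * stage
## structure (cell means over female/male x juvenile/adult); detection models
## range over all subsets of {sex, year, stage} with full interactions among
## included terms. Individuals marked as hatchlings are juveniles on their
## first interval (and first re-encounter occasion) and adults thereafter.

#' Validate a table of encounter histories
#'
#' @param df A data.frame with columns `id`, `sex` (`"F"`/`"M"`),
#'   `stage_at_marking` (`"hatchling"`/`"adult"`), optionally `population`,
#'   and annual detection columns `y1 ... yN` of 0/1 indicators.
#' @return The validated data.frame with class `encounter_histories`.
#' @export
as_encounter_histories <- function(df) {
  df <- as.data.frame(df)
  need <- c("id", "sex", "stage_at_marking")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  ycols <- grep("^y[0-9]+$", names(df), value = TRUE)
  ycols <- ycols[order(as.integer(sub("^y", "", ycols)))]
  if (length(ycols) < 2L)
    stop("need at least 2 annual detection columns y1, y2, ...", call. = FALSE)
  det <- as.matrix(df[, ycols, drop = FALSE])
  if (!all(det %in% c(0, 1)))
    stop("detection columns must be 0/1", call. = FALSE)
  if (any(rowSums(det) == 0))
    stop("every encounter history must contain at least one detection",
         call. = FALSE)
  if (!all(df$sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M'", call. = FALSE)
  if (!all(df$stage_at_marking %in% c("hatchling", "adult")))
    stop("stage_at_marking must be 'hatchling' or 'adult'", call. = FALSE)
  class(df) <- unique(c("encounter_histories", class(df)))
  df
}

.detection_cols <- function(histories) {
  ycols <- grep("^y[0-9]+$", names(histories), value = TRUE)
  ycols[order(as.integer(sub("^y", "", ycols)))]
}

.detection_matrix <- function(histories) {
  as.matrix(histories[, .detection_cols(histories), drop = FALSE])
}

#' Specify a CJS model
#'
#' Survival is always modelled as the full sex-by-stage interaction; candidate
#' models differ only in their detection structure.
#'
#' @param p_terms Character subset of `c("sex", "year", "stage")`; detection
#'   probability gets one parameter per cell of the full interaction among the
#'   included terms (empty set = constant detection).
#' @return A `cjs_model_spec` object.
#' @export
cjs_model_spec <- function(p_terms = character()) {
  p_terms <- as.character(p_terms)
  if (!all(p_terms %in% c("sex", "year", "stage")))
    stop("p_terms must be a subset of {sex, year, stage}", call. = FALSE)
  p_terms <- intersect(c("sex", "year", "stage"), unique(p_terms))
  label <- if (length(p_terms)) paste(p_terms, collapse = "*") else "1"
  structure(list(phi_terms = "sex*stage", p_terms = p_terms,
                 label = paste0("phi~sex*stage, p~", label)),
            class = "cjs_model_spec")
}

#' The candidate detection-model set
#'
#' All 8 subsets of `{sex, year, stage}`, each with full interactions among
#' the included terms and `phi ~ sex * stage` throughout.
#'
#' @return A named list of [cjs_model_spec] objects.
#' @export
cjs_model_set <- function() {
  terms <- c("sex", "year", "stage")
  specs <- list()
  for (i in 0:7) {
    inc <- terms[bitwAnd(i, c(1L, 2L, 4L)) > 0]
    sp <- cjs_model_spec(inc)
    specs[[sp$label]] <- sp
  }
  specs[order(names(specs))]
}

## Aggregate histories into weighted classes and precompute parameter-cell
## index matrices for the likelihood.
.build_cjs_data <- function(histories, spec) {
  histories <- as_encounter_histories(histories)
  det <- .detection_matrix(histories)
  T_ <- ncol(det)
  first_all <- max.col(det, ties.method = "first")
  key <- paste(histories$sex, histories$stage_at_marking,
               do.call(paste0, as.data.frame(det)), sep = "|")
  idx <- !duplicated(key)
  counts <- as.vector(table(key)[key[idx]])
  det <- det[idx, , drop = FALSE]
  sex <- histories$sex[idx]
  stg <- histories$stage_at_marking[idx]
  first <- first_all[idx]
  last <- T_ + 1L - max.col(det[, T_:1L, drop = FALSE], ties.method = "first")
  nc <- nrow(det)

  phi_lab <- matrix(NA_character_, nc, T_ - 1L)
  p_lab <- matrix(NA_character_, nc, T_)
  for (i in seq_len(nc)) {
    f <- first[i]
    ## a release on the final occasion contributes nothing to the likelihood
    if (f >= T_) next
    for (t in f:(T_ - 1L)) {
      st <- if (stg[i] == "hatchling" && t == f) "J" else "A"
      phi_lab[i, t] <- paste0("phi:", sex[i], ":", st)
    }
    for (t in (f + 1L):T_) {
      parts <- character()
      if ("sex" %in% spec$p_terms) parts <- c(parts, sex[i])
      if ("year" %in% spec$p_terms) parts <- c(parts, paste0("t", t))
      if ("stage" %in% spec$p_terms)
        parts <- c(parts, if (stg[i] == "hatchling" && t == f + 1L) "J" else "A")
      p_lab[i, t] <- paste0("p:", if (length(parts)) paste(parts, collapse = ":")
                            else "const")
    }
  }
  phi_cells <- sort(unique(stats::na.omit(as.vector(phi_lab))))
  p_cells <- sort(unique(stats::na.omit(as.vector(p_lab))))
  par_names <- c(phi_cells, p_cells)
  lookup <- stats::setNames(seq_along(par_names), par_names)
  phi_idx <- matrix(lookup[phi_lab], nc, T_ - 1L)
  p_idx <- matrix(lookup[p_lab], nc, T_)

  mask_s <- matrix(FALSE, nc, T_ - 1L)
  for (i in seq_len(nc))
    if (last[i] > first[i]) mask_s[i, first[i]:(last[i] - 1L)] <- TRUE

  list(det = det, counts = counts, first = first, last = last, sex = sex,
       stage = stg, n_class = nc, n_occ = T_, par_names = par_names,
       phi_idx = phi_idx, p_idx = p_idx, mask_s = mask_s,
       n_ind = nrow(histories), n_eff = sum(T_ - first_all))
}

.cjs_loglik_cells <- function(beta, dat, clip = 0) {
  T_ <- dat$n_occ
  phi <- matrix(stats::plogis(beta[dat$phi_idx]), dat$n_class, T_ - 1L)
  p <- matrix(stats::plogis(beta[dat$p_idx]), dat$n_class, T_)
  if (clip > 0) {
    phi <- pmin(pmax(phi, clip), 1 - clip)
    p <- pmin(pmax(p, clip), 1 - clip)
  }
  phi[is.na(phi)] <- 0.5
  p[is.na(p)] <- 0.5
  ## chi_t = P(never seen after occasion t | alive at t)
  chi <- matrix(1, dat$n_class, T_)
  for (t in (T_ - 1L):1L)
    chi[, t] <- (1 - phi[, t]) + phi[, t] * (1 - p[, t + 1L]) * chi[, t + 1L]
  y_next <- dat$det[, 2:T_, drop = FALSE]
  p_next <- p[, 2:T_, drop = FALSE]
  surv_terms <- log(phi) + y_next * log(p_next) + (1 - y_next) * log(1 - p_next)
  ll <- rowSums(ifelse(dat$mask_s, surv_terms, 0)) +
    log(chi[cbind(seq_len(dat$n_class), dat$last)])
  sum(dat$counts * ll)
}

## Analytic score of the cell-means likelihood. Direct terms differentiate
## the survival/detection products over the observed stretch; the chi tail is
## handled by backward accumulation of d log chi_last / d(phi_s, p_{s+1}).
.cjs_grad_cells <- function(beta, dat, clip = 0) {
  T_ <- dat$n_occ
  nc <- dat$n_class
  phi <- matrix(stats::plogis(beta[dat$phi_idx]), nc, T_ - 1L)
  p <- matrix(stats::plogis(beta[dat$p_idx]), nc, T_)
  if (clip > 0) {
    phi <- pmin(pmax(phi, clip), 1 - clip)
    p <- pmin(pmax(p, clip), 1 - clip)
  }
  phi[is.na(phi)] <- 0.5
  p[is.na(p)] <- 0.5
  chi <- matrix(1, nc, T_)
  for (t in (T_ - 1L):1L)
    chi[, t] <- (1 - phi[, t]) + phi[, t] * (1 - p[, t + 1L]) * chi[, t + 1L]
  y_next <- dat$det[, 2:T_, drop = FALSE]
  last <- dat$last

  dphi <- ifelse(dat$mask_s, 1 / phi, 0)
  dp <- matrix(0, nc, T_)
  dp[, 2:T_] <- ifelse(dat$mask_s,
                       y_next / p[, 2:T_, drop = FALSE] -
                         (1 - y_next) / (1 - p[, 2:T_, drop = FALSE]), 0)

  ## cum[, s] = d chi_last / d chi_s along the never-seen tail (0 for s < last)
  cum <- matrix(0, nc, T_ - 1L)
  chi_last <- chi[cbind(seq_len(nc), last)]
  for (s in seq_len(T_ - 1L)) {
    at <- last == s
    if (any(at)) cum[at, s] <- 1
    if (s > 1L) {
      carry <- last < s
      if (any(carry))
        cum[carry, s] <- cum[carry, s - 1L] * phi[carry, s - 1L] *
          (1 - p[carry, s])
    }
  }
  for (s in seq_len(T_ - 1L)) {
    act <- cum[, s] > 0
    if (!any(act)) next
    w <- cum[act, s] / chi_last[act]
    dphi[act, s] <- dphi[act, s] +
      w * (-1 + (1 - p[act, s + 1L]) * chi[act, s + 1L])
    dp[act, s + 1L] <- dp[act, s + 1L] + w * (-phi[act, s] * chi[act, s + 1L])
  }

  gphi <- dat$counts * dphi * phi * (1 - phi)
  gp <- dat$counts * dp * p * (1 - p)
  grad <- numeric(length(beta))
  ok <- !is.na(dat$phi_idx)
  gsum <- rowsum(as.vector(gphi)[ok], as.vector(dat$phi_idx)[ok])
  grad[as.integer(rownames(gsum))] <- gsum
  ok <- !is.na(dat$p_idx)
  gsum <- rowsum(as.vector(gp)[ok], as.vector(dat$p_idx)[ok])
  grad[as.integer(rownames(gsum))] <-
    grad[as.integer(rownames(gsum))] + gsum
  grad
}

#' CJS log-likelihood
#'
#' Evaluates the Cormack-Jolly-Seber log-likelihood, conditional on first
#' capture, for coefficients on the logit scale under a given model
#' specification. Uses per-interval survival/detection products and the
#' never-seen-again recursion
#' `chi_t = (1 - phi_t) + phi_t (1 - p_{t+1}) chi_{t+1}`.
#'
#' @param beta Numeric coefficient vector, one logit per parameter cell (in
#'   the order given by `cjs_parameter_names()`).
#' @param histories An [as_encounter_histories] table.
#' @param spec A [cjs_model_spec].
#' @return The log-likelihood (scalar, never positive). A warning is issued if
#'   it is non-finite.
#' @export
cjs_log_likelihood <- function(beta, histories, spec = cjs_model_spec()) {
  dat <- .build_cjs_data(histories, spec)
  if (length(beta) != length(dat$par_names))
    stop("coefficient vector has length ", length(beta), " but the model has ",
         length(dat$par_names), " parameters", call. = FALSE)
  ll <- .cjs_loglik_cells(beta, dat)
  if (!is.finite(ll))
    warning("non-finite log-likelihood at the supplied coefficients",
            call. = FALSE)
  ll
}

#' Parameter cell names for a CJS model on a dataset
#'
#' @inheritParams cjs_log_likelihood
#' @return Character vector naming the identifiable parameter cells (survival
#'   cells first, then detection cells), defining the coefficient order used
#'   by [cjs_log_likelihood] and [fit_cjs].
#' @export
cjs_parameter_names <- function(histories, spec = cjs_model_spec()) {
  .build_cjs_data(histories, spec)$par_names
}

#' Fit a CJS model by maximum likelihood
#'
#' Maximises the conditional CJS likelihood on the logit scale by quasi-Newton
#' optimisation with random multi-starts, then back-transforms to survival and
#' detection probabilities. When detection varies by year the final interval's
#' survival and detection are only identified through their product; survival
#' estimates reported in `phi_hat` come from the time-constant
#' `sex * stage` survival cells, which are unaffected.
#'
#' @param histories An [as_encounter_histories] table with >= 2 occasions.
#' @param spec A [cjs_model_spec].
#' @param n_starts Number of optimisation starts (the first at 0, the rest
#'   random).
#' @param seed Integer seed for the random starts.
#' @param start Optional named start vector (matched to parameter cells by
#'   name); used as the first start.
#' @return An object of class `cjs_fit` with elements `spec`, `beta`, `vcov`,
#'   `phi_hat` (data.frame of survival estimates and standard errors by sex
#'   and stage), `p_hat` (named detection estimates), `logL`, `K`, `n_eff`,
#'   `AICc`, `converged`, `boundary`.
#' @export
fit_cjs <- function(histories, spec = cjs_model_spec(), n_starts = 5,
                    seed = NULL, start = NULL) {
  dat <- .build_cjs_data(histories, spec)
  npar <- length(dat$par_names)
  obj <- function(b) {
    ll <- .cjs_loglik_cells(b, dat, clip = 1e-12)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  grd <- function(b) -.cjs_grad_cells(b, dat, clip = 1e-12)
  starts <- list(rep(0, npar))
  if (!is.null(start)) {
    s0 <- rep(0, npar)
    common <- intersect(names(start), dat$par_names)
    s0[match(common, dat$par_names)] <- start[common]
    starts[[1]] <- s0
  }
  if (n_starts > 1) {
    rs <- with_seed(if (is.null(seed)) 1L else seed, {
      lapply(seq_len(n_starts - 1L), function(i) stats::rnorm(npar, 0, 1.5))
    })
    starts <- c(starts, rs)
  }
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj, gr = grd, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all optimisation starts failed", call. = FALSE)
  ## polish + hessian at the optimum
  pol <- tryCatch(
    stats::optim(best$par, obj, gr = grd, method = "BFGS", hessian = TRUE,
                 control = list(maxit = 200, reltol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value + 1e-8) best <- pol
  beta <- stats::setNames(best$par, dat$par_names)
  H <- best$hessian
  vcov <- if (!is.null(H)) tryCatch(solve(H), error = function(e)
    matrix(NA_real_, npar, npar)) else matrix(NA_real_, npar, npar)
  dimnames(vcov) <- list(dat$par_names, dat$par_names)
  boundary <- any(abs(beta) > 9)
  converged <- !is.null(best$convergence) && best$convergence == 0

  phi_cells <- grep("^phi:", dat$par_names, value = TRUE)
  se_beta <- sqrt(pmax(diag(vcov), 0))
  grid <- expand.grid(sex = c("F", "M"), stage = c("J", "A"),
                      stringsAsFactors = FALSE)
  cell <- paste0("phi:", grid$sex, ":", grid$stage)
  est <- ifelse(cell %in% phi_cells, stats::plogis(beta[cell]), NA_real_)
  seb <- ifelse(cell %in% phi_cells, se_beta[match(cell, dat$par_names)],
                NA_real_)
  phi_hat <- data.frame(sex = grid$sex, stage = grid$stage,
                        estimate = as.numeric(est),
                        se = as.numeric(est * (1 - est) * seb),
                        logit = as.numeric(ifelse(cell %in% phi_cells,
                                                  beta[cell], NA_real_)),
                        logit_se = as.numeric(seb),
                        row.names = cell)
  p_cells <- grep("^p:", dat$par_names, value = TRUE)
  p_hat <- stats::setNames(stats::plogis(beta[p_cells]), p_cells)

  logL <- -best$value
  K <- npar
  fit <- structure(list(spec = spec, beta = beta, vcov = vcov,
                        phi_hat = phi_hat, p_hat = p_hat, logL = logL, K = K,
                        n_eff = dat$n_eff, n_histories = dat$n_ind,
                        n_occasions = dat$n_occ,
                        AICc = aicc(logL, K, dat$n_eff),
                        converged = converged, boundary = boundary),
                   class = "cjs_fit")
  fit
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat("CJS fit:", x$spec$label, "\n")
  cat(sprintf("  logL = %.3f  K = %d  n_eff = %d  AICc = %.3f%s%s\n",
              x$logL, x$K, x$n_eff, x$AICc,
              if (x$converged) "" else "  [NOT CONVERGED]",
              if (x$boundary) "  [boundary]" else ""))
  cat("  apparent survival:\n")
  print(x$phi_hat[, c("sex", "stage", "estimate", "se")], digits = 3)
  invisible(x)
}

#' Survival point estimates as a two-sex parameter block
#'
#' @param fit A `cjs_fit`.
#' @return Named list `phi_fj`, `phi_mj`, `phi_fa`, `phi_ma`.
#' @export
survival_parameters <- function(fit) {
  stopifnot(inherits(fit, "cjs_fit"))
  ph <- fit$phi_hat
  pick <- function(s, st) ph$estimate[ph$sex == s & ph$stage == st]
  list(phi_fj = pick("F", "J"), phi_mj = pick("M", "J"),
       phi_fa = pick("F", "A"), phi_ma = pick("M", "A"))
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logL + 2K + 2K(K+1) / (n_eff - K - 1)`, with the effective
#' sample size taken as the number of released individual-occasions.
#'
#' @param logL Maximised log-likelihood.
#' @param K Number of estimated parameters.
#' @param n_eff Effective sample size; must exceed `K + 1`.
#' @return The AICc value.
#' @export
aicc <- function(logL, K, n_eff) {
  if (n_eff <= K + 1)
    stop("AICc undefined for n_eff <= K + 1; consider plain AIC",
         call. = FALSE)
  -2 * logL + 2 * K + 2 * K * (K + 1) / (n_eff - K - 1)
}

#' Select the best model by AICc
#'
#' @param fits A list of `cjs_fit` objects.
#' @return The converged fit with minimum AICc; ties broken by smaller `K`,
#'   then by the lexicographically first detection-model label.
#' @export
select_best_model <- function(fits) {
  fits <- Filter(function(f) inherits(f, "cjs_fit") && f$converged, fits)
  if (!length(fits)) stop("no converged fits to select from", call. = FALSE)
  a <- vapply(fits, function(f) f$AICc, numeric(1))
  k <- vapply(fits, function(f) as.numeric(f$K), numeric(1))
  lab <- vapply(fits, function(f) f$spec$label, character(1))
  ord <- order(a, k, lab)
  fits[[ord[1]]]
}

#' Resample encounter histories with replacement
#'
#' Nonparametric bootstrap resample, stratified by stage at marking so that
#' the juvenile and adult release structure is preserved.
#'
#' @param histories An [as_encounter_histories] table.
#' @param seed Integer seed.
#' @return A resampled table of the same size and class.
#' @export
resample_histories <- function(histories, seed = NULL) {
  histories <- as_encounter_histories(histories)
  if (!nrow(histories)) stop("no histories to resample", call. = FALSE)
  draw <- function() {
    idx <- unlist(lapply(split(seq_len(nrow(histories)),
                               histories$stage_at_marking),
                         function(ii) ii[sample.int(length(ii),
                                                    length(ii),
                                                    replace = TRUE)]),
                  use.names = FALSE)
    histories[sort(idx), , drop = FALSE]
  }
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  rownames(out) <- NULL
  out
}

#' Simulate encounter histories under known CJS parameters
#'
#' Forward simulation of marked individuals: each is released (first detected)
#' at a given occasion, survives each subsequent interval with its sex- and
#' stage-specific probability, and, while alive, is detected on each later
#' occasion with the detection probability. Histories are conditioned on the
#' marking detection, matching the CJS likelihood's conditioning on first
#' capture.
#'
#' @param n Number of individuals.
#' @param n_occasions Number of annual occasions (>= 2).
#' @param phi Named vector/list with `phi_fj`, `phi_mj`, `phi_fa`, `phi_ma`.
#' @param p Detection probability: a scalar, or a function `(sex, stage, occ)`
#'   returning a probability.
#' @param prop_hatchling Proportion of releases marked as hatchlings.
#' @param prop_female Proportion female.
#' @param first Release occasions: a vector recycled over individuals, or NULL
#'   to spread releases uniformly over occasions `1 .. n_occasions - 1`.
#' @param seed Integer seed.
#' @return An `encounter_histories` table.
#' @export
simulate_cjs_histories <- function(n, n_occasions, phi, p,
                                   prop_hatchling = 0.5, prop_female = 0.5,
                                   first = NULL, seed = NULL) {
  stopifnot(n >= 1, n_occasions >= 2)
  p_fun <- if (is.function(p)) p else function(sex, stage, occ) p
  run <- function() {
    sex <- ifelse(stats::runif(n) < prop_female, "F", "M")
    stg <- ifelse(stats::runif(n) < prop_hatchling, "hatchling", "adult")
    f <- if (is.null(first))
      sample(rep_len(seq_len(n_occasions - 1L), n)) else rep_len(first, n)
    det <- matrix(0L, n, n_occasions)
    det[cbind(seq_len(n), f)] <- 1L
    for (i in seq_len(n)) {
      alive <- TRUE
      for (t in f[i]:(n_occasions - 1L)) {
        st <- if (stg[i] == "hatchling" && t == f[i]) "J" else "A"
        ph <- phi[[paste0("phi_", tolower(sex[i]), tolower(st))]]
        alive <- alive && stats::runif(1) < ph
        if (!alive) break
        st_next <- if (stg[i] == "hatchling" && t + 1L == f[i] + 1L) "J" else "A"
        if (stats::runif(1) < p_fun(sex[i], st_next, t + 1L))
          det[i, t + 1L] <- 1L
      }
    }
    out <- data.frame(id = paste0("ind", seq_len(n)), population = "sim",
                      sex = sex, stage_at_marking = stg)
    det <- as.data.frame(det)
    names(det) <- paste0("y", seq_len(n_occasions))
    as_encounter_histories(cbind(out, det))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Parametric-bootstrap dispersion diagnostic
#'
#' Simulates datasets from the fitted model (same releases: first occasions,
#' sexes and stages as observed), refits, and returns the ratio of the
#' observed deviance to the mean simulated deviance. Values near 1 indicate
#' adequate dispersion; values above ~3 indicate serious lack of fit.
#'
#' @param fit A converged `cjs_fit`.
#' @param histories The data the fit was computed from.
#' @param n_boot Number of parametric-bootstrap datasets (a warning is issued
#'   below 20).
#' @param seed Integer seed.
#' @return A list with `c_hat`, the observed deviance `dev_obs`, and the
#'   vector of simulated deviances `dev_sim`.
#' @export
dispersion_check <- function(fit, histories, n_boot = 100, seed = 1L) {
  stopifnot(inherits(fit, "cjs_fit"))
  if (!fit$converged) stop("dispersion check requires a converged fit",
                           call. = FALSE)
  if (n_boot < 20)
    warning("n_boot < 20 gives an unstable dispersion estimate",
            call. = FALSE)
  histories <- as_encounter_histories(histories)
  det <- .detection_matrix(histories)
  T_ <- ncol(det)
  f <- apply(det == 1, 1L, which.max)
  sex <- histories$sex
  stg <- histories$stage_at_marking
  beta <- fit$beta
  cell_p <- function(sex_i, stage_i, occ, f_i) {
    parts <- character()
    sp <- fit$spec
    if ("sex" %in% sp$p_terms) parts <- c(parts, sex_i)
    if ("year" %in% sp$p_terms) parts <- c(parts, paste0("t", occ))
    if ("stage" %in% sp$p_terms)
      parts <- c(parts, if (stage_i == "hatchling" && occ == f_i + 1L) "J" else "A")
    nm <- paste0("p:", if (length(parts)) paste(parts, collapse = ":") else "const")
    if (!nm %in% names(beta)) return(0.5)
    stats::plogis(beta[[nm]])
  }
  cell_phi <- function(sex_i, stage_i, t, f_i) {
    st <- if (stage_i == "hatchling" && t == f_i) "J" else "A"
    nm <- paste0("phi:", sex_i, ":", st)
    if (!nm %in% names(beta)) return(0.5)
    stats::plogis(beta[[nm]])
  }
  dev_obs <- -2 * fit$logL
  dev_sim <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      sim <- matrix(0L, nrow(det), T_)
      sim[cbind(seq_len(nrow(det)), f)] <- 1L
      for (i in seq_len(nrow(det))) {
        if (f[i] >= T_) next  # released on the final occasion
        alive <- TRUE
        for (t in f[i]:(T_ - 1L)) {
          alive <- alive && stats::runif(1) < cell_phi(sex[i], stg[i], t, f[i])
          if (!alive) break
          if (stats::runif(1) < cell_p(sex[i], stg[i], t + 1L, f[i]))
            sim[i, t + 1L] <- 1L
        }
      }
      simdf <- histories
      simdf[, .detection_cols(histories)] <- sim
      rf <- fit_cjs(simdf, fit$spec, n_starts = 1, start = beta)
      -2 * rf$logL
    }, numeric(1))
  })
  list(c_hat = dev_obs / mean(dev_sim), dev_obs = dev_obs, dev_sim = dev_sim)
}
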
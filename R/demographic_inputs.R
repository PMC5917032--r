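## Hatching sex ratio (with brood-level clustering) and the mating-system
## index, the two reproduction-side inputs of the two-sex model.

#' Estimate the hatching sex ratio with a brood random effect
#'
#' Fits an intercept-only binomial mixed model on the logit scale -- chick sex
#' against a brood random intercept -- so that the non-independence of
#' siblings is absorbed by the brood term. When the estimated brood variance
#' is numerically zero (<= 1e-8) the model degenerates to a plain binomial
#' GLM, which is then used and flagged. The returned interval is a Wald 95% CI
#' on the logit scale, back-transformed.
#'
#' @param hatch_records data.frame with columns `brood_id` and `sex`
#'   (`"M"`/`"F"`). Complete broods only: apply the completeness filter (e.g.
#'   [read_hatches] with `complete_only`) upstream.
#' @return A list of class `hatching_sex_ratio` with `rho_hat`, `ci`
#'   (length 2), `intercept_z` (Wald z for the logit intercept differing from
#'   0, i.e. from a 50:50 ratio), `n_broods`, `n_chicks`, `glm_fallback`,
#'   `boundary` (all chicks one sex; CI from the exact binomial on the
#'   admissible side).
#' @export
estimate_hatching_sex_ratio <- function(hatch_records) {
  df <- as.data.frame(hatch_records)
  if (!all(c("brood_id", "sex") %in% names(df)))
    stop("hatch records need columns brood_id and sex", call. = FALSE)
  if (!all(df$sex %in% c("M", "F")))
    stop("chick sex must be 'M' or 'F'", call. = FALSE)
  n_broods <- length(unique(df$brood_id))
  if (n_broods < 2)
    stop("need at least 2 broods to separate brood-level variance",
         call. = FALSE)
  y <- as.integer(df$sex == "M")
  n <- length(y)

  if (all(y == 1L) || all(y == 0L)) {
    ## boundary: intercept diverges; exact binomial CI on the admissible side
    bt <- stats::binom.test(sum(y), n)
    return(structure(list(rho_hat = mean(y), ci = as.numeric(bt$conf.int),
                          intercept_z = NA_real_, n_broods = n_broods,
                          n_chicks = n, glm_fallback = FALSE,
                          boundary = TRUE),
                     class = "hatching_sex_ratio"))
  }

  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(y ~ 1 + (1 | brood_id),
                data = data.frame(y = y, brood_id = df$brood_id),
                family = stats::binomial())))
  var_brood <- as.numeric(lme4::VarCorr(fit)$brood_id[1])
  glm_fallback <- !is.finite(var_brood) || var_brood <= 1e-8
  if (glm_fallback) {
    gfit <- stats::glm(y ~ 1, family = stats::binomial())
    est <- stats::coef(gfit)[[1]]
    se <- sqrt(stats::vcov(gfit)[1, 1])
  } else {
    est <- lme4::fixef(fit)[[1]]
    se <- sqrt(as.numeric(stats::vcov(fit)[1, 1]))
  }
  structure(list(rho_hat = stats::plogis(est),
                 ci = stats::plogis(est + c(-1, 1) * stats::qnorm(0.975) * se),
                 intercept_z = est / se, n_broods = n_broods, n_chicks = n,
                 glm_fallback = glm_fallback, boundary = FALSE),
            class = "hatching_sex_ratio")
}

#' @export
print.hatching_sex_ratio <- function(x, ...) {
  cat(sprintf("Hatching sex ratio: %.3f [%.3f, %.3f] (%d chicks, %d broods)\n",
              x$rho_hat, x$ci[1], x$ci[2], x$n_chicks, x$n_broods))
  if (!is.na(x$intercept_z))
    cat(sprintf("  logit-intercept z = %.2f%s%s\n", x$intercept_z,
                if (x$glm_fallback) "  [GLM fallback: brood variance ~ 0]" else "",
                if (x$boundary) "  [boundary]" else ""))
  invisible(x)
}

#' Annual mate rate of a female
#'
#' `mu = max(1, m / b)`: a female with at most one mate per breeding year is
#' functionally monogamous (`mu = 1`); within-season polyandry pushes the rate
#' above 1.
#'
#' @param m Total number of mating partners over the observed years (positive
#'   integer).
#' @param b Total number of years the female was seen breeding (positive
#'   integer).
#' @return The annual mate rate `mu >= 1`. Vectorised over `m` and `b`.
#' @export
female_mating_rate <- function(m, b) {
  if (any(!is.finite(m)) || any(!is.finite(b)) || any(m < 1) || any(b < 1) ||
      any(abs(m - round(m)) > 1e-8) || any(abs(b - round(b)) > 1e-8))
    stop("'m' and 'b' must be positive integers", call. = FALSE)
  pmax(1, m / b)
}

#' Population mating-system index
#'
#' `h = 1 / mean(mu_i)` over the females of a population: the implied mean
#' annual number of mates per male. Because each `mu_i >= 1`, the index lies
#' in `(0, 1]`, with `h = 1` only when every female is functionally
#' monogamous.
#'
#' @param records data.frame with columns `m` and `b` (see
#'   [female_mating_rate]); restrict upstream to females observed in at least
#'   two reproductive attempts (e.g. [read_matings]).
#' @return A list of class `mating_system_index` with `h`, `n_females`,
#'   `mean_mu`.
#' @export
mating_system_index <- function(records) {
  df <- as.data.frame(records)
  if (!all(c("m", "b") %in% names(df)))
    stop("mating records need columns m and b", call. = FALSE)
  if (!nrow(df)) stop("no mating records", call. = FALSE)
  mu <- female_mating_rate(df$m, df$b)
  h <- 1 / mean(mu)
  if (h > 1 + 1e-12)
    stop("computed h > 1: mating rates below 1 are not admissible",
         call. = FALSE)
  structure(list(h = min(h, 1), n_females = nrow(df), mean_mu = mean(mu)),
            class = "mating_system_index")
}

#' @export
print.mating_system_index <- function(x, ...) {
  cat(sprintf("Mating-system index h = %.3f (mean annual mate rate %.3f, %d females)\n",
              x$h, x$mean_mu, x$n_females))
  invisible(x)
}
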
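## Parental-care analysis: category proportions with simultaneous multinomial
## confidence intervals, and bootstrap regressions of cooperation (quadratic)
## and uniparental care (exponential) on the adult sex ratio.

.care_levels <- c("biparental", "male_only", "female_only")

## Exact simultaneous coverage of the box |Y_j - x_j| <= c under
## multinomial(N, x/N), computed via independent Poissons conditioned on the
## total (truncated-Poisson convolution). Returns P(all j: |Y_j - x_j| <= c).
.sim_coverage <- function(x, c) {
  N <- sum(x)
  conv <- 1
  offset <- 0L
  for (xj in x) {
    lo <- max(0L, xj - c)
    hi <- min(N, xj + c)
    pmf <- stats::dpois(lo:hi, xj)
    conv <- as.vector(stats::convolve(conv, rev(pmf), type = "open"))
    offset <- offset + lo
  }
  idx <- N - offset + 1L
  num <- if (idx >= 1L && idx <= length(conv)) conv[idx] else 0
  num / stats::dpois(N, N)
}

#' Parental-care proportions with simultaneous multinomial CIs
#'
#' Counts families in the three care categories and attaches simultaneous 95%
#' confidence intervals, truncated to `[0, 1]`. The default
#' `method = "bonferroni_exact"` uses Clopper-Pearson intervals at level
#' `1 - (1 - level)/3` per category, whose simultaneous coverage is guaranteed
#' to be at least `level` for every true composition and sample size.
#' `method = "sison_glaz"` gives the equal-half-width intervals `p_i +/- c/N`
#' with `c` the smallest integer whose exact simultaneous coverage under the
#' multinomial at the observed proportions reaches `level` (coverage computed
#' by truncated-Poisson convolution conditioned on the total, rather than the
#' original Edgeworth approximation); these are narrower but only
#' approximately calibrated at small `N`.
#'
#' @param care_records data.frame with columns `family_id` and `category`
#'   (one of `"biparental"`, `"male_only"`, `"female_only"`).
#' @param level Simultaneous confidence level.
#' @param method `"bonferroni_exact"` (default) or `"sison_glaz"`.
#' @return A list of class `care_proportions` with `counts`, `props`,
#'   `sim_ci` (3 x 2 matrix of truncated bounds), `half_width` (the integer
#'   `c`; `NA` for the exact method), `coverage` (exact conditional coverage
#'   for `"sison_glaz"`, the guaranteed lower bound for the default),
#'   `n_families`.
#' @export
care_proportions <- function(care_records, level = 0.95,
                             method = c("bonferroni_exact", "sison_glaz")) {
  method <- match.arg(method)
  df <- as.data.frame(care_records)
  if (!all(c("family_id", "category") %in% names(df)))
    stop("care records need columns family_id and category", call. = FALSE)
  if (!nrow(df)) stop("no care records", call. = FALSE)
  bad <- which(!df$category %in% .care_levels)
  if (length(bad))
    stop("unknown care category '", df$category[bad[1]], "' in row ", bad[1],
         call. = FALSE)
  counts <- stats::setNames(
    as.integer(table(factor(df$category, levels = .care_levels))),
    .care_levels)
  N <- sum(counts)
  props <- counts / N
  if (method == "sison_glaz") {
    cc <- 0L
    cov <- .sim_coverage(counts, cc)
    while (cov < level && cc < N) {
      cc <- cc + 1L
      cov <- .sim_coverage(counts, cc)
    }
    ci <- cbind(lower = pmax(0, props - cc / N),
                upper = pmin(1, props + cc / N))
  } else {
    adj <- 1 - (1 - level) / length(counts)
    cc <- NA_integer_
    cov <- level
    ci <- t(vapply(counts, function(x)
      as.numeric(stats::binom.test(x, N, conf.level = adj)$conf.int),
      numeric(2)))
    colnames(ci) <- c("lower", "upper")
  }
  rownames(ci) <- .care_levels
  structure(list(counts = counts, props = props, sim_ci = ci,
                 half_width = cc, coverage = cov, n_families = N,
                 level = level, method = method),
            class = "care_proportions")
}

#' @export
print.care_proportions <- function(x, ...) {
  cat("Parental care over", x$n_families, "families:\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-12s %3d  (%.3f  [%.3f, %.3f])\n", nm, x$counts[[nm]],
                x$props[[nm]], x$sim_ci[nm, 1], x$sim_ci[nm, 2]))
  if (identical(x$method, "sison_glaz"))
    cat(sprintf("  simultaneous %.0f%% CIs, half-width %d/%d (exact coverage %.3f)\n",
                100 * x$level, x$half_width, x$n_families, x$coverage))
  else
    cat(sprintf("  simultaneous %.0f%% CIs (Bonferroni-adjusted exact)\n",
                100 * x$level))
  invisible(x)
}

#' Quadratic regression of parental cooperation on ASR
#'
#' Ordinary least squares for `P = b0 + b1 A + b2 A^2`, the a priori model of
#' maximum cooperation at an unbiased ASR and breakdown at either extreme
#' (concave: `b2 < 0`).
#'
#' @param points data.frame (or matrix) with columns `A` (ASR) and `P`
#'   (proportion of cooperating families); at least 3 distinct `A` values.
#' @return Named coefficient vector `c(b0, b1, b2)`.
#' @export
fit_quadratic_care_model <- function(points) {
  pts <- as.data.frame(points)
  if (!all(c("A", "P") %in% names(pts)))
    stop("points need columns A and P", call. = FALSE)
  if (length(unique(pts$A)) < 3)
    stop("need at least 3 distinct ASR values for a quadratic fit",
         call. = FALSE)
  fit <- stats::lm(P ~ A + I(A^2), data = pts)
  stats::setNames(as.numeric(stats::coef(fit)), c("b0", "b1", "b2"))
}

#' Exponential regression of uniparental care on ASR
#'
#' Nonlinear least squares for `P = b0 + exp(b1 A)`: an increasing rate
#' (`b1 > 0`) captures uniparental care rising with the abundance of that sex,
#' a negative rate a decline. Fitted by profiling: for fixed `b1` the
#' intercept is linear, so the residual sum of squares is minimised over `b1`
#' on a coarse grid followed by local refinement. `form = "power"` reports the
#' rate on the base scale `b1' = exp(b1)` so the model reads `P = b0 + b1'^A`
#' (only evaluable for a positive base, which is why the exponential-rate
#' parameterisation is the default).
#'
#' @param points data.frame with columns `A` and `P` (at least 3 points, 2
#'   distinct `A`).
#' @param form `"offset_exp"` (default) or `"power"`.
#' @param b1_range Search range for the rate coefficient.
#' @return Named coefficient vector `c(b0, b1)`.
#' @export
fit_exponential_care_model <- function(points, form = c("offset_exp", "power"),
                                       b1_range = c(-15, 15)) {
  form <- match.arg(form)
  pts <- as.data.frame(points)
  if (!all(c("A", "P") %in% names(pts)))
    stop("points need columns A and P", call. = FALSE)
  if (length(unique(pts$A)) < 2 || nrow(pts) < 3)
    stop("need at least 3 points with 2 distinct ASR values", call. = FALSE)
  rss <- function(b1) {
    e <- exp(b1 * pts$A)
    b0 <- mean(pts$P - e)
    sum((pts$P - b0 - e)^2)
  }
  grid <- seq(b1_range[1], b1_range[2], length.out = 61)
  vals <- vapply(grid, rss, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(rss, c(lo, hi))
  b1 <- opt$minimum
  b0 <- mean(pts$P - exp(b1 * pts$A))
  if (form == "power") b1 <- exp(b1)
  stats::setNames(c(b0, b1), c("b0", "b1"))
}

#' Bootstrap regression of care on ASR across populations
#'
#' Propagates the uncertainty of both axes into the regression: each iteration
#' draws one ASR value per population (from its stored bootstrap replicates
#' when supplied, otherwise uniformly within its 95% CI) and one care
#' proportion per population (uniformly within its truncated simultaneous CI),
#' then fits the chosen model. The ensemble of coefficient vectors summarises
#' the relationship; its mean is the central tendency.
#'
#' @param asr_uncertainty List (one element per population) of either
#'   [bootstrap_asr] results, lists with a `replicates` vector, or lists with
#'   a `ci = c(low, high)` interval.
#' @param care_uncertainty List (one per population) of [care_proportions]
#'   objects, or lists with `ci = c(low, high)` for the modelled category.
#' @param model `"quadratic"` (biparental cooperation), `"exponential_male"`
#'   (male-only care) or `"exponential_female"` (female-only care).
#' @param B Number of bootstrap iterations.
#' @param seed Integer seed.
#' @return A list of class `care_regression_ensemble` with `coefficients`
#'   (`B` x 2 or 3 matrix), `central_tendency`, `model`, `B`, `seed`,
#'   `n_failed`.
#' @export
bootstrap_care_regression <- function(asr_uncertainty, care_uncertainty,
                                      model = c("quadratic",
                                                "exponential_male",
                                                "exponential_female"),
                                      B = 1000, seed = 1L) {
  model <- match.arg(model)
  npop <- length(asr_uncertainty)
  if (npop < 3) stop("need at least 3 populations", call. = FALSE)
  if (length(care_uncertainty) != npop)
    stop("asr_uncertainty and care_uncertainty must align by population",
         call. = FALSE)
  category <- switch(model, quadratic = "biparental",
                     exponential_male = "male_only",
                     exponential_female = "female_only")
  draw_asr <- function(u) {
    if (!is.null(u$replicates)) sample(u$replicates, 1L)
    else if (!is.null(u$ci)) stats::runif(1, u$ci[1], u$ci[2])
    else if (!is.null(u$ci_low)) stats::runif(1, u$ci_low, u$ci_high)
    else stop("ASR uncertainty needs replicates or a ci", call. = FALSE)
  }
  draw_care <- function(u) {
    ci <- if (inherits(u, "care_proportions")) u$sim_ci[category, ]
          else u$ci
    stats::runif(1, ci[1], ci[2])
  }
  fit_one <- function(A, P) {
    pts <- data.frame(A = A, P = P)
    if (model == "quadratic") fit_quadratic_care_model(pts)
    else fit_exponential_care_model(pts)
  }
  ncoef <- if (model == "quadratic") 3L else 2L
  coefs <- matrix(NA_real_, B, ncoef)
  colnames(coefs) <- if (ncoef == 3L) c("b0", "b1", "b2") else c("b0", "b1")
  n_failed <- 0L
  max_failures <- max(1, ceiling(0.1 * B))
  with_seed(seed, {
    b <- 1L
    while (b <= B) {
      res <- tryCatch({
        A <- vapply(asr_uncertainty, draw_asr, numeric(1))
        P <- vapply(care_uncertainty, draw_care, numeric(1))
        fit_one(A, P)
      }, error = function(e) NULL)
      if (is.null(res) || any(!is.finite(res))) {
        n_failed <<- n_failed + 1L
        if (n_failed > max_failures)
          stop("more than 10% of regression iterations failed", call. = FALSE)
        next
      }
      coefs[b, ] <- res
      b <- b + 1L
    }
  })
  structure(list(coefficients = coefs,
                 central_tendency = colMeans(coefs), model = model,
                 category = category, B = B, seed = seed,
                 n_failed = n_failed),
            class = "care_regression_ensemble")
}

#' @export
print.care_regression_ensemble <- function(x, ...) {
  cat("Care-vs-ASR bootstrap regression (", x$model, ", category ",
      x$category, ")\n", sep = "")
  cat(sprintf("  B = %d iterations (%d redrawn)\n  mean coefficients: %s\n",
              x$B, x$n_failed,
              paste(sprintf("%s=%.4f", names(x$central_tendency),
                            x$central_tendency), collapse = "  ")))
  invisible(x)
}
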
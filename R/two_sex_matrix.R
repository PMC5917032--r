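#' Two-sex model parameter set
#'
#' Bundles the vital rates of the nonlinear two-sex projection model: sex- and
#' stage-specific annual apparent survival, the hatching sex ratio, the modal
#' clutch size and the mating-system index.
#'
#' @param phi_fj,phi_mj Annual apparent survival of female / male juveniles
#'   (the one-year transition from hatching to recruitment), in `[0, 1]`.
#' @param phi_fa,phi_ma Annual apparent survival of female / male adults,
#'   in `[0, 1]`.
#' @param rho Hatching sex ratio: the probability that a hatchling is male.
#' @param k Modal clutch size (positive integer; 2 or 3 in the plover
#'   populations that motivated this model).
#' @param h Mating-system index: the mean annual number of mates acquired per
#'   male. `h = 1` is monogamy, `h < 1` polyandry, `h > 1` polygyny. Must be
#'   positive.
#' @return An object of class `two_sex_params`: a named list with components
#'   `phi_fj`, `phi_mj`, `phi_fa`, `phi_ma`, `rho`, `k`, `h`.
#' @examples
#' p <- two_sex_params(phi_fj = 0.3, phi_mj = 0.5, phi_fa = 0.7,
#'                     phi_ma = 0.7, rho = 0.5, k = 3, h = 1)
#' stable_structure(p)$asr  # 0.625: male-biased via juvenile survival
#' @export
two_sex_params <- function(phi_fj, phi_mj, phi_fa, phi_ma, rho, k, h) {
  probs <- c(phi_fj = phi_fj, phi_mj = phi_mj, phi_fa = phi_fa,
             phi_ma = phi_ma, rho = rho)
  for (nm in names(probs)) {
    v <- probs[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("parameter '", nm, "' must be a single probability in [0, 1]",
           call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 1 ||
      abs(k - round(k)) > 1e-8)
    stop("parameter 'k' must be a positive integer clutch size", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("parameter 'h' must be a positive mating index", call. = FALSE)
  structure(list(phi_fj = phi_fj, phi_mj = phi_mj, phi_fa = phi_fa,
                 phi_ma = phi_ma, rho = rho, k = as.numeric(round(k)), h = h),
            class = "two_sex_params")
}

#' @export
print.two_sex_params <- function(x, ...) {
  cat("Two-sex model parameters\n")
  cat(sprintf("  survival: phi_fj=%.3f phi_mj=%.3f phi_fa=%.3f phi_ma=%.3f\n",
              x$phi_fj, x$phi_mj, x$phi_fa, x$phi_ma))
  cat(sprintf("  rho=%.3f  k=%d  h=%.3f\n", x$rho, as.integer(x$k), x$h))
  invisible(x)
}

#' Harmonic-mean per-capita reproduction
#'
#' Frequency-dependent birth function linking the sexes. Each breeding pair
#' produces `k` hatchlings; the harmonic mean allocates matings according to
#' the relative abundance of adult males and females, with the mating index
#' `h` discounting the effective female density (a polyandrous female,
#' `h < 1`, ties up more than one male per year).
#'
#' @param n_ma,n_fa Adult male and adult female abundances (nonnegative, not
#'   both zero).
#' @param k Modal clutch size.
#' @param h Mating index (> 0).
#' @return Named numeric vector `c(R_f, R_m)`: per-capita annual production of
#'   hatchlings credited to an adult female (`R_f`) and an adult male (`R_m`).
#'   Both are zero when either sex is absent.
#' @export
reproduction_rates <- function(n_ma, n_fa, k, h) {
  if (h <= 0) stop("mating index 'h' must be positive", call. = FALSE)
  if (n_ma < 0 || n_fa < 0) stop("adult abundances must be nonnegative",
                                 call. = FALSE)
  if (n_ma == 0 && n_fa == 0)
    stop("at least one sex must have nonzero adult abundance", call. = FALSE)
  if (n_ma == 0 || n_fa == 0) return(c(R_f = 0, R_m = 0))
  den <- n_ma + n_fa / h
  c(R_f = k * n_ma / den, R_m = k * n_fa / den)
}

#' Build the two-sex projection matrix at a given population state
#'
#' Assembles the 4x4 post-breeding projection matrix over the stage vector
#' `[female juvenile, female adult, male juvenile, male adult]`. Row 1 places
#' female hatchling production `R_f (1 - rho)`, `R_m (1 - rho)` on the adult
#' columns, row 3 the male hatchling production `R_f rho`, `R_m rho`; rows 2
#' and 4 carry the survival transitions. Because the reproduction rates depend
#' on the current adult abundances, the matrix is state-dependent and the
#' model is nonlinear.
#'
#' @param params A [two_sex_params] object.
#' @param n Population vector of length 4 (`n_fj`, `n_fa`, `n_mj`, `n_ma`),
#'   nonnegative.
#' @return A 4x4 numeric matrix.
#' @export
build_projection_matrix <- function(params, n) {
  stopifnot(inherits(params, "two_sex_params"))
  n <- as.numeric(n)
  if (length(n) != 4L || any(!is.finite(n)) || any(n < 0))
    stop("'n' must be 4 nonnegative abundances", call. = FALSE)
  R <- if (n[2] == 0 || n[4] == 0) c(R_f = 0, R_m = 0)
       else reproduction_rates(n[4], n[2], params$k, params$h)
  M <- matrix(0, 4, 4)
  M[1, 2] <- R[["R_f"]] * (1 - params$rho)
  M[1, 4] <- R[["R_m"]] * (1 - params$rho)
  M[3, 2] <- R[["R_f"]] * params$rho
  M[3, 4] <- R[["R_m"]] * params$rho
  M[2, 1] <- params$phi_fj
  M[2, 2] <- params$phi_fa
  M[4, 3] <- params$phi_mj
  M[4, 4] <- params$phi_ma
  dimnames(M) <- list(c("fJ", "fA", "mJ", "mA"), c("fJ", "fA", "mJ", "mA"))
  M
}

#' Project the nonlinear two-sex dynamics
#'
#' Iterates `n_t = M(n_{t-1}) n_{t-1}`, rebuilding the projection matrix each
#' step because the fecundity elements depend on the current adult sex
#' composition. The structure is renormalised to unit sum each step; the
#' dynamics are homogeneous of degree one, so this leaves the stage
#' composition unchanged while preventing overflow over long horizons.
#'
#' @param params A [two_sex_params] object.
#' @param n0 Starting population vector (length 4, nonnegative, not all zero).
#' @param steps Number of annual time steps (>= 1).
#' @return A list of class `projection_trajectory` with `vectors` (a
#'   `(steps+1) x 4` matrix of normalised stage structures, row `t+1` holding
#'   the structure after `t` steps), `growth` (the per-step multiplier at each
#'   step), and `extinct` (flag: the population hit all-zero and the
#'   trajectory was truncated).
#' @export
project <- function(params, n0, steps) {
  stopifnot(inherits(params, "two_sex_params"))
  n0 <- as.numeric(n0)
  if (length(n0) != 4L || any(n0 < 0) || sum(n0) == 0)
    stop("'n0' must be 4 nonnegative abundances, not all zero", call. = FALSE)
  if (steps < 1) stop("'steps' must be >= 1", call. = FALSE)
  out <- matrix(NA_real_, steps + 1L, 4L,
                dimnames = list(NULL, c("fJ", "fA", "mJ", "mA")))
  growth <- rep(NA_real_, steps)
  n <- n0 / sum(n0)
  out[1L, ] <- n
  extinct <- FALSE
  for (t in seq_len(steps)) {
    M <- build_projection_matrix(params, n)
    n_new <- drop(M %*% n)
    s <- sum(n_new)
    if (s <= 0 || !is.finite(s)) {
      extinct <- TRUE
      out <- out[seq_len(t), , drop = FALSE]
      growth <- growth[seq_len(t - 1L)]
      warning("population collapsed to zero at step ", t,
              "; returning partial trajectory", call. = FALSE)
      break
    }
    growth[t] <- s
    n <- n_new / s
    out[t + 1L, ] <- n
  }
  structure(list(vectors = out, growth = growth, extinct = extinct,
                 params = params),
            class = "projection_trajectory")
}

## Fast scalar iteration of the same dynamics (used where only the terminal
## structure is needed; equality with project() is asserted by tests).
.iterate_structure <- function(params, n0, steps) {
  pfj <- params$phi_fj; pmj <- params$phi_mj
  pfa <- params$phi_fa; pma <- params$phi_ma
  rho <- params$rho; k <- params$k; h <- params$h
  n <- n0 / sum(n0)
  delta <- NA_real_
  for (t in seq_len(steps)) {
    births <- if (n[2] > 0 && n[4] > 0) 2 * k * n[2] * n[4] / (n[4] + n[2] / h) else 0
    n_new <- c((1 - rho) * births,
               pfj * n[1] + pfa * n[2],
               rho * births,
               pmj * n[3] + pma * n[4])
    s <- sum(n_new)
    if (s <= 0) return(list(w = n, growth = 0, delta = Inf, extinct = TRUE))
    n_new <- n_new / s
    delta <- max(abs(n_new - n))
    n <- n_new
    last_growth <- s
  }
  list(w = n, growth = last_growth, delta = delta, extinct = FALSE)
}

#' Stable stage structure and adult sex ratio
#'
#' Runs the nonlinear projection to (numerical) equilibrium and reads off the
#' stable stage distribution `w`, the asymptotic per-step growth multiplier,
#' and the adult sex ratio `ASR = w_mA / (w_mA + w_fA)`.
#'
#' @param params A [two_sex_params] object.
#' @param steps Projection horizon (default 1000 annual steps).
#' @param n0 Starting structure; defaults to uniform `(1/4, 1/4, 1/4, 1/4)`.
#'   The asymptotic structure does not depend on the interior starting point.
#' @param tol Convergence tolerance on the max-norm change in structure over
#'   the final step; a warning carrying the residual is issued if it is not
#'   met.
#' @return A list of class `stable_structure` with `w` (length-4 normalised
#'   structure), `growth_rate`, `asr`, and `residual` (final-step max-norm
#'   change).
#' @export
stable_structure <- function(params, steps = 1000, n0 = rep(0.25, 4),
                             tol = 1e-9) {
  stopifnot(inherits(params, "two_sex_params"))
  n0 <- as.numeric(n0)
  if (length(n0) != 4L || any(n0 < 0) || sum(n0) == 0)
    stop("'n0' must be 4 nonnegative abundances, not all zero", call. = FALSE)
  res <- .iterate_structure(params, n0, steps)
  if (res$extinct)
    warning("population collapsed before reaching equilibrium", call. = FALSE)
  else if (res$delta > tol)
    warning(sprintf(
      "structure not converged to %.1e after %d steps (residual %.3e)",
      tol, steps, res$delta), call. = FALSE)
  w <- res$w
  names(w) <- c("fJ", "fA", "mJ", "mA")
  asr <- if (w[["fA"]] + w[["mA"]] > 0) w[["mA"]] / (w[["mA"]] + w[["fA"]])
         else NA_real_
  structure(list(w = w, growth_rate = res$growth, asr = asr,
                 residual = res$delta),
            class = "stable_structure")
}

#' @export
print.stable_structure <- function(x, ...) {
  cat("Stable stage structure (fJ, fA, mJ, mA):\n  ")
  cat(sprintf("%.4f", x$w), sep = "  ")
  cat(sprintf("\n  growth rate: %.4f   ASR: %.4f\n", x$growth_rate, x$asr))
  invisible(x)
}

#' Equilibrium ASR by root finding
#'
#' Independent check on the simulated stable structure. At equilibrium with
#' per-step multiplier `lambda` and adult sex ratio expressed through
#' `x = n_mA / n_fA`, the adult recruitment balance of each sex gives
#' `lambda (lambda - phi_fa) = 2 (1 - rho) phi_fj B(x)` and
#' `lambda (lambda - phi_ma) x = 2 rho phi_mj B(x)`, with the female-normalised
#' harmonic-mean birth rate `B(x) = k x / (x + 1/h)` (total hatchlings per
#' adult female is `2 B(x)`; the extra factor of `lambda` reflects the
#' one-step delay between hatching and recruitment). Given `x`, the female
#' equation fixes `lambda` in closed form; the male equation is then solved
#' for `x` by bracketing root finding, and `ASR = x / (1 + x)`.
#'
#' @param params A [two_sex_params] object.
#' @param interval Search interval for `x` (adult males per adult female).
#' @return The equilibrium adult sex ratio (scalar in `(0, 1)`).
#' @export
equilibrium_oracle <- function(params, interval = c(1e-9, 1e9)) {
  stopifnot(inherits(params, "two_sex_params"))
  pfj <- params$phi_fj; pmj <- params$phi_mj
  pfa <- params$phi_fa; pma <- params$phi_ma
  rho <- params$rho; k <- params$k; h <- params$h
  if (pfj == 0 || pmj == 0)
    stop("no interior equilibrium when a juvenile survival rate is zero",
         call. = FALSE)
  B <- function(x) k * x / (x + 1 / h)
  g <- function(logx) {
    x <- exp(logx)
    lam <- (pfa + sqrt(pfa^2 + 8 * (1 - rho) * pfj * B(x))) / 2
    lam * (lam - pma) * x - 2 * rho * pmj * B(x)
  }
  lo <- log(interval[1]); hi <- log(interval[2])
  if (g(lo) * g(hi) > 0)
    stop("no interior equilibrium in the search interval: ",
         "one sex outgrows the other (boundary ASR of 0 or 1)", call. = FALSE)
  x <- exp(stats::uniroot(g, c(lo, hi), tol = 1e-13)$root)
  x / (1 + x)
}
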
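test_that("log-likelihood matches hand-computed 2- and 3-occasion values", {
  sp <- cjs_model_spec()          # constant detection
  b <- c(0, 0)                    # phi = p = 0.5 on the logit scale

  h11 <- make_histories(c(1, 1))
  expect_equal(cjs_log_likelihood(b, h11, sp), log(0.25), tolerance = 1e-10)

  h10 <- make_histories(c(1, 0))
  expect_equal(cjs_log_likelihood(b, h10, sp), log(0.75), tolerance = 1e-10)

  h101 <- make_histories(matrix(c(1, 0, 1), 1))
  expect_equal(cjs_log_likelihood(b, h101, sp), log(0.0625),
               tolerance = 1e-10)

  expect_error(cjs_log_likelihood(c(0, 0, 0), h11, sp), "length")
})

test_that("likelihood equals the death-time enumeration oracle (<= 4 occ)", {
  set.seed(5)
  tr <- truth_parameters(0.35, 0.5, 0.65, 0.7, p_detect = 0.6, rho = 0.5,
                         k = 2, h = 0.9, n_years = 4, n0 = 120, seed = 5)
  hist <- simulate_population(tr)$encounter_histories
  for (sp in list(cjs_model_spec(), cjs_model_spec("sex"),
                  cjs_model_spec(c("sex", "year", "stage")))) {
    npar <- length(cjs_parameter_names(hist, sp))
    beta <- rnorm(npar, 0, 0.7)
    expect_equal(cjs_log_likelihood(beta, hist, sp),
                 brute_force_cjs_loglik(beta, hist, sp), tolerance = 1e-10)
  }
})

test_that("log-likelihood is never positive and is order-invariant", {
  tr <- truth_parameters(0.35, 0.5, 0.65, 0.7, p_detect = 0.6, rho = 0.5,
                         k = 2, h = 0.9, n_years = 5, n0 = 150, seed = 9)
  hist <- simulate_population(tr)$encounter_histories
  sp <- cjs_model_spec("sex")
  beta <- rnorm(length(cjs_parameter_names(hist, sp)), 0, 0.5)
  ll <- cjs_log_likelihood(beta, hist, sp)
  expect_lte(ll, 0)
  perm <- with_seed(2, hist[sample.int(nrow(hist)), ])
  expect_equal(cjs_log_likelihood(beta, perm, sp), ll, tolerance = 1e-12)
})

test_that("terminal survival and detection enter only through their product", {
  # with a single interval the likelihood is a function of phi * p alone
  hist <- make_histories(matrix(c(1, 1, 1, 0), 2, byrow = TRUE),
                         sex = c("F", "F"))
  sp <- cjs_model_spec("year")
  nm <- cjs_parameter_names(hist, sp)
  b1 <- setNames(c(qlogis(0.8), qlogis(0.5)), nm)
  b2 <- setNames(c(qlogis(0.5), qlogis(0.8)), nm)
  expect_equal(cjs_log_likelihood(b1, hist, sp),
               cjs_log_likelihood(b2, hist, sp), tolerance = 1e-12)
})

test_that("MLE matches a grid-search oracle on a constant-parameter dataset", {
  phi_t <- 0.7; p_t <- 0.6
  hist <- simulate_cjs_histories(200, 3, phi = list(phi_fj = phi_t,
                                                    phi_mj = phi_t,
                                                    phi_fa = phi_t,
                                                    phi_ma = phi_t),
                                 p = p_t, prop_hatchling = 0,
                                 first = 1, seed = 31)
  hist$sex <- "F"   # collapse to a single survival cell
  fit <- fit_cjs(hist, cjs_model_spec(), n_starts = 3, seed = 1)
  expect_true(fit$converged)

  # independent oracle: exhaustive likelihood over a (phi, p) lattice using
  # the closed-form 3-occasion history probabilities
  det <- as.matrix(hist[, c("y1", "y2", "y3")])
  pat <- paste0(det[, 2], det[, 3])
  cnt <- table(pat)
  grid <- seq(0.001, 0.999, by = 0.001)
  gp <- expand.grid(phi = grid, p = grid)
  ll <- with(gp, {
    p11 <- phi * p * phi * p
    p10 <- phi * p * (1 - phi * p)
    p01 <- phi * (1 - p) * phi * p
    p00 <- 1 - phi * p - phi * (1 - p) * phi * p
    n <- function(k) if (k %in% names(cnt)) cnt[[k]] else 0
    n("11") * log(p11) + n("10") * log(p10) + n("01") * log(p01) +
      n("00") * log(p00)
  })
  best <- gp[which.min(-ll), ]
  phi_hat <- fit$phi_hat["phi:F:A", "estimate"]
  p_hat <- unname(fit$p_hat["p:const"])
  expect_lt(abs(phi_hat - best$phi), 1e-3 + 1e-9)
  expect_lt(abs(p_hat - best$p), 1e-3 + 1e-9)
})

test_that("complete data drives estimates to the boundary with a flag", {
  det <- matrix(1, 40, 4)
  hist <- make_histories(det, sex = rep(c("F", "M"), 20))
  fit <- fit_cjs(hist, cjs_model_spec(), n_starts = 1)
  expect_true(fit$boundary)
  expect_true(all(fit$phi_hat$estimate[c(3, 4)] > 0.99))  # adult cells
  expect_true(all(fit$p_hat > 0.99))
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(aicc(-100, 4, 50), 208 + 40 / 45, tolerance = 1e-12)
  expect_equal(aicc(-100, 0, 50), 200)
  # large-sample limit: AICc -> AIC
  expect_equal(aicc(-100, 4, 1e9), 208, tolerance = 1e-5)
  expect_error(aicc(-100, 4, 5), "n_eff")
  tr <- truth_parameters(0.35, 0.5, 0.65, 0.7, p_detect = 0.6, rho = 0.5,
                         k = 2, h = 0.9, n_years = 4, n0 = 100, seed = 2)
  fit <- fit_cjs(simulate_population(tr)$encounter_histories,
                 cjs_model_spec(), n_starts = 1)
  expect_gte(fit$AICc, -2 * fit$logL + 2 * fit$K)  # AICc >= AIC
})

test_that("model selection picks minimum AICc with documented tie-breaks", {
  mk <- function(aicc, K, label, converged = TRUE)
    structure(list(AICc = aicc, K = K, spec = list(label = label),
                   converged = converged), class = "cjs_fit")
  expect_equal(select_best_model(list(mk(102, 5, "b"), mk(100, 7, "a")))$AICc,
               100)
  # AICc tie: smaller K wins
  expect_equal(select_best_model(list(mk(100, 7, "a"), mk(100, 5, "b")))$K, 5)
  # full tie: lexicographic label
  expect_equal(select_best_model(
    list(mk(100, 5, "b"), mk(100, 5, "a")))$spec$label, "a")
  # non-converged fits are never selected
  expect_equal(select_best_model(
    list(mk(90, 5, "a", converged = FALSE), mk(100, 5, "b")))$AICc, 100)
  expect_error(select_best_model(list(mk(90, 5, "a", FALSE))), "converged")
})

test_that("the generating detection model wins on average", {
  # detection strongly year-dependent; phi constant across sexes/stages
  p_year <- function(sex, stage, occ) c(0.3, 0.85, 0.3, 0.85)[occ - 1]
  wins <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    hist <- simulate_cjs_histories(
      300, 5, phi = list(phi_fj = 0.45, phi_mj = 0.45,
                         phi_fa = 0.7, phi_ma = 0.7),
      p = function(sex, stage, occ) p_year(sex, stage, occ + 1 - 1),
      prop_hatchling = 0.5, seed = 100 + r)
    fits <- lapply(cjs_model_set(), function(sp)
      tryCatch(fit_cjs(hist, sp, n_starts = 1), error = function(e) NULL))
    best <- select_best_model(Filter(Negate(is.null), fits))
    if (identical(best$spec$p_terms, "year")) wins <- wins + 1L
  }
  expect_gt(wins / n_rep, 0.5)
})

test_that("survival estimates recover simulation truth within Wald error", {
  truth <- list(phi_fj = 0.3, phi_mj = 0.5, phi_fa = 0.7, phi_ma = 0.7)
  hist <- simulate_cjs_histories(800, 5, phi = truth, p = 0.6, seed = 42)
  fit <- fit_cjs(hist, cjs_model_spec(), n_starts = 3, seed = 1)
  expect_true(fit$converged)
  for (i in seq_len(4)) {
    cell <- paste0("phi_", tolower(fit$phi_hat$sex[i]),
                   tolower(fit$phi_hat$stage[i]))
    z <- abs(fit$phi_hat$estimate[i] - truth[[cell]]) / fit$phi_hat$se[i]
    expect_lt(z, 3)
  }
})

test_that("resampling is stratified, deterministic, and unbiased", {
  tr <- truth_parameters(0.35, 0.5, 0.65, 0.7, p_detect = 0.7, rho = 0.5,
                         k = 2, h = 0.9, n_years = 4, n0 = 200, seed = 3)
  hist <- simulate_population(tr)$encounter_histories
  r1 <- resample_histories(hist, seed = 11)
  r2 <- resample_histories(hist, seed = 11)
  expect_identical(r1, r2)
  expect_equal(table(r1$stage_at_marking), table(hist$stage_at_marking))

  one <- hist[1, , drop = FALSE]
  expect_equal(nrow(resample_histories(one, seed = 1)), 1)
  expect_equal(resample_histories(one, seed = 1)$id, one$id)

  # expected inclusion count of each history is 1
  hist100 <- hist[seq_len(100), ]
  R <- 3000L
  counts <- numeric(100)
  for (r in seq_len(R)) {
    rs <- resample_histories(hist100, seed = 5000 + r)
    tab <- table(factor(rs$id, levels = hist100$id))
    counts <- counts + as.numeric(tab)
  }
  mean_incl <- counts / R
  expect_true(all(abs(mean_incl - 1) < 3 / sqrt(R) * 3 + 0.15))
  expect_lt(abs(mean(mean_incl) - 1), 3 / sqrt(100 * R) * 2 + 0.01)
})

test_that("dispersion diagnostic calibrates near 1 and detects mixtures", {
  phi0 <- list(phi_fj = 0.4, phi_mj = 0.4, phi_fa = 0.65, phi_ma = 0.65)
  hist <- simulate_cjs_histories(400, 5, phi = phi0, p = 0.6, seed = 17)
  fit <- fit_cjs(hist, cjs_model_spec(), n_starts = 1)
  dc <- dispersion_check(fit, hist, n_boot = 40, seed = 8)
  expect_equal(dc$c_hat, 1, tolerance = 0.1)
  dc2 <- dispersion_check(fit, hist, n_boot = 40, seed = 8)
  expect_identical(dc$c_hat, dc2$c_hat)
  expect_warning(dispersion_check(fit, hist, n_boot = 5, seed = 1),
                 "n_boot")

  # two hidden survival regimes inflate the deviance ratio
  hi <- simulate_cjs_histories(300, 5,
                               phi = list(phi_fj = 0.9, phi_mj = 0.9,
                                          phi_fa = 0.9, phi_ma = 0.9),
                               p = 0.6, seed = 21)
  lo <- simulate_cjs_histories(300, 5,
                               phi = list(phi_fj = 0.1, phi_mj = 0.1,
                                          phi_fa = 0.1, phi_ma = 0.1),
                               p = 0.6, seed = 22)
  lo$id <- paste0("lo_", lo$id)
  mix <- as_encounter_histories(rbind(hi, lo))
  fit_mix <- fit_cjs(mix, cjs_model_spec(), n_starts = 1)
  dc_mix <- dispersion_check(fit_mix, mix, n_boot = 40, seed = 9)
  expect_gt(dc_mix$c_hat, 1)
})
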
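test_that("care proportions and intervals are well-formed", {
  cp <- care_proportions(records_from_counts(50, 25, 25))
  expect_equal(unname(cp$props), c(0.50, 0.25, 0.25))
  expect_equal(cp$n_families, 100)
  expect_true(all(cp$sim_ci[, "lower"] <= cp$props))
  expect_true(all(cp$sim_ci[, "upper"] >= cp$props))
  expect_true(all(cp$sim_ci >= 0 & cp$sim_ci <= 1))

  # boundary: every family biparental
  cp1 <- care_proportions(records_from_counts(30, 0, 0))
  expect_equal(cp1$props[["biparental"]], 1)
  expect_equal(cp1$sim_ci["biparental", "upper"], 1)

  # the equal-half-width variant also brackets the point proportions
  sg <- care_proportions(records_from_counts(50, 25, 25),
                         method = "sison_glaz")
  expect_true(all(sg$sim_ci[, "lower"] <= sg$props))
  expect_true(all(sg$sim_ci[, "upper"] >= sg$props))
  expect_true(all(sg$sim_ci >= 0 & sg$sim_ci <= 1))
  expect_gte(sg$coverage, 0.95)

  bad <- data.frame(family_id = 1:2, category = c("biparental", "shared"))
  expect_error(care_proportions(bad), "shared")
  expect_error(care_proportions(bad), "row 2")
})

test_that("simultaneous coverage is at least nominal by enumeration (n = 10)", {
  obs <- c(5L, 3L, 2L)
  p_true <- obs / sum(obs)   # the MLE of the observed table
  n <- 10L
  covered_prob <- 0
  for (a in 0:n) for (b in 0:(n - a)) {
    y <- c(a, b, n - a - b)
    prob <- dmultinom(y, prob = p_true)
    if (sum(y > 0) == 0) next
    cp <- care_proportions(records_from_counts(y[1], y[2], y[3]))
    inside <- all(p_true >= cp$sim_ci[, "lower"] - 1e-12 &
                  p_true <= cp$sim_ci[, "upper"] + 1e-12)
    if (inside) covered_prob <- covered_prob + prob
  }
  expect_gte(covered_prob, 0.95)
})

test_that("exact conditional coverage computation matches direct enumeration", {
  x <- c(5L, 3L, 2L)
  n <- sum(x)
  for (cc in 0:4) {
    direct <- 0
    for (a in 0:n) for (b in 0:(n - a)) {
      y <- c(a, b, n - a - b)
      if (all(abs(y - x) <= cc))
        direct <- direct + dmultinom(y, prob = x / n)
    }
    expect_equal(asrdemog:::.sim_coverage(x, cc), direct, tolerance = 1e-10)
  }
})

test_that("quadratic care fit equals exact and normal-equation solutions", {
  # exact interpolation of a parabola peaking at A = 0.5
  A <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  P <- -1 + 6 * A - 6 * A^2
  co <- fit_quadratic_care_model(data.frame(A = A, P = P))
  expect_equal(unname(co), c(-1, 6, -6), tolerance = 1e-10)

  # noisy points: match the normal equations solved independently
  set.seed(8)
  A <- runif(6, 0.2, 0.8)
  P <- 0.3 + 0.9 * A - 1.1 * A^2 + rnorm(6, 0, 0.05)
  co <- fit_quadratic_care_model(data.frame(A = A, P = P))
  X <- cbind(1, A, A^2)
  oracle <- solve(t(X) %*% X, t(X) %*% P)
  expect_equal(unname(co), as.numeric(oracle), tolerance = 1e-8)

  # mirror-symmetric data force the vertex to 0.5
  A <- c(0.2, 0.4, 0.5, 0.6, 0.8)
  P <- c(0.3, 0.6, 0.7, 0.6, 0.3)
  co <- fit_quadratic_care_model(data.frame(A = A, P = P))
  expect_equal(-co[["b1"]] / (2 * co[["b2"]]), 0.5, tolerance = 1e-8)

  expect_error(fit_quadratic_care_model(
    data.frame(A = c(1, 1, 2), P = c(0, 0, 1))), "distinct")
})

test_that("exponential care fit recovers exact curves in both forms", {
  A <- seq(0.2, 0.8, length.out = 7)
  P <- 0.1 + exp(1.2 * A)
  co <- fit_exponential_care_model(data.frame(A = A, P = P))
  expect_equal(co[["b1"]], 1.2, tolerance = 1e-4)
  expect_equal(co[["b0"]], 0.1, tolerance = 1e-4)
  cow <- fit_exponential_care_model(data.frame(A = A, P = P), form = "power")
  expect_equal(cow[["b1"]], exp(1.2), tolerance = 1e-3)

  # declining care: negative rate coefficient
  P2 <- 0.4 + exp(-0.9 * A)
  co2 <- fit_exponential_care_model(data.frame(A = A, P = P2))
  expect_equal(co2[["b1"]], -0.9, tolerance = 1e-4)
})

test_that("mirrored care data yield opposite-signed rate coefficients", {
  set.seed(15)
  A <- runif(8, 0.25, 0.75)
  P_male <- 0.05 + exp(1.5 * A) / 10 + rnorm(8, 0, 0.01)
  male <- fit_exponential_care_model(data.frame(A = A, P = P_male))
  fem <- fit_exponential_care_model(data.frame(A = 1 - A, P = P_male))
  expect_gt(male[["b1"]], 0)
  expect_lt(fem[["b1"]], 0)
})

test_that("care regression bootstrap is deterministic and degenerates cleanly", {
  asr_u <- list(list(ci = c(0.4, 0.4)), list(ci = c(0.5, 0.5)),
                list(ci = c(0.6, 0.6)), list(ci = c(0.7, 0.7)))
  care_u <- list(list(ci = c(0.5, 0.5)), list(ci = c(0.8, 0.8)),
                 list(ci = c(0.7, 0.7)), list(ci = c(0.3, 0.3)))
  e1 <- bootstrap_care_regression(asr_u, care_u, "quadratic", B = 10,
                                  seed = 3)
  # zero-width uncertainty: every iteration identical
  expect_true(all(apply(e1$coefficients, 2, function(x) diff(range(x))) == 0))
  e2 <- bootstrap_care_regression(asr_u, care_u, "quadratic", B = 10,
                                  seed = 3)
  expect_identical(e1$coefficients, e2$coefficients)
  expect_error(bootstrap_care_regression(asr_u[1:2], care_u[1:2],
                                         "quadratic", B = 2, seed = 1),
               "3 populations")
})

test_that("the ensemble recovers concave cooperation against ASR", {
  # six populations whose cooperation peaks at an unbiased ASR
  A0 <- c(0.30, 0.40, 0.48, 0.55, 0.62, 0.72)
  P0 <- 0.8 - 1.5 * (A0 - 0.5)^2
  neg <- 0L
  n_runs <- 10L
  for (r in seq_len(n_runs)) {
    asr_u <- lapply(A0, function(a) list(ci = c(a - 0.05, a + 0.05)))
    care_u <- lapply(P0, function(p) list(ci = c(max(0, p - 0.05),
                                                 min(1, p + 0.05))))
    ens <- bootstrap_care_regression(asr_u, care_u, "quadratic", B = 40,
                                     seed = 700 + r)
    if (ens$central_tendency[["b2"]] < 0) neg <- neg + 1L
  }
  expect_equal(neg, n_runs)
})

test_that("quadratic ensembles are sex-relabelling equivariant", {
  A0 <- c(0.30, 0.42, 0.55, 0.68)
  P0 <- c(0.5, 0.75, 0.7, 0.4)
  asr_u <- lapply(A0, function(a) list(ci = c(a, a)))
  asr_m <- lapply(1 - A0, function(a) list(ci = c(a, a)))
  care_u <- lapply(P0, function(p) list(ci = c(p, p)))
  e <- bootstrap_care_regression(asr_u, care_u, "quadratic", B = 2, seed = 1)
  em <- bootstrap_care_regression(asr_m, care_u, "quadratic", B = 2, seed = 1)
  b <- e$central_tendency; bm <- em$central_tendency
  # P(A) and Pm(1-A) describe the same curve
  expect_equal(bm[["b0"]] + bm[["b1"]] + bm[["b2"]], b[["b0"]],
               tolerance = 1e-8)
  expect_equal(-bm[["b1"]] - 2 * bm[["b2"]], b[["b1"]], tolerance = 1e-8)
  expect_equal(bm[["b2"]], b[["b2"]], tolerance = 1e-8)
})
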
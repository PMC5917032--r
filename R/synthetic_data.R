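## Synthetic study generator: simulates the four field tables (encounter
## histories, hatch records, mating records, care records) from known vital
## rates so the whole pipeline can be validated by parameter recovery.

#' Ground-truth parameters for a synthetic study
#'
#' @param phi_fj,phi_mj,phi_fa,phi_ma Annual apparent survival (female/male x
#'   juvenile/adult), probabilities. Apparent survival is a single
#'   per-interval Bernoulli: mortality and permanent emigration are not
#'   distinguished.
#' @param p_detect Per-occasion detection probability for live, present,
#'   marked individuals (scalar).
#' @param rho Hatching sex ratio (proportion male).
#' @param brood_sd Standard deviation of the brood-level random intercept on
#'   the logit of `rho`; 0 gives i.i.d. Bernoulli chick sexes.
#' @param k Modal clutch size (positive integer; complete broods have exactly
#'   `k` chicks).
#' @param h Mating-system index in `(0, 1]`: the generator calibrates female
#'   mating records so the population-level index converges to `h`.
#' @param care_probs Probabilities of the three family care categories, in the
#'   order biparental, male-only, female-only; must sum to 1.
#' @param n_years Number of annual occasions (>= 3).
#' @param n0 Founding adult cohort size (>= 1); also sets the annual number of
#'   broods, `round(n0 / (2 k))`.
#' @param seed Integer RNG seed.
#' @param population Population label written into the tables.
#' @return An object of class `truth_parameters`.
#' @export
truth_parameters <- function(phi_fj, phi_mj, phi_fa, phi_ma, p_detect, rho,
                             brood_sd = 0, k, h,
                             care_probs = c(biparental = 0.6, male_only = 0.2,
                                            female_only = 0.2),
                             n_years, n0, seed = 1L, population = "pop1") {
  chk_prob <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("field '", nm, "' must be a probability in [0, 1]", call. = FALSE)
  }
  for (nm in c("phi_fj", "phi_mj", "phi_fa", "phi_ma", "p_detect", "rho"))
    chk_prob(get(nm), nm)
  if (!is.finite(brood_sd) || brood_sd < 0)
    stop("field 'brood_sd' must be a nonnegative number", call. = FALSE)
  if (!is.finite(k) || k < 1 || abs(k - round(k)) > 1e-8)
    stop("field 'k' must be a positive integer", call. = FALSE)
  if (!is.finite(h) || h <= 0 || h > 1)
    stop("field 'h' must lie in (0, 1]: female mating rates are >= 1 by ",
         "construction, so the index cannot exceed 1", call. = FALSE)
  care_probs <- as.numeric(care_probs)
  if (length(care_probs) != 3L || any(!is.finite(care_probs)) ||
      any(care_probs < 0) || abs(sum(care_probs) - 1) > 1e-12)
    stop("field 'care_probs' must be 3 nonnegative probabilities summing to 1",
         call. = FALSE)
  if (!is.finite(n_years) || n_years < 3)
    stop("field 'n_years' must be >= 3", call. = FALSE)
  if (!is.finite(n0) || n0 < 1)
    stop("field 'n0' must be >= 1", call. = FALSE)
  structure(list(phi_fj = phi_fj, phi_mj = phi_mj, phi_fa = phi_fa,
                 phi_ma = phi_ma, p_detect = p_detect, rho = rho,
                 brood_sd = brood_sd, k = as.integer(round(k)), h = h,
                 care_probs = stats::setNames(
                   care_probs, c("biparental", "male_only", "female_only")),
                 n_years = as.integer(n_years), n0 = as.integer(n0),
                 seed = as.integer(seed), population = population),
            class = "truth_parameters")
}

#' Simulate a complete synthetic study
#'
#' Simulates a marked population forward in annual steps. A founding adult
#' cohort (half of each sex) enters at occasion 1; each year a fixed number of
#' complete broods of `k` chicks hatch, with chick sex drawn at probability
#' `rho` perturbed by a Normal(0, `brood_sd`) brood intercept on the logit
#' scale. Chicks survive their first interval with the sex-specific juvenile
#' rate and annually thereafter with the adult rate; every live individual is
#' detected with probability `p_detect` at each occasion from entry onward.
#' Histories with zero detections are discarded (the CJS likelihood conditions
#' on first capture); the number censored is recorded. Individuals whose first
#' detection falls in their hatch year are marked as hatchlings, all others as
#' adults. Female mating records are drawn from a two-point annual-mate-rate
#' distribution calibrated so the population mating index converges to `h`,
#' and one care category per brood is drawn i.i.d. from `care_probs`.
#'
#' @param truth A [truth_parameters] object.
#' @return An object of class `synthetic_dataset`: a list with data.frames
#'   `encounter_histories`, `hatch_records`, `mating_records`, `care_records`,
#'   plus `truth`, `n_censored` (zero-detection histories dropped) and
#'   `latent` (realised survival tallies by sex and stage, for diagnostics).
#' @export
simulate_population <- function(truth) {
  stopifnot(inherits(truth, "truth_parameters"))
  with_seed(truth$seed, .simulate_population_impl(truth))
}

.simulate_population_impl <- function(truth) {
  T_ <- truth$n_years
  k <- truth$k
  n_broods_yr <- max(1L, as.integer(round(truth$n0 / (2 * k))))
  hatch_years <- seq_len(T_ - 1L)

  ## --- individuals: founding adults + all chicks ---
  n_ad <- truth$n0
  ad_sex <- rep_len(c("F", "M"), n_ad)[sample.int(n_ad)]

  brood_id <- sprintf("B%03d_%05d", rep(hatch_years, each = n_broods_yr),
                      seq_len(n_broods_yr * length(hatch_years)))
  n_broods <- length(brood_id)
  brood_year <- rep(hatch_years, each = n_broods_yr)
  brood_eff <- stats::rnorm(n_broods, 0, truth$brood_sd)
  p_male <- stats::plogis(stats::qlogis(truth$rho) + brood_eff)
  chick_sex_mat <- matrix(stats::runif(n_broods * k) <
                            rep(p_male, each = k), k, n_broods)
  n_ch <- n_broods * k
  ch_sex <- ifelse(as.vector(chick_sex_mat), "M", "F")
  ch_brood <- rep(brood_id, each = k)
  ch_year <- rep(brood_year, each = k)
  ch_id <- paste0(ch_brood, "_c", rep(seq_len(k), times = n_broods))

  sex <- c(ad_sex, ch_sex)
  entry <- c(rep(1L, n_ad), ch_year)
  is_chick <- c(rep(FALSE, n_ad), rep(TRUE, n_ch))
  n <- n_ad + n_ch
  id <- c(sprintf("A%05d", seq_len(n_ad)), ch_id)

  ## --- survival forward ---
  alive <- matrix(FALSE, n, T_)
  alive[cbind(seq_len(n), entry)] <- TRUE
  surv_tally <- list(FJ = c(0, 0), MJ = c(0, 0), FA = c(0, 0), MA = c(0, 0))
  for (t in seq_len(T_ - 1L)) {
    cur <- alive[, t]
    if (!any(cur)) next
    juv <- is_chick & entry == t
    pr <- ifelse(juv,
                 ifelse(sex == "F", truth$phi_fj, truth$phi_mj),
                 ifelse(sex == "F", truth$phi_fa, truth$phi_ma))
    surv <- cur & (stats::runif(n) < pr)
    alive[, t + 1L] <- surv | (entry == t + 1L)  # next cohort enters
    for (s in c("F", "M")) for (st in c("J", "A")) {
      sel <- cur & sex == s & (if (st == "J") juv else !juv)
      key <- paste0(s, st)
      surv_tally[[key]] <- surv_tally[[key]] + c(sum(surv[sel]), sum(sel))
    }
  }

  ## --- detection ---
  det <- alive & matrix(stats::runif(n * T_) < truth$p_detect, n, T_)
  seen <- rowSums(det) > 0
  n_censored <- sum(!seen)
  first <- rep(NA_integer_, n)
  first[seen] <- apply(det[seen, , drop = FALSE], 1L, which.max)
  stage_mark <- ifelse(is_chick & first == entry, "hatchling", "adult")

  enc <- data.frame(id = id[seen], population = truth$population,
                    sex = sex[seen], stage_at_marking = stage_mark[seen])
  detdf <- as.data.frame(det[seen, , drop = FALSE] * 1L)
  names(detdf) <- paste0("y", seq_len(T_))
  enc <- cbind(enc, detdf)
  rownames(enc) <- NULL

  hatch <- data.frame(brood_id = ch_brood, chick_id = ch_id, sex = ch_sex)

  ## --- mating records: two-point annual mate rate with mean 1/h ---
  n_fem <- max(30L, as.integer(round(truth$n0 / 2)))
  mu2 <- max(2L, as.integer(ceiling(1 / truth$h)))
  q <- (1 / truth$h - 1) / (mu2 - 1)
  poly <- stats::runif(n_fem) < q
  b <- rep(2L, n_fem)
  m <- ifelse(poly, b * mu2, b)
  matings <- data.frame(female_id = sprintf("F%05d", seq_len(n_fem)),
                        m = as.integer(m), b = b)

  care <- data.frame(family_id = brood_id,
                     category = sample(names(truth$care_probs), n_broods,
                                       replace = TRUE,
                                       prob = truth$care_probs))

  latent <- data.frame(
    sex = c("F", "M", "F", "M"), stage = c("J", "J", "A", "A"),
    survived = c(surv_tally$FJ[1], surv_tally$MJ[1],
                 surv_tally$FA[1], surv_tally$MA[1]),
    trials = c(surv_tally$FJ[2], surv_tally$MJ[2],
               surv_tally$FA[2], surv_tally$MA[2]))
  latent$realized <- ifelse(latent$trials > 0,
                            latent$survived / latent$trials, NA_real_)

  structure(list(encounter_histories = as_encounter_histories(enc),
                 hatch_records = hatch, mating_records = matings,
                 care_records = care, truth = truth,
                 n_censored = n_censored, latent = latent),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic study:", nrow(x$encounter_histories), "encounter histories,",
      nrow(x$hatch_records), "chicks in",
      length(unique(x$hatch_records$brood_id)), "broods,",
      nrow(x$mating_records), "mating records,",
      nrow(x$care_records), "care records\n")
  cat("  zero-detection histories censored:", x$n_censored, "\n")
  invisible(x)
}

#' Write a synthetic dataset to CSV files
#'
#' Writes `encounters.csv`, `hatches.csv`, `matings.csv` and `care.csv` into
#' `directory`; the files round-trip losslessly through [read_dataset].
#'
#' @param ds A `synthetic_dataset` (or any list with the four tables).
#' @param directory Output directory (created if absent).
#' @return Invisibly, the four file paths.
#' @export
write_dataset <- function(ds, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  paths <- file.path(directory,
                     c("encounters.csv", "hatches.csv", "matings.csv",
                       "care.csv"))
  utils::write.csv(ds$encounter_histories, paths[1], row.names = FALSE)
  utils::write.csv(ds$hatch_records, paths[2], row.names = FALSE)
  utils::write.csv(ds$mating_records, paths[3], row.names = FALSE)
  utils::write.csv(ds$care_records, paths[4], row.names = FALSE)
  invisible(paths)
}

#' Read a dataset written by [write_dataset]
#'
#' @param directory Directory holding the four CSV files.
#' @return A list with `encounter_histories`, `hatch_records`,
#'   `mating_records`, `care_records`.
#' @export
read_dataset <- function(directory) {
  list(encounter_histories = read_encounters(file.path(directory,
                                                       "encounters.csv")),
       hatch_records = read_hatches(file.path(directory, "hatches.csv")),
       mating_records = read_matings(file.path(directory, "matings.csv"),
                                     min_attempts = 1),
       care_records = read_care(file.path(directory, "care.csv")))
}

#' Read encounter histories from CSV
#'
#' @param path CSV with columns `id, population, sex, stage_at_marking,
#'   y1..yN`.
#' @return An `encounter_histories` table.
#' @export
read_encounters <- function(path) {
  as_encounter_histories(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read hatch records from CSV
#'
#' @param path CSV with columns `brood_id, chick_id, sex`.
#' @param complete_only If a positive integer `k`, keep only broods with
#'   exactly `k` chicks (the complete-brood filter applied before estimating
#'   the hatching sex ratio). `NULL` keeps everything.
#' @return A data.frame.
#' @export
read_hatches <- function(path, complete_only = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("brood_id", "chick_id", "sex") %in% names(df)))
    stop("hatches file must have brood_id, chick_id, sex", call. = FALSE)
  if (!is.null(complete_only)) {
    sizes <- table(df$brood_id)
    keep <- names(sizes)[sizes == complete_only]
    df <- df[df$brood_id %in% keep, , drop = FALSE]
  }
  df
}

#' Read female mating records from CSV
#'
#' @param path CSV with columns `female_id, m, b` (total mates, years seen
#'   breeding).
#' @param min_attempts Keep only females observed in at least this many
#'   breeding years (default 2, the usual inclusion rule for the mating
#'   index).
#' @return A data.frame.
#' @export
read_matings <- function(path, min_attempts = 2) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("female_id", "m", "b") %in% names(df)))
    stop("matings file must have female_id, m, b", call. = FALSE)
  df[df$b >= min_attempts, , drop = FALSE]
}

#' Read family care records from CSV
#'
#' @param path CSV with columns `family_id, category` where category is one of
#'   `biparental`, `male_only`, `female_only`.
#' @return A data.frame.
#' @export
read_care <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("family_id", "category") %in% names(df)))
    stop("care file must have family_id, category", call. = FALSE)
  df
}
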
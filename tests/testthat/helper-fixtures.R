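# Shared fixtures: plover-like parameter draws and a brute-force CJS
# likelihood that enumerates latent death times (independent oracle for <= 4
# occasions).

# Random admissible two-sex parameters in ranges typical of small shorebirds:
# juvenile survival well below adult survival, modest sex ratio bias,
# monogamous-to-polyandrous mating. These ranges always admit an interior
# two-sex equilibrium.
draw_params <- function() {
  two_sex_params(phi_fj = runif(1, 0.15, 0.55),
                 phi_mj = runif(1, 0.15, 0.55),
                 phi_fa = runif(1, 0.55, 0.80),
                 phi_ma = runif(1, 0.55, 0.80),
                 rho = runif(1, 0.35, 0.65),
                 k = sample(2:3, 1),
                 h = runif(1, 0.7, 1))
}

make_histories <- function(det, sex = "F", stage = "adult") {
  det <- matrix(det, nrow = length(sex) %||% 1)
  df <- data.frame(id = paste0("i", seq_len(nrow(det))),
                   population = "test",
                   sex = rep_len(sex, nrow(det)),
                   stage_at_marking = rep_len(stage, nrow(det)))
  detdf <- as.data.frame(det)
  names(detdf) <- paste0("y", seq_len(ncol(det)))
  as_encounter_histories(cbind(df, detdf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force CJS likelihood: enumerates, per individual, every latent
# "alive through occasion a" scenario (a >= last detection), multiplying
# interval survival, the death/survival tail, and detection terms. Stage
# rules re-derived here independently: a hatchling-marked bird is a juvenile
# on its first interval and first re-encounter occasion only.
brute_force_cjs_loglik <- function(beta, histories, spec) {
  det <- as.matrix(histories[, grep("^y[0-9]+$", names(histories))])
  T_ <- ncol(det)
  stopifnot(T_ <= 4)
  nm <- cjs_parameter_names(histories, spec)
  stopifnot(length(beta) == length(nm))
  beta <- setNames(beta, nm)
  phi_of <- function(sex, stg, t, f) {
    st <- if (stg == "hatchling" && t == f) "J" else "A"
    plogis(beta[[paste0("phi:", sex, ":", st)]])
  }
  p_of <- function(sex, stg, t, f) {
    parts <- character()
    if ("sex" %in% spec$p_terms) parts <- c(parts, sex)
    if ("year" %in% spec$p_terms) parts <- c(parts, paste0("t", t))
    if ("stage" %in% spec$p_terms)
      parts <- c(parts, if (stg == "hatchling" && t == f + 1) "J" else "A")
    key <- paste0("p:", if (length(parts)) paste(parts, collapse = ":") else "const")
    plogis(beta[[key]])
  }
  ll <- 0
  for (i in seq_len(nrow(det))) {
    y <- det[i, ]
    f <- which(y == 1)[1]
    l <- max(which(y == 1))
    sex <- histories$sex[i]
    stg <- histories$stage_at_marking[i]
    if (f == T_) next  # released on final occasion: no information
    prob <- 0
    for (a in l:T_) {  # alive through occasion a
      pr <- 1
      if (a > f) for (t in f:(a - 1)) pr <- pr * phi_of(sex, stg, t, f)
      if (a < T_) pr <- pr * (1 - phi_of(sex, stg, a, f))
      if (a > f) for (t in (f + 1):a)
        pr <- pr * (if (y[t] == 1) p_of(sex, stg, t, f)
                    else 1 - p_of(sex, stg, t, f))
      # occasions after death are necessarily undetected (prob 1)
      prob <- prob + pr
    }
    ll <- ll + log(prob)
  }
  ll
}

records_from_counts <- function(bi, m, f) {
  data.frame(family_id = seq_len(bi + m + f),
             category = rep(c("biparental", "male_only", "female_only"),
                            c(bi, m, f)))
}
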
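## Synthetic surgical-EHR cohort generator with planted outcome effects.
##
## Three event tables mirror the schema of an inpatient surgical data
## warehouse: one row per encounter (demographics, perioperative covariates,
## postoperative LOS, death offset), provider assignments (encounter,
## provider, role) and inter-unit transfer events. Outcome risk is planted on
## the log-odds scale as a linear combination of standardized covariate and
## connectivity terms, so that downstream models can be tested for signal
## recovery without any protected data.

PROVIDER_ROLES <- c("surgical_team", "other_clinician", "nurse", "technician", "other")
UNIT_TYPES <- c("intermediate", "intensive", "acute")
OUTCOMES <- c("plos", "mort30", "mort90")

#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set controlling cohort size, provider
#' pools, transfer intensity, planted outcome effects and missingness.
#'
#' Planted effects are expressed per outcome as named log-odds weights on
#' standardized terms. Recognised term names are any numeric encounter
#' covariate (e.g. `"age"`, `"bmi"`, `"cci"`, `"asa_ps"`), assignment counts
#' `"n_<role>"`, latent team-risk averages `"team_risk_<role>"` (mean of a
#' per-provider latent risk score over the encounter's providers of that
#' role), stay counts `"n_stay_<unit>"` and unit exposure `"hours_<unit>"`.
#'
#' @param n_patients number of patients (>= 0).
#' @param encounters_per_patient mean encounters per patient (>= 1); counts are
#'   drawn as 1 + Poisson(mean - 1).
#' @param provider_pool_sizes named integer vector of pool sizes for the five
#'   provider roles (surgical_team, other_clinician, nurse, technician, other).
#' @param team_size_range length-2 integer vector, overall min/max providers
#'   per encounter.
#' @param role_count_range named list of per-role length-2 min/max inclusion
#'   counts per encounter.
#' @param transfer_rate expected number of unit stays per encounter beyond the
#'   first (Poisson mean, >= 0).
#' @param baseline_logit named numeric vector of baseline log-odds for the
#'   outcomes `plos`, `mort30`, `mort90`. The mortality defaults are
#'   variance-corrected (logit-normal approximation,
#'   `logit(p) * sqrt(1 + 0.346 * sum(w^2))`) so that the *marginal*
#'   prevalences under the default planted effects land near 3.2% and 5.3%;
#'   with zero effect weights the marginal rate is `expit(baseline_logit)`
#'   directly.
#' @param effect_weights named list (per outcome) of named numeric log-odds
#'   weights on standardized terms; empty vectors mean no planted effect.
#' @param missingness_rates named numeric vector of per-feature missingness
#'   fractions in `[0, 1]`.
#' @param seed integer seed; the generator is fully reproducible given the
#'   config.
#' @return an object of class `synth_config` (a validated list).
#' @export
#' @examples
#' cfg <- synth_config(n_patients = 50, seed = 1)
#' tabs <- generate_cohort(cfg)
#' nrow(tabs$encounters)
synth_config <- function(n_patients = 3000,
                         encounters_per_patient = 1.33,
                         provider_pool_sizes = c(surgical_team = 60L,
                                                 other_clinician = 80L,
                                                 nurse = 120L,
                                                 technician = 50L,
                                                 other = 40L),
                         team_size_range = c(1L, 16L),
                         role_count_range = list(surgical_team = c(1L, 3L),
                                                 other_clinician = c(1L, 3L),
                                                 nurse = c(1L, 4L),
                                                 technician = c(0L, 3L),
                                                 other = c(0L, 2L)),
                         transfer_rate = 1.2,
                         baseline_logit = c(plos = logit(0.25),
                                            mort30 = -4.0214,
                                            mort90 = -3.4995),
                         effect_weights = list(plos = c(hours_acute = 0.8, cci = 0.5, age = 0.3),
                                               mort30 = c(age = 0.7, cci = 0.6, asa_ps = 0.5),
                                               mort90 = c(age = 0.8, cci = 0.7, asa_ps = 0.5)),
                         missingness_rates = c(bmi = 0.043, height = 0.043,
                                               marital_status = 0.0211,
                                               cci = 0.083, asa_ps = 0.017),
                         seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 0 ||
      n_patients != floor(n_patients))
    stopf("'n_patients' must be a non-negative integer")
  if (!is.numeric(encounters_per_patient) || encounters_per_patient < 1)
    stopf("'encounters_per_patient' must be >= 1")
  if (!all(PROVIDER_ROLES %in% names(provider_pool_sizes)))
    stopf("'provider_pool_sizes' must name all roles: %s",
          paste(PROVIDER_ROLES, collapse = ", "))
  if (any(provider_pool_sizes < 1)) stopf("'provider_pool_sizes' must be >= 1")
  if (length(team_size_range) != 2L || team_size_range[1] > team_size_range[2])
    stopf("'team_size_range' must be c(min, max) with min <= max")
  for (r in names(role_count_range)) {
    rng <- role_count_range[[r]]
    if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 0)
      stopf("'role_count_range$%s' must be c(min, max), 0 <= min <= max", r)
  }
  if (!is.numeric(transfer_rate) || transfer_rate < 0)
    stopf("'transfer_rate' must be >= 0")
  if (!all(OUTCOMES %in% names(baseline_logit)))
    stopf("'baseline_logit' must name %s", paste(OUTCOMES, collapse = ", "))
  if (!is.list(effect_weights) || !all(names(effect_weights) %in% OUTCOMES))
    stopf("'effect_weights' must be a list keyed by outcome (%s)",
          paste(OUTCOMES, collapse = ", "))
  for (o in OUTCOMES) if (is.null(effect_weights[[o]])) effect_weights[[o]] <- numeric(0)
  if (is.null(missingness_rates)) missingness_rates <- numeric(0)
  check_rate(missingness_rates, "missingness_rates")
  if (!is.numeric(seed) || length(seed) != 1L) stopf("'seed' must be an integer")
  structure(list(n_patients = as.integer(n_patients),
                 encounters_per_patient = encounters_per_patient,
                 provider_pool_sizes = provider_pool_sizes[PROVIDER_ROLES],
                 team_size_range = as.integer(team_size_range),
                 role_count_range = role_count_range,
                 transfer_rate = transfer_rate,
                 baseline_logit = baseline_logit[OUTCOMES],
                 effect_weights = effect_weights[OUTCOMES],
                 missingness_rates = missingness_rates,
                 seed = as.integer(seed)),
            class = "synth_config")
}

empty_encounters <- function() {
  data.frame(encounter_id = character(0), patient_id = character(0),
             age = numeric(0), sex = character(0), race_ethnicity = character(0),
             marital_status = character(0), height = numeric(0),
             weight = numeric(0), bmi = numeric(0), cci = numeric(0),
             asa_ps = numeric(0),
             flag_diabetes = integer(0), flag_hypertension = integer(0),
             flag_copd = integer(0), flag_ckd = integer(0),
             min_start_induction = numeric(0), min_induction_incision = numeric(0),
             min_incision_dressing = numeric(0), min_dressing_emergence = numeric(0),
             min_emergence_end = numeric(0), min_anesthesia = numeric(0),
             anesthesia_type = character(0), block_flag = integer(0),
             day_of_week = character(0), day_type = character(0),
             admission_source = character(0),
             hours_intermediate = numeric(0), hours_intensive = numeric(0),
             hours_acute = numeric(0),
             postop_los = numeric(0), death_offset = numeric(0),
             stringsAsFactors = FALSE)
}

## Resolve the planted term matrix (one column per effect-weight key) on the
## raw scale; standardization happens in generate_cohort.
resolve_terms <- function(keys, enc, conn) {
  known <- c(names(conn), names(enc)[vapply(enc, is.numeric, TRUE)])
  out <- matrix(0, nrow(enc), length(keys), dimnames = list(NULL, keys))
  for (k in keys) {
    if (!is.null(conn[[k]])) out[, k] <- conn[[k]]
    else if (k %in% names(enc) && is.numeric(enc[[k]])) out[, k] <- enc[[k]]
    else stopf("unknown effect term '%s'; known terms: %s", k,
               paste(sort(unique(known)), collapse = ", "))
  }
  out
}

#' Planted linear log-odds for one encounter
#'
#' Returns `baseline_logit + sum(weight * standardized term)` for the given
#' outcome. Term values are looked up first among the supplied connectivity
#' terms, then among numeric encounter covariates, and are expected on the
#' standardized scale used when the cohort was generated.
#'
#' @param encounter_row a single-row data.frame of (standardized) encounter
#'   covariates.
#' @param connectivity_terms named numeric vector/list of standardized
#'   connectivity terms (e.g. `team_risk_technician`, `hours_acute`).
#' @param config a [synth_config()].
#' @param outcome one of `"plos"`, `"mort30"`, `"mort90"`.
#' @return scalar log-odds.
#' @export
planted_outcome_logit <- function(encounter_row, connectivity_terms, config,
                                  outcome = "plos") {
  outcome <- match.arg(outcome, OUTCOMES)
  w <- config$effect_weights[[outcome]]
  b <- unname(config$baseline_logit[[outcome]])
  if (length(w) == 0L) return(b)
  tm <- resolve_terms(names(w), as.data.frame(encounter_row),
                      as.list(connectivity_terms))
  b + sum(w * tm[1L, names(w)])
}

std_cols <- function(m) {
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j]); sd <- sqrt(mean((m[, j] - mu)^2))
    m[, j] <- if (sd > 0) (m[, j] - mu) / sd else 0
  }
  m
}

#' Generate a synthetic surgical cohort
#'
#' Draws encounters, provider assignments and unit-transfer events under a
#' [synth_config()]. Outcomes are Bernoulli draws from the planted linear
#' log-odds; prolonged-LOS positives receive `postop_los` above 6 days and
#' negatives below, so that the 75th-percentile rule recovers the planted
#' label when prevalence is at its 25% default. Death offsets are sampled
#' uniformly on \[1, 30\] days for 30-day deaths and \[31, 90\] for 90-day-only
#' deaths, which makes the two mortality labels nested. Configured
#' missingness is injected last (MCAR).
#'
#' @param config a [synth_config()].
#' @return a list of class `medhg_cohort` with elements `encounters`,
#'   `assignments`, `transfers` (data.frames), and attributes
#'   `planted` (the drawn outcome labels) and `terms` (the standardized term
#'   matrix actually used), kept for validation.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) stopf("'config' must be a synth_config")
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n_pat <- config$n_patients
  if (n_pat == 0L) {
    out <- list(encounters = empty_encounters(),
                assignments = data.frame(encounter_id = character(0),
                                         provider_id = character(0),
                                         role = character(0),
                                         stringsAsFactors = FALSE),
                transfers = data.frame(encounter_id = character(0),
                                       unit_type = character(0),
                                       sequence_index = integer(0),
                                       duration = numeric(0),
                                       stringsAsFactors = FALSE))
    class(out) <- "medhg_cohort"
    return(out)
  }

  ## patient-level draws
  pat_id <- sprintf("PT%06d", seq_len(n_pat))
  n_enc_per <- 1L + stats::rpois(n_pat, config$encounters_per_patient - 1)
  age_p <- pmin(pmax(stats::rnorm(n_pat, 55.72, 18.01), 18), 100)
  sex_p <- sample(c("Female", "Male"), n_pat, TRUE, prob = c(0.6037, 0.3963))
  race_p <- sample(c("NHW", "NHB", "Hispanic", "Other"), n_pat, TRUE,
                   prob = c(0.6473, 0.1281, 0.0464, 0.1782))
  marital_p <- sample(c("Married", "Single", "Divorced", "Widowed"), n_pat, TRUE,
                      prob = c(0.45, 0.35, 0.12, 0.08))
  height_p <- stats::rnorm(n_pat, ifelse(sex_p == "Female", 162.5, 176.5), 7)
  weight_p <- pmax(stats::rnorm(n_pat, ifelse(sex_p == "Female", 74, 88), 16), 35)

  n_enc <- sum(n_enc_per)
  pat_of <- rep(seq_len(n_pat), n_enc_per)
  enc_id <- sprintf("EN%07d", seq_len(n_enc))

  enc <- data.frame(
    encounter_id = enc_id,
    patient_id = pat_id[pat_of],
    age = round(age_p[pat_of] + stats::runif(n_enc, 0, 2), 1),
    sex = sex_p[pat_of],
    race_ethnicity = race_p[pat_of],
    marital_status = marital_p[pat_of],
    height = round(height_p[pat_of], 1),
    weight = round(pmax(weight_p[pat_of] + stats::rnorm(n_enc, 0, 3), 35), 1),
    stringsAsFactors = FALSE)
  enc$bmi <- round(enc$weight / (enc$height / 100)^2, 2)
  enc$cci <- pmin(stats::rpois(n_enc, 1.6), 14)
  enc$asa_ps <- sample(1:5, n_enc, TRUE, prob = c(0.08, 0.32, 0.40, 0.17, 0.03))
  enc$flag_diabetes <- stats::rbinom(n_enc, 1, 0.22)
  enc$flag_hypertension <- stats::rbinom(n_enc, 1, 0.45)
  enc$flag_copd <- stats::rbinom(n_enc, 1, 0.10)
  enc$flag_ckd <- stats::rbinom(n_enc, 1, 0.12)
  enc$min_start_induction <- round(stats::rgamma(n_enc, 4, scale = 5), 1)
  enc$min_induction_incision <- round(stats::rgamma(n_enc, 3, scale = 8), 1)
  enc$min_incision_dressing <- round(stats::rgamma(n_enc, 2.5, scale = 45), 1)
  enc$min_dressing_emergence <- round(stats::rgamma(n_enc, 2, scale = 6), 1)
  enc$min_emergence_end <- round(stats::rgamma(n_enc, 2, scale = 5), 1)
  enc$min_anesthesia <- round(enc$min_start_induction + enc$min_induction_incision +
                                enc$min_incision_dressing + enc$min_dressing_emergence +
                                enc$min_emergence_end + stats::rgamma(n_enc, 2, scale = 5), 1)
  enc$anesthesia_type <- sample(c("General", "Regional", "MAC"), n_enc, TRUE,
                                prob = c(0.72, 0.16, 0.12))
  enc$block_flag <- stats::rbinom(n_enc, 1, 0.18)
  enc$day_of_week <- sample(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"),
                            n_enc, TRUE,
                            prob = c(0.19, 0.19, 0.19, 0.19, 0.18, 0.03, 0.03))
  enc$day_type <- ifelse(enc$day_of_week %in% c("Sat", "Sun"), "Weekend", "Weekday")
  enc$admission_source <- sample(c("Emergency", "Clinic", "Transfer"), n_enc, TRUE,
                                 prob = c(0.38, 0.50, 0.12))

  ## provider assignments: a shared pool per role induces cross-encounter
  ## co-occurrence; each provider carries a latent risk score used by the
  ## team_risk_* planted terms.
  prefixes <- c(surgical_team = "ST", other_clinician = "OC", nurse = "NU",
                technician = "TE", other = "OX")
  pools <- lapply(PROVIDER_ROLES, function(r) {
    k <- config$provider_pool_sizes[[r]]
    list(ids = sprintf("%s%04d", prefixes[[r]], seq_len(k)),
         risk = stats::rnorm(k))
  })
  names(pools) <- PROVIDER_ROLES

  asg_enc <- character(0); asg_prov <- character(0); asg_role <- character(0)
  conn <- list()
  for (r in PROVIDER_ROLES) {
    rng <- config$role_count_range[[r]] %||% c(0L, 2L)
    k_pool <- length(pools[[r]]$ids)
    cnt <- pmin(sample(rng[1]:rng[2], n_enc, TRUE), k_pool)
    idx <- lapply(cnt, function(m) if (m > 0) sample.int(k_pool, m) else integer(0))
    asg_enc <- c(asg_enc, rep(enc_id, cnt))
    asg_prov <- c(asg_prov, pools[[r]]$ids[unlist(idx)])
    asg_role <- c(asg_role, rep(r, sum(cnt)))
    conn[[paste0("n_", r)]] <- cnt
    conn[[paste0("team_risk_", r)]] <-
      vapply(idx, function(i) if (length(i)) mean(pools[[r]]$risk[i]) else 0, 0)
  }
  ## guarantee >= 1 assignment per encounter (min team size): surgical_team
  ## min is 1 by default, but guard anyway for custom configs
  missing_enc <- setdiff(enc_id, unique(asg_enc))
  if (length(missing_enc)) {
    asg_enc <- c(asg_enc, missing_enc)
    asg_prov <- c(asg_prov, sample(pools$surgical_team$ids, length(missing_enc), TRUE))
    asg_role <- c(asg_role, rep("surgical_team", length(missing_enc)))
  }
  assignments <- data.frame(encounter_id = asg_enc, provider_id = asg_prov,
                            role = asg_role, stringsAsFactors = FALSE)
  assignments <- assignments[order(assignments$encounter_id, assignments$role,
                                   assignments$provider_id), , drop = FALSE]
  rownames(assignments) <- NULL

  ## unit stays: 1 + Poisson(transfer_rate) stays per encounter; sicker mixes
  ## weighted toward acute/intensive via admission source
  n_stay <- 1L + stats::rpois(n_enc, config$transfer_rate)
  stay_probs <- cbind(intermediate = 0.30, intensive = 0.20, acute = 0.50)
  tr_enc <- rep(enc_id, n_stay)
  tr_seq <- unlist(lapply(n_stay, function(m) seq_len(m) - 1L))
  tr_unit <- unlist(lapply(n_stay, function(m)
    sample(UNIT_TYPES, m, TRUE, prob = stay_probs[1, ])))
  tr_dur <- round(stats::rgamma(length(tr_enc), 2, scale = 10), 2)
  transfers <- data.frame(encounter_id = tr_enc, unit_type = tr_unit,
                          sequence_index = tr_seq, duration = tr_dur,
                          stringsAsFactors = FALSE)

  for (u in UNIT_TYPES) {
    cnt <- numeric(n_enc); hrs <- numeric(n_enc)
    sel <- transfers$unit_type == u
    if (any(sel)) {
      tb <- tapply(rep(1, sum(sel)), transfers$encounter_id[sel], sum)
      hb <- tapply(transfers$duration[sel], transfers$encounter_id[sel], sum)
      cnt[match(names(tb), enc_id)] <- tb
      hrs[match(names(hb), enc_id)] <- hb
    }
    conn[[paste0("n_stay_", u)]] <- cnt
    conn[[paste0("hours_", u)]] <- hrs
    enc[[paste0("hours_", u)]] <- hrs
  }

  ## planted outcomes
  keys <- unique(unlist(lapply(config$effect_weights, names)))
  tm <- if (length(keys)) std_cols(resolve_terms(keys, enc, conn)) else
    matrix(0, n_enc, 0)
  lin <- function(outcome) {
    w <- config$effect_weights[[outcome]]
    b <- unname(config$baseline_logit[[outcome]])
    if (length(w) == 0L) rep(b, n_enc) else b + drop(tm[, names(w), drop = FALSE] %*% w)
  }
  p_plos <- expit(lin("plos"))
  p_m30 <- expit(lin("mort30"))
  p_m90 <- pmax(expit(lin("mort90")), p_m30)
  y_plos <- stats::rbinom(n_enc, 1, p_plos)
  y_m30 <- stats::rbinom(n_enc, 1, p_m30)
  extra <- ifelse(p_m30 < 1, (p_m90 - p_m30) / (1 - p_m30), 0)
  y_m90 <- pmax(y_m30, stats::rbinom(n_enc, 1, extra))

  ## postop LOS: negatives in [0, 6), positives above 6 days, so the
  ## 75th-percentile rule matches the planted label at default prevalence
  enc$postop_los <- round(ifelse(y_plos == 1,
                                 6 + stats::rgamma(n_enc, 1.5, scale = 4),
                                 6 * stats::rbeta(n_enc, 2, 1.5)), 2)
  enc$death_offset <- rep(NA_real_, n_enc)
  enc$death_offset[y_m30 == 1] <- round(stats::runif(sum(y_m30), 1, 30), 1)
  only90 <- y_m90 == 1 & y_m30 == 0
  enc$death_offset[only90] <- round(stats::runif(sum(only90), 31, 90), 1)

  if (length(config$missingness_rates) && any(config$missingness_rates > 0))
    enc <- inject_missingness(enc, config$missingness_rates,
                              seed = child_seed(config$seed, "missingness"))

  out <- list(encounters = enc, assignments = assignments, transfers = transfers)
  attr(out, "planted") <- data.frame(encounter_id = enc_id, plos = y_plos,
                                     mort30 = y_m30, mort90 = y_m90)
  attr(out, "terms") <- tm
  attr(out, "config") <- config
  class(out) <- "medhg_cohort"
  out
}

#' @export
print.medhg_cohort <- function(x, ...) {
  cat("Synthetic surgical cohort:\n")
  cat(sprintf("  %d encounters, %d patients\n", nrow(x$encounters),
              length(unique(x$encounters$patient_id))))
  cat(sprintf("  %d provider assignments, %d unit stays\n",
              nrow(x$assignments), nrow(x$transfers)))
  invisible(x)
}

#' Inject missing-completely-at-random cells into an encounter table
#'
#' Masks each listed feature independently at its nominal rate. Used both by
#' the generator (cohort missingness) and by the robustness masking
#' experiment.
#'
#' @param table an encounter data.frame.
#' @param rates named numeric vector, feature -> fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return the table with masked cells set to `NA`.
#' @export
inject_missingness <- function(table, rates, seed = 1L) {
  check_rate(rates, "rates")
  bad <- setdiff(names(rates), names(table))
  if (length(bad)) stopf("unknown feature(s) in rates: %s", paste(bad, collapse = ", "))
  with_seed(seed, {
    for (f in names(rates)) {
      r <- rates[[f]]
      if (r <= 0) next
      hit <- stats::runif(nrow(table)) < r
      table[[f]][hit] <- NA
    }
    table
  })
}

#' Write a cohort's three tables as CSV
#'
#' @param cohort a `medhg_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$encounters, file.path(dir, "encounters.csv"), row.names = FALSE)
  utils::write.csv(cohort$assignments, file.path(dir, "assignments.csv"), row.names = FALSE)
  utils::write.csv(cohort$transfers, file.path(dir, "transfers.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir directory containing `encounters.csv`, `assignments.csv`,
#'   `transfers.csv`.
#' @return a `medhg_cohort` list.
#' @export
read_cohort <- function(dir) {
  out <- list(
    encounters = utils::read.csv(file.path(dir, "encounters.csv"),
                                 stringsAsFactors = FALSE),
    assignments = utils::read.csv(file.path(dir, "assignments.csv"),
                                  stringsAsFactors = FALSE),
    transfers = utils::read.csv(file.path(dir, "transfers.csv"),
                                stringsAsFactors = FALSE))
  class(out) <- "medhg_cohort"
  out
}
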
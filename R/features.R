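## Outcome derivation, feature-matrix construction and the cohort-level
## experiment mechanics (masking, resampling, data splits).

#' Derive binary outcome labels from an encounter table
#'
#' Prolonged length of stay (PLOS) is defined against the cohort's LOS
#' quantile (default the 75th percentile, the conventional PLOS cut-off):
#' `plos = 1` iff `postop_los` strictly exceeds the threshold computed over
#' `reference_rows`. Mortality labels use an inclusive window on the death
#' offset: `mort30 = 1` iff death occurred within 30 days of the index date,
#' `mort90` within 90; the labels are nested by construction.
#'
#' @param encounters encounter data.frame with `postop_los` and
#'   `death_offset` columns.
#' @param quantile LOS quantile in (0,1) defining the PLOS threshold.
#' @param reference_rows encounter ids over which the threshold quantile is
#'   computed (e.g. the training split); defaults to all rows.
#' @param qtype quantile convention passed to [stats::quantile()]; the default
#'   7 is linear interpolation between order statistics.
#' @return data.frame of class `medhg_labels`: `encounter_id`, `plos`,
#'   `mort30`, `mort90`, with the threshold in attribute
#'   `plos_threshold_days`.
#' @export
derive_outcomes <- function(encounters, quantile = 0.75, reference_rows = NULL,
                            qtype = 7) {
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1)
    stopf("'quantile' must be in (0, 1)")
  if (any(is.na(encounters$postop_los)))
    stopf("'postop_los' must be present for all rows")
  ref <- if (is.null(reference_rows)) encounters$encounter_id else reference_rows
  if (length(ref) == 0L) stopf("'reference_rows' must be nonempty")
  los_ref <- encounters$postop_los[match(ref, encounters$encounter_id)]
  if (any(is.na(los_ref))) stopf("reference_rows contain unknown encounter ids")
  thr <- unname(stats::quantile(los_ref, quantile, type = qtype))
  d <- encounters$death_offset
  out <- data.frame(encounter_id = encounters$encounter_id,
                    plos = as.integer(encounters$postop_los > thr),
                    mort30 = as.integer(!is.na(d) & d <= 30),
                    mort90 = as.integer(!is.na(d) & d <= 90),
                    stringsAsFactors = FALSE)
  attr(out, "plos_threshold_days") <- thr
  class(out) <- c("medhg_labels", "data.frame")
  out
}

#' Default covariate schema for the synthetic encounter table
#'
#' Lists which columns are treated as continuous, categorical or binary, and
#' the plausibility ranges used to null out physiologically impossible values
#' before fitting (configurable; values outside a range are treated as
#' missing).
#'
#' @return a list with elements `continuous`, `categorical`, `binary`,
#'   `ranges`.
#' @export
default_feature_schema <- function() {
  list(
    continuous = c("age", "height", "weight", "bmi", "cci", "asa_ps",
                   "min_start_induction", "min_induction_incision",
                   "min_incision_dressing", "min_dressing_emergence",
                   "min_emergence_end", "min_anesthesia",
                   "hours_intermediate", "hours_intensive", "hours_acute"),
    categorical = c("sex", "race_ethnicity", "marital_status",
                    "anesthesia_type", "day_of_week", "day_type",
                    "admission_source"),
    binary = c("flag_diabetes", "flag_hypertension", "flag_copd", "flag_ckd",
               "block_flag"),
    ranges = list(age = c(18, 110), bmi = c(10, 80), height = c(120, 220),
                  weight = c(30, 300),
                  min_start_induction = c(0, Inf), min_induction_incision = c(0, Inf),
                  min_incision_dressing = c(0, Inf), min_dressing_emergence = c(0, Inf),
                  min_emergence_end = c(0, Inf), min_anesthesia = c(0, Inf),
                  hours_intermediate = c(0, Inf), hours_intensive = c(0, Inf),
                  hours_acute = c(0, Inf)))
}

#' Build the encounter feature matrix
#'
#' Continuous covariates: values outside the schema's plausibility range are
#' set missing; the mean and population SD are learned on the observed
#' training values only; missing entries are imputed with the training mean
#' and every value standardized to the training scale. Categorical
#' covariates: missing values become the `"Unknown"` level, categories unseen
#' in training map to `"Unknown"`, and each variable is one-hot encoded (the
#' group sums to 1 per row). Binary flags pass through with missing set to 0.
#' Zero-variance continuous columns (or columns entirely missing in training)
#' are dropped with a warning.
#'
#' @param encounters encounter data.frame.
#' @param schema a schema list as from [default_feature_schema()]; columns not
#'   present in the table are ignored.
#' @param train_ids encounter ids on which transformation statistics are
#'   fitted (no leakage from validation/test rows).
#' @return object of class `medhg_features`: list with dense matrix `X`
#'   (rownames = encounter ids), `columns` (name, kind, source), and
#'   `fitted_stats`.
#' @export
build_feature_matrix <- function(encounters, schema = default_feature_schema(),
                                 train_ids = encounters$encounter_id) {
  if (length(train_ids) == 0L) stopf("'train_ids' must be nonempty")
  tr <- match(train_ids, encounters$encounter_id)
  if (any(is.na(tr))) stopf("train_ids contain unknown encounter ids")
  n <- nrow(encounters)
  cols <- list(); info <- list(); stats_out <- list()

  for (v in intersect(schema$continuous, names(encounters))) {
    x <- as.numeric(encounters[[v]])
    rng <- schema$ranges[[v]]
    if (!is.null(rng)) x[!is.na(x) & (x < rng[1] | x > rng[2])] <- NA
    obs <- x[tr]; obs <- obs[!is.na(obs)]
    if (length(obs) == 0L) {
      warnf("continuous column '%s' has no observed training values; dropped", v)
      next
    }
    mu <- mean(obs); sd <- sqrt(mean((obs - mu)^2))
    if (sd == 0) {
      warnf("continuous column '%s' has zero variance on training rows; dropped", v)
      next
    }
    x[is.na(x)] <- mu
    cols[[v]] <- (x - mu) / sd
    info[[v]] <- data.frame(name = v, kind = "continuous", source = v)
    stats_out[[v]] <- list(mean = mu, sd = sd)
  }

  for (v in intersect(schema$categorical, names(encounters))) {
    x <- as.character(encounters[[v]])
    x[is.na(x) | x == ""] <- "Unknown"
    lev <- sort(unique(x[tr]))
    if (!"Unknown" %in% lev) lev <- c(lev, "Unknown")
    x[!x %in% lev] <- "Unknown"
    for (l in lev) {
      nm <- paste0(v, "=", l)
      cols[[nm]] <- as.numeric(x == l)
      info[[nm]] <- data.frame(name = nm, kind = "one-hot", source = v)
    }
    stats_out[[v]] <- list(levels = lev)
  }

  for (v in intersect(schema$binary, names(encounters))) {
    x <- as.numeric(encounters[[v]])
    x[is.na(x)] <- 0
    cols[[v]] <- x
    info[[v]] <- data.frame(name = v, kind = "binary", source = v)
  }

  if (length(cols) == 0L) stopf("no usable feature columns")
  X <- do.call(cbind, cols)
  rownames(X) <- encounters$encounter_id
  out <- list(X = X, columns = do.call(rbind, info), fitted_stats = stats_out,
              train_ids = train_ids)
  class(out) <- "medhg_features"
  out
}

#' @export
print.medhg_features <- function(x, ...) {
  cat(sprintf("Encounter feature matrix: %d rows x %d columns (%d continuous, %d one-hot, %d binary)\n",
              nrow(x$X), ncol(x$X), sum(x$columns$kind == "continuous"),
              sum(x$columns$kind == "one-hot"), sum(x$columns$kind == "binary")))
  invisible(x)
}

#' Cohort-table percentage
#'
#' The rounding convention used throughout cohort summaries:
#' `100 * count / total` to two decimals.
#'
#' @param count,total non-negative counts.
#' @return percentage rounded to 2 decimals.
#' @export
summary_percent <- function(count, total) round(100 * count / total, 2)

#' Cohort summary table
#'
#' Counts and percentages in the layout of a cohort-description table:
#' patient-level demographic strata are counted once per patient (first
#' encounter), encounter-level outcomes once per encounter; percentages are
#' `100 * count / total` rounded to two decimals.
#'
#' @param encounters encounter data.frame.
#' @param labels labels from [derive_outcomes()].
#' @return data.frame with columns `level`, `variable`, `stratum`, `count`,
#'   `percent`.
#' @export
cohort_summary <- function(encounters, labels) {
  if (!identical(labels$encounter_id, encounters$encounter_id))
    labels <- labels[match(encounters$encounter_id, labels$encounter_id), ]
  first <- !duplicated(encounters$patient_id)
  pat <- encounters[first, , drop = FALSE]
  n_pat <- nrow(pat); n_enc <- nrow(encounters)
  rows <- list()
  add <- function(level, variable, stratum, count, total)
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, variable = variable, stratum = stratum,
      count = count, percent = summary_percent(count, total),
      stringsAsFactors = FALSE)
  add("patient", "total", "", n_pat, n_pat)
  for (v in intersect(c("sex", "race_ethnicity"), names(pat)))
    for (s in sort(unique(stats::na.omit(pat[[v]]))))
      add("patient", v, s, sum(pat[[v]] == s, na.rm = TRUE), n_pat)
  add("encounter", "total", "", n_enc, n_enc)
  for (o in c("plos", "mort30", "mort90")) {
    add("encounter", o, "Yes", sum(labels[[o]] == 1), n_enc)
    add("encounter", o, "No", sum(labels[[o]] == 0), n_enc)
  }
  do.call(rbind, rows)
}

#' Mask features of an already-built cohort (robustness experiment)
#'
#' Identical mechanics to [inject_missingness()], applied to a cohort before
#' feature-matrix construction to probe the imputation strategy.
#'
#' @inheritParams inject_missingness
#' @param mask_spec named numeric vector, feature -> masking rate in `[0,1]`.
#' @export
mask_features <- function(table, mask_spec, seed = 1L) {
  inject_missingness(table, mask_spec, seed = seed)
}

#' Rebalance training ids by under- or oversampling
#'
#' `undersample` randomly drops negatives until the classes are balanced (no
#' duplicates); `oversample` duplicates positives (sampling with replacement)
#' up to the negative count; `none` returns the input unchanged.
#'
#' @param ids training encounter ids.
#' @param labels named or aligned 0/1 vector for those ids.
#' @param mode `"none"`, `"undersample"` or `"oversample"`.
#' @param seed integer seed.
#' @return character vector of (possibly repeated) ids.
#' @export
resample_training <- function(ids, labels, mode = c("none", "undersample", "oversample"),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (length(ids) != length(labels)) stopf("ids and labels must align")
  pos <- ids[labels == 1]; neg <- ids[labels == 0]
  if (mode != "none" && (length(pos) == 0L || length(neg) == 0L))
    stopf("resampling requires both classes present")
  with_seed(seed, switch(mode,
    none = ids,
    undersample = sample(c(pos, sample(neg, length(pos)))),
    oversample = sample(c(neg, pos, sample(pos, length(neg) - length(pos),
                                           replace = TRUE)))))
}

#' Train/validation/test split
#'
#' Random split in the given ratios (default 8:1:1). With
#' `group_by = "patient"` all encounters of one patient are kept in the same
#' split (a leakage guard for correlated repeat encounters).
#'
#' @param encounters encounter data.frame.
#' @param ratios positive length-3 numeric vector.
#' @param seed integer seed.
#' @param group_by `"encounter"` (default) or `"patient"`.
#' @return list of class `medhg_splits` with `train`, `validation`, `test`
#'   id vectors plus the call parameters.
#' @export
split_indices <- function(encounters, ratios = c(8, 1, 1), seed = 1L,
                          group_by = c("encounter", "patient")) {
  group_by <- match.arg(group_by)
  if (length(ratios) != 3L || any(ratios <= 0)) stopf("'ratios' must be 3 positive numbers")
  units <- if (group_by == "patient") unique(encounters$patient_id)
           else encounters$encounter_id
  if (length(units) < 3L) stopf("fewer groups (%d) than splits", length(units))
  perm <- with_seed(seed, sample(units))
  cuts <- round(cumsum(ratios) / sum(ratios) * length(units))
  grp <- list(train = perm[seq_len(cuts[1])],
              validation = perm[(cuts[1] + 1):cuts[2]],
              test = perm[(cuts[2] + 1):cuts[3]])
  out <- if (group_by == "patient")
    lapply(grp, function(g) encounters$encounter_id[encounters$patient_id %in% g])
  else grp
  out$ratios <- ratios; out$seed <- seed; out$group_by <- group_by
  class(out) <- "medhg_splits"
  out
}
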
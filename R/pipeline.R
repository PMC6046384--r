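# Orchestration: per-subject measure extraction and cohort-level runs.

#' Default Bonferroni families of cardiac measures
#'
#' The four conceptual families used when grouping two-group comparisons
#' for Bonferroni correction: time domain (HR, RMSSD), frequency domain
#' (LF, lnHF), scaling measures (DFA alpha1, alpha2, FD) and the entropy
#' measures (five scale factors). With a base alpha of 0.05 the per-test
#' levels are 0.025, 0.025, 0.017 and 0.01.
#'
#' @return named list of character vectors of measure column names.
#' @export
measure_families <- function() {
  list(time_domain = c("hr", "rmssd"),
       frequency = c("lf", "ln_hf"),
       scaling = c("dfa_alpha1", "dfa_alpha2", "fd"),
       entropy = paste0("mse_s", c(1, 5, 10, 15, 20)))
}

# Short content hash (polynomial rolling hash over the serialized
# object) used to stamp output files so reruns with an identical
# configuration are identifiable.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Extract all cardiac measures from one recording
#'
#' Runs the full per-subject chain: preprocessing (trim, band filter,
#' central-window filter), time- and frequency-domain HRV, DFA,
#' allometric fractal dimension and multiscale entropy. Returns a
#' one-row data frame; on failure of any stage the row carries the error
#' message in `error` with measure columns `NA`, so a batch can continue.
#'
#' @param x a file path, a `raw_ibi` recording, or a numeric IBI vector.
#' @param filter_cfg,spectral_cfg,dfa_cfg,allo_cfg,mse_cfg stage
#'   configurations.
#' @return one-row data frame: `subject_id`, filter-report counts, the
#'   twelve measure columns, and `error` (`NA` when all stages
#'   succeeded).
#' @export
run_subject <- function(x,
                        filter_cfg = filter_config(),
                        spectral_cfg = spectral_config(),
                        dfa_cfg = dfa_config(),
                        allo_cfg = allometric_config(),
                        mse_cfg = mse_config()) {
  if (is.character(x)) x <- read_ibi_file(x)
  if (is.numeric(x)) x <- raw_ibi(x)
  measure_cols <- c("avnn", "hr", "rmssd", "lf", "hf", "ln_hf",
                    "dfa_alpha1", "dfa_alpha2", "allometric_h", "fd",
                    paste0("mse_s", mse_config()$scales))
  tryCatch({
    cln <- preprocess(x, filter_cfg)
    hrv <- hrv_measures(cln, spectral_cfg)
    cc <- complexity_measures(cln, dfa_cfg, allo_cfg, mse_cfg)
    out <- cbind(cln$report,
                 as.data.frame(c(hrv, cc), stringsAsFactors = FALSE))
    out$error <- NA_character_
    out
  }, error = function(e) {
    out <- data.frame(subject_id = x$subject_id, n_input = NA_integer_,
                      n_excluded_band = NA_integer_,
                      n_excluded_window = NA_integer_,
                      n_output = NA_integer_,
                      excluded_fraction = NA_real_,
                      stringsAsFactors = FALSE)
    for (mc in measure_cols) out[[mc]] <- NA_real_
    out$error <- conditionMessage(e)
    out
  })
}

#' Extract measures for a batch of recordings
#'
#' @param xs list of file paths, recordings or numeric vectors.
#' @param ... stage configurations passed on to [run_subject()].
#' @return data frame with one row per input, in order; failed subjects
#'   carry their error message and do not interrupt the batch.
#' @export
run_subjects <- function(xs, ...) {
  do.call(rbind, lapply(xs, run_subject, ...))
}

#' Run the cohort-level analysis
#'
#' Applies the HR-adjustment rule, the Bonferroni-grouped two-group
#' comparisons (with Cohen's d) and the two-step hierarchical
#' regressions of every symptom subscale on sex and each cardiac
#' measure, for both unadjusted and HR-adjusted measures. Mean HR itself
#' is never adjusted (it would be constant under its own rule).
#'
#' @param cohort data frame, one row per subject, with `sex_code`,
#'   measure columns and (optionally) symptom columns.
#' @param measures measure column names (default the twelve standard
#'   measures present in the cohort).
#' @param outcomes symptom column names to regress (default: any of the
#'   standard subscales present).
#' @param families named list grouping measures for Bonferroni
#'   correction (default [measure_families()], intersected with
#'   `measures`).
#' @param base_alpha family-wise alpha before correction (default 0.05).
#' @param adjust run the HR-adjusted arm as well (default TRUE).
#' @param out_dir if non-NULL, tidy CSVs (`comparisons.csv`,
#'   `regressions.csv`, `hr_adjustment.csv`) are written there, each
#'   stamped with the seed and a configuration hash in a `#` header line.
#' @param seed seed recorded in the output stamps (the analysis itself is
#'   deterministic).
#' @return list with `comparisons`, `regressions`, `adjustment` data
#'   frames and the `config_hash` string.
#' @export
run_cohort <- function(cohort,
                       measures = intersect(cohort_measure_defaults()$measure,
                                            names(cohort)),
                       outcomes = intersect(names(cohort_symptom_defaults()),
                                            names(cohort)),
                       families = measure_families(),
                       base_alpha = 0.05,
                       adjust = TRUE,
                       out_dir = NULL,
                       seed = NA_integer_) {
  families <- lapply(families, intersect, y = measures)
  families <- families[vapply(families, length, 1L) > 0]

  adjustment <- NULL
  if (adjust) {
    adj <- hr_adjust(cohort, setdiff(measures, "hr"))
    cohort <- adj$cohort
    cohort$hr_adj <- cohort$hr # HR is not adjusted by itself
    adjustment <- adj$report
  }

  comp_arm <- function(suffix, state) {
    do.call(rbind, lapply(names(families), function(fam) {
      fam_measures <- paste0(families[[fam]], suffix)
      alpha <- bonferroni_alpha(base_alpha, length(families[[fam]]))
      out <- compare_groups(cohort, fam_measures, family_alpha = alpha)
      out$family <- fam
      out$adjustment <- state
      out
    }))
  }
  comparisons <- comp_arm("", "unadjusted")
  if (adjust) comparisons <- rbind(comparisons, comp_arm("_adj", "adjusted"))

  regressions <- NULL
  if (length(outcomes) > 0) {
    arms <- if (adjust) c("", "_adj") else ""
    regressions <- do.call(rbind, lapply(arms, function(suffix) {
      do.call(rbind, lapply(outcomes, function(oc) {
        do.call(rbind, lapply(setdiff(measures, character(0)), function(m) {
          tr <- tidy_hier_reg(
            hierarchical_regression(cohort, oc, paste0(m, suffix)))
          tr$adjustment <- if (suffix == "") "unadjusted" else "adjusted"
          tr
        }))
      }))
    }))
  }

  hash <- config_hash(list(measures = measures, outcomes = outcomes,
                           families = families, base_alpha = base_alpha,
                           adjust = adjust, n = nrow(cohort)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- sprintf("# hrvcc run: seed=%s config_hash=%s", seed, hash)
    wr <- function(df, file) {
      if (is.null(df)) return(invisible(NULL))
      path <- file.path(out_dir, file)
      writeLines(stamp, path)
      suppressWarnings(write.table(df, path, sep = ",", row.names = FALSE,
                                   append = TRUE, quote = FALSE))
    }
    wr(comparisons, "comparisons.csv")
    wr(regressions, "regressions.csv")
    wr(adjustment, "hr_adjustment.csv")
  }
  list(comparisons = comparisons, regressions = regressions,
       adjustment = adjustment, config_hash = hash)
}
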
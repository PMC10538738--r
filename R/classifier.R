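# Decision rules applied per subject: per-muscle reduced-thickness flags
# against the normative reference, the "at least k abnormal muscles"
# verdicts, proximal-distal differential markers, and fasciculation-count
# criteria. Missing observations are excluded from every count -- a muscle
# that was not measured is never scored.

#' Decision-rule configuration
#'
#' @param min_abnormal_muscles Minimum number of reduced-thickness muscles
#'   for a positive thickness verdict (default 1).
#' @param fasc_threshold_all8 Minimum number of fasciculating muscles among
#'   all eight for a positive fasciculation verdict (default 2).
#' @param fasc_threshold_proximal Minimum among the proximal subset
#'   (default 1).
#' @param proximal_set Muscles forming the proximal subset (default biceps
#'   and quadriceps).
#' @param scan_window_s Fasciculation observation window in seconds
#'   (default 15; metadata only -- presence is recorded as a boolean).
#' @return A `musono_rule_config`.
#' @export
rule_config <- function(min_abnormal_muscles = 1, fasc_threshold_all8 = 2,
                        fasc_threshold_proximal = 1,
                        proximal_set = proximal_muscles(),
                        scan_window_s = 15) {
  stopifnot(min_abnormal_muscles >= 1, fasc_threshold_all8 >= 1,
            fasc_threshold_proximal >= 1, scan_window_s > 0,
            all(proximal_set %in% .MUSCLES))
  structure(list(min_abnormal_muscles = as.integer(min_abnormal_muscles),
                 fasc_threshold_all8 = as.integer(fasc_threshold_all8),
                 fasc_threshold_proximal = as.integer(fasc_threshold_proximal),
                 proximal_set = proximal_set,
                 scan_window_s = scan_window_s),
            class = "musono_rule_config")
}

#' Flag a single thickness measurement against a cutoff
#'
#' Strict comparison: a thickness exactly equal to the cutoff is NORMAL
#' ("lower than the percentile" means strictly lower).
#'
#' @param thickness Thickness in cm (non-negative); vectorized.
#' @param cutoff Normative cutoff in cm (positive); vectorized.
#' @return Character vector of `"ABNORMAL"` / `"NORMAL"`.
#' @export
#' @examples
#' flag_muscle(0.30, 0.35)  # ABNORMAL
#' flag_muscle(0.35, 0.35)  # NORMAL (boundary)
flag_muscle <- function(thickness, cutoff) {
  if (any(!is.na(thickness) & thickness < 0)) {
    stop("negative thickness", call. = FALSE)
  }
  if (any(!is.na(cutoff) & cutoff <= 0)) stop("cutoff must be positive", call. = FALSE)
  ifelse(is.na(thickness), NA_character_,
         ifelse(thickness < cutoff, "ABNORMAL", "NORMAL"))
}

#' Biceps-EDB thickness differential
#'
#' Relaxed biceps thickness minus EDB thickness (cm), a proxy for the
#' proximal-versus-distal atrophy pattern: low in myopathy and SMA
#' (proximal loss), high in polyneuropathy (distal loss). Computed for
#' every subject, controls included; may be negative; missing when either
#' measurement is absent.
#'
#' @param cohort A `musono_cohort` (any number of rows).
#' @return Numeric vector (cm), NA where either muscle is unmeasured.
#' @export
biceps_minus_edb <- function(cohort) {
  stopifnot(inherits(cohort, "musono_cohort"))
  cohort$rel_biceps - cohort$rel_edb
}

#' MRC elbow-flexion minus big-toe-extension differential
#'
#' Strength analogue of the proximal-distal thickness differential.
#' Missing when either movement was not graded (big-toe extension is not
#' tested in SMA).
#'
#' @param cohort A `musono_cohort`.
#' @return Numeric vector, NA where either score is absent.
#' @export
mrc_differential <- function(cohort) {
  stopifnot(inherits(cohort, "musono_cohort"))
  cohort$mrc_elbow_flex - cohort$mrc_bigtoe_ext
}

# cutoff vector for one (muscle, state) across subjects given stratum index
.cutoff_vector <- function(ref, muscle, state, si) {
  by_stratum <- rep(NA_real_, nrow(ref$strata))
  hit <- ref$cutoffs$muscle == muscle & ref$cutoffs$state == state
  by_stratum[ref$cutoffs$stratum_index[hit]] <- ref$cutoffs$cutoff_cm[hit]
  by_stratum[si]
}

#' Classify every subject in a cohort
#'
#' Applies the full rule set to each record: per-muscle reduced-thickness
#' flags (relaxed over all eight muscles, contracted over the four
#' contracted-capable muscles), the overall thickness verdicts, the
#' biceps-EDB and MRC differentials, and both fasciculation criteria.
#' Unmeasured muscles are MISSING and excluded from all counts; a subject
#' with no usable observations for a rule gets a missing verdict, not a
#' negative one.
#'
#' @param cohort A `musono_cohort`.
#' @param ref A `musono_reference` covering every subject's age and sex.
#' @param config A `musono_rule_config`.
#' @return A `musono_profiles` data.frame, one row per subject.
#' @export
classify_cohort <- function(cohort, ref, config = rule_config()) {
  stopifnot(inherits(cohort, "musono_cohort"), inherits(ref, "musono_reference"),
            inherits(config, "musono_rule_config"))
  n <- nrow(cohort)
  si <- .stratum_index(ref$strata, cohort$sex, cohort$age)
  if (anyNA(si)) {
    stop("age outside reference coverage for subject(s): ",
         paste(cohort$subject_id[is.na(si)], collapse = ", "), call. = FALSE)
  }

  out <- data.frame(subject_id = cohort$subject_id, group = cohort$group,
                    stringsAsFactors = FALSE)

  flag_block <- function(muscles_in, state) {
    flags <- matrix(NA_character_, nrow = n, ncol = length(muscles_in),
                    dimnames = list(NULL, muscles_in))
    for (m in muscles_in) {
      th <- cohort[[thick_col(m, state)]]
      cut <- .cutoff_vector(ref, m, state, si)
      observed_uncovered <- !is.na(th) & is.na(cut)
      if (any(observed_uncovered)) {
        stop("no populated cutoff for ", m, "/", state,
             " in the stratum of subject(s): ",
             paste(cohort$subject_id[observed_uncovered], collapse = ", "),
             call. = FALSE)
      }
      flags[, m] <- flag_muscle(th, ifelse(is.na(cut), 1, cut))
    }
    flags
  }
  rel_flags <- flag_block(.MUSCLES, "RELAXED")
  con_flags <- flag_block(.CONTRACTED_MUSCLES, "CONTRACTED")

  for (m in .MUSCLES) out[[paste0("flag_rel_", .MUSCLE_COL[m])]] <- rel_flags[, m]
  for (m in .CONTRACTED_MUSCLES) {
    out[[paste0("flag_con_", .MUSCLE_COL[m])]] <- con_flags[, m]
  }

  n_abn <- function(flags) rowSums(flags == "ABNORMAL", na.rm = TRUE)
  n_obs <- function(flags) rowSums(!is.na(flags))
  out$n_relaxed_abnormal <- as.integer(n_abn(rel_flags))
  out$n_relaxed_observed <- as.integer(n_obs(rel_flags))
  out$relaxed_positive <- ifelse(out$n_relaxed_observed == 0, NA,
                                 out$n_relaxed_abnormal >= config$min_abnormal_muscles)
  out$n_contracted_abnormal <- as.integer(n_abn(con_flags))
  out$n_contracted_observed <- as.integer(n_obs(con_flags))
  out$contracted_positive <- ifelse(out$n_contracted_observed == 0, NA,
                                    out$n_contracted_abnormal >= config$min_abnormal_muscles)

  out$biceps_minus_edb_cm <- biceps_minus_edb(cohort)
  out$mrc_elbowflex_minus_bigtoe <- mrc_differential(cohort)

  fasc <- as.matrix(as.data.frame(lapply(fasc_col(.MUSCLES),
                                         function(cl) cohort[[cl]])))
  colnames(fasc) <- .MUSCLES
  fasc_obs_all <- rowSums(!is.na(fasc))
  out$fasc_count_all8 <- ifelse(fasc_obs_all == 0, NA_integer_,
                                as.integer(rowSums(fasc, na.rm = TRUE)))
  prox <- fasc[, config$proximal_set, drop = FALSE]
  fasc_obs_prox <- rowSums(!is.na(prox))
  out$fasc_count_proximal <- ifelse(fasc_obs_prox == 0, NA_integer_,
                                    as.integer(rowSums(prox, na.rm = TRUE)))
  out$fasc_positive_all8 <- out$fasc_count_all8 >= config$fasc_threshold_all8
  out$fasc_positive_proximal <- out$fasc_count_proximal >= config$fasc_threshold_proximal

  structure(out, class = c("musono_profiles", "data.frame"))
}

#' Classify a single subject record
#'
#' Convenience wrapper around [classify_cohort()] for a one-row cohort.
#'
#' @inheritParams classify_cohort
#' @param record A one-row `musono_cohort`.
#' @return A one-row `musono_profiles`.
#' @export
classify_subject <- function(record, ref, config = rule_config()) {
  stopifnot(nrow(record) == 1)
  classify_cohort(record, ref, config)
}

#' Write classifier profiles to delimited text
#'
#' Booleans are written as `true`/`false`, missing values as empty cells.
#'
#' @param profiles A `musono_profiles`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "musono_profiles"))
  out <- as.data.frame(lapply(profiles, function(x) {
    if (is.logical(x)) ifelse(is.na(x), "", ifelse(x, "true", "false"))
    else .fmt_cell(x)
  }), stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- names(profiles)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
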
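# Cohort-level accuracy report: per-muscle reduced-thickness rates by
# group, the overall rule sensitivities/specificity, and AUCs -- the shape
# of a diagnostic-accuracy results table. Optionally restricted to the
# subset of patients with normal strength on examination (every recorded
# MRC movement equal to 5); controls are always retained in full as the
# comparison population.

.pct <- function(x) 100 * x

.muscle_block <- function(profiles, state) {
  musc <- if (state == "RELAXED") .MUSCLES else .CONTRACTED_MUSCLES
  prefix <- if (state == "RELAXED") "flag_rel_" else "flag_con_"
  groups <- intersect(.GROUPS, unique(profiles$group))
  patient_groups <- setdiff(groups, "CONTROL")
  rows <- lapply(musc, function(m) {
    col <- paste0(prefix, .MUSCLE_COL[m])
    row <- list(muscle = m)
    for (g in groups) {
      f <- profiles[[col]][profiles$group == g]
      n_obs <- sum(!is.na(f))
      row[[g]] <- if (n_obs == 0) NA_real_ else .pct(sum(f == "ABNORMAL",
                                                         na.rm = TRUE) / n_obs)
    }
    # single-muscle binary rule AUC: pooled patient sensitivity vs control FP
    f <- profiles[[col]]
    is_pat <- profiles$group %in% patient_groups & !is.na(f)
    is_con <- profiles$group == "CONTROL" & !is.na(f)
    row$auc <- if (sum(is_pat) > 0 && sum(is_con) > 0) {
      auc_binary(mean(f[is_pat] == "ABNORMAL"), mean(f[is_con] != "ABNORMAL"))
    } else NA_real_
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.overall_rule <- function(profiles, field, positive_groups, negative_groups) {
  present_pos <- intersect(positive_groups, unique(profiles$group))
  present_neg <- intersect(negative_groups, unique(profiles$group))
  usable <- function(gs) {
    any(!is.na(profiles[[field]][profiles$group %in% gs]))
  }
  if (length(present_pos) == 0 || !usable(present_pos)) {
    warning("rule ", field, ": no usable positive-class subjects; ",
            "reporting group rates only", call. = FALSE)
    return(list(per_group = sensitivity_by_group(profiles, field), accuracy = NULL))
  }
  if (length(present_neg) == 0 || !usable(present_neg)) {
    warning("rule ", field, ": no usable negative-class subjects; ",
            "reporting group rates only", call. = FALSE)
    return(list(per_group = sensitivity_by_group(profiles, field), accuracy = NULL))
  }
  acc <- evaluate_rule(profiles, field, present_pos, present_neg)
  list(per_group = acc$per_group_sensitivity, accuracy = acc)
}

#' Diagnostic-accuracy report for a classified cohort
#'
#' Builds the full results table for a cohort and its classifier profiles:
#' percent of subjects with reduced thickness per muscle and group (with a
#' per-muscle binary-rule AUC, patients pooled against controls), the
#' overall relaxed and contracted rule accuracies (any neuromuscular
#' disease vs controls), and both fasciculation criteria (ALS vs everyone
#' else). With `normal_strength_only = TRUE`, patients are restricted to
#' those whose recorded MRC scores are all 5 (at least one movement
#' recorded); controls are kept in full as the comparison population.
#'
#' @param cohort The `musono_cohort` the profiles were computed from.
#' @param profiles The matching `musono_profiles`.
#' @param normal_strength_only Restrict patients to normal-strength subset.
#' @return A `musono_report` list.
#' @export
accuracy_report <- function(cohort, profiles, normal_strength_only = FALSE) {
  stopifnot(inherits(profiles, "musono_profiles"),
            identical(cohort$subject_id, profiles$subject_id))
  if (normal_strength_only) {
    mrc <- as.matrix(cohort[, paste0("mrc_", .MRC_MOVEMENTS)])
    n_rec <- rowSums(!is.na(mrc))
    all5 <- n_rec > 0 & rowSums(mrc == 5, na.rm = TRUE) == n_rec
    keep <- cohort$group == "CONTROL" | all5
    if (!any(keep & cohort$group != "CONTROL")) {
      warning("normal-strength subset contains no patients", call. = FALSE)
    }
    profiles <- profiles[keep, , drop = FALSE]
    cohort <- cohort[keep, , drop = FALSE]
  }
  groups <- intersect(.GROUPS, unique(profiles$group))
  patient_groups <- setdiff(groups, "CONTROL")

  rules <- list(
    relaxed_positive = .overall_rule(profiles, "relaxed_positive",
                                     patient_groups, "CONTROL"),
    contracted_positive = .overall_rule(profiles, "contracted_positive",
                                        patient_groups, "CONTROL"),
    fasc_positive_all8 = .overall_rule(profiles, "fasc_positive_all8",
                                       "ALS", setdiff(groups, "ALS")),
    fasc_positive_proximal = .overall_rule(profiles, "fasc_positive_proximal",
                                           "ALS", setdiff(groups, "ALS"))
  )
  structure(list(
    n_per_group = as.list(table(factor(profiles$group, levels = groups))),
    normal_strength_only = normal_strength_only,
    relaxed_by_muscle = .muscle_block(profiles, "RELAXED"),
    contracted_by_muscle = .muscle_block(profiles, "CONTRACTED"),
    rules = rules
  ), class = "musono_report")
}

#' Serialize a `musono_report` to JSON
#'
#' @param report A `musono_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_report <- function(report, path) {
  stopifnot(inherits(report, "musono_report"))
  payload <- unclass(report)
  payload$rules <- lapply(payload$rules, function(r) {
    list(per_group = r$per_group,
         accuracy = if (is.null(r$accuracy)) NULL else unclass(r$accuracy))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @export
print.musono_report <- function(x, ...) {
  cat("<musono_report>", if (x$normal_strength_only) " (normal-strength subset)",
      "\n  n: ", paste(sprintf("%s=%d", names(x$n_per_group),
                               unlist(x$n_per_group)), collapse = ", "),
      "\n", sep = "")
  for (nm in names(x$rules)) {
    acc <- x$rules[[nm]]$accuracy
    if (is.null(acc)) next
    cat(sprintf("  %-24s Se %.0f%%  Sp %.0f%%  AUC %.2f\n", nm,
                .pct(acc$pooled_sensitivity$proportion),
                .pct(acc$control_specificity$proportion), acc$auc))
  }
  invisible(x)
}
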
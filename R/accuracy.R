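# Diagnostic accuracy of classifier verdicts: per-group sensitivity,
# specificity among negatives, pooled sensitivity, and AUC under three
# estimators. For a single binary decision rule the ROC polygon has one
# interior vertex, so its area is (Se + Sp) / 2 exactly; continuous
# markers use the rank-based (Mann-Whitney) estimator or the binormal
# closed form.

#' Per-group positive-verdict rates
#'
#' Proportion of positive verdicts in each group. For patient groups this
#' is the rule's sensitivity; for CONTROL it is the false-positive rate
#' (specificity = 1 - rate). Subjects with a missing verdict are excluded
#' from both numerator and denominator; groups with no usable verdict are
#' omitted with a warning.
#'
#' @param profiles A `musono_profiles` (or data.frame with a `group` column).
#' @param verdict_field Name of a logical column, e.g. `"relaxed_positive"`.
#' @return data.frame with columns `group`, `n_positive`, `n_total`,
#'   `proportion`.
#' @export
sensitivity_by_group <- function(profiles, verdict_field = "relaxed_positive") {
  stopifnot(verdict_field %in% names(profiles))
  v <- profiles[[verdict_field]]
  if (!is.logical(v)) stop("verdict field must be logical", call. = FALSE)
  groups <- intersect(.GROUPS, unique(profiles$group))
  rows <- lapply(groups, function(g) {
    vg <- v[profiles$group == g]
    n_tot <- sum(!is.na(vg))
    if (n_tot == 0) {
      warning("group ", g, " has no non-missing verdicts; omitted", call. = FALSE)
      return(NULL)
    }
    data.frame(group = g, n_positive = sum(vg, na.rm = TRUE), n_total = n_tot,
               proportion = sum(vg, na.rm = TRUE) / n_tot,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pool per-group sensitivities by group size
#'
#' Case-count-weighted mean, identical to total positives / total cases.
#'
#' @param sensitivities Proportions in `[0, 1]`.
#' @param ns Group sizes (same length).
#' @return Pooled proportion.
#' @export
pool_sensitivity <- function(sensitivities, ns) {
  stopifnot(length(sensitivities) == length(ns), all(ns >= 0), sum(ns) > 0,
            all(sensitivities >= 0 & sensitivities <= 1))
  sum(sensitivities * ns) / sum(ns)
}

#' AUC of a single binary decision rule
#'
#' The ROC curve of a one-threshold rule is the polygon through (0,0),
#' (1 - Sp, Se), (1,1); its trapezoidal area is `(Se + Sp) / 2`.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_binary(1, 1)           # 1
#' auc_binary(0.9486, 0.85)   # 0.8993
auc_binary <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1 | specificity < 0 | specificity > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  (sensitivity + specificity) / 2
}

#' Empirical rank-based AUC
#'
#' Fraction of case-control pairs in which the case score exceeds the
#' control score, ties counted one half (the normalized Mann-Whitney
#' statistic). Orientation is the caller's responsibility: higher scores
#' are assumed more case-like and no automatic flipping is applied, so
#' values below 0.5 are reported as-is.
#'
#' @param scores Numeric marker values.
#' @param labels Logical (or 0/1) case indicators, same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_empirical <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binormal closed-form AUC
#'
#' AUC under Gaussian score distributions in both classes:
#' `pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))`. Useful for
#' computing the ROC area implied by published group means and SDs.
#'
#' @param mu_pos,sd_pos Case mean and SD (sd > 0).
#' @param mu_neg,sd_neg Control mean and SD (sd > 0).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_binormal(2.06, 0.63, 0.88, 1.07)  # 0.83: PNP vs MYO biceps-EDB
auc_binormal <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  if (any(sd_pos <= 0) || any(sd_neg <= 0)) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  stats::pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))
}

#' Evaluate a decision rule or marker against group labels
#'
#' Assembles a full accuracy summary for one verdict field: per-group
#' sensitivities with counts, specificity over the negative class, pooled
#' sensitivity, and the AUC. Boolean verdicts use the binary-threshold
#' identity (`BINARY_IDENTITY`); numeric markers use the empirical
#' rank-based estimator (`EMPIRICAL_RANK`) with no orientation flipping
#' unless `higher_is_positive = FALSE` negates the scores first.
#'
#' @param profiles A `musono_profiles`.
#' @param verdict_field Column name of the verdict (logical) or marker
#'   (numeric).
#' @param positive_groups,negative_groups Disjoint, non-empty sets of
#'   diagnosis groups.
#' @param higher_is_positive For numeric markers: whether larger values
#'   indicate the positive class (default TRUE).
#' @return A `musono_accuracy` list with all underlying counts.
#' @export
evaluate_rule <- function(profiles, verdict_field,
                          positive_groups, negative_groups = "CONTROL",
                          higher_is_positive = TRUE) {
  stopifnot(verdict_field %in% names(profiles))
  if (length(intersect(positive_groups, negative_groups)) > 0) {
    stop("positive and negative classes overlap", call. = FALSE)
  }
  if (length(positive_groups) == 0 || length(negative_groups) == 0) {
    stop("both classes must name at least one group", call. = FALSE)
  }
  v <- profiles[[verdict_field]]
  pos <- profiles$group %in% positive_groups & !is.na(v)
  neg <- profiles$group %in% negative_groups & !is.na(v)
  if (sum(pos) == 0) stop("positive class has no usable subjects", call. = FALSE)
  if (sum(neg) == 0) stop("negative class has no usable subjects", call. = FALSE)

  if (is.logical(v)) {
    per_group <- sensitivity_by_group(
      profiles[profiles$group %in% c(positive_groups, negative_groups), ,
               drop = FALSE],
      verdict_field)
    n_fp <- sum(v[neg]); n_neg <- sum(neg)
    n_tp <- sum(v[pos]); n_pos <- sum(pos)
    se <- n_tp / n_pos
    sp <- 1 - n_fp / n_neg
    auc <- auc_binary(se, sp)
    auc_method <- "BINARY_IDENTITY"
  } else if (is.numeric(v)) {
    scores <- if (higher_is_positive) v else -v
    lab <- rep(NA, nrow(profiles))
    lab[pos] <- TRUE; lab[neg] <- FALSE
    auc <- auc_empirical(scores, lab)
    auc_method <- "EMPIRICAL_RANK"
    per_group <- NULL
    n_tp <- NA_integer_; n_fp <- NA_integer_
    n_pos <- sum(pos); n_neg <- sum(neg)
    se <- NA_real_; sp <- NA_real_
  } else {
    stop("verdict field must be logical or numeric", call. = FALSE)
  }

  structure(list(
    rule_name = verdict_field,
    positive_groups = positive_groups, negative_groups = negative_groups,
    per_group_sensitivity = per_group,
    control_specificity = list(n_false_positive = n_fp, n_negative = n_neg,
                               proportion = sp),
    pooled_sensitivity = list(n_true_positive = n_tp, n_case = n_pos,
                              proportion = se),
    auc = auc, auc_method = auc_method
  ), class = "musono_accuracy")
}

#' Serialize a `musono_accuracy` to JSON with all counts
#'
#' @param acc A `musono_accuracy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_accuracy <- function(acc, path) {
  stopifnot(inherits(acc, "musono_accuracy"))
  jsonlite::write_json(unclass(acc), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' @export
print.musono_accuracy <- function(x, ...) {
  cat("<musono_accuracy> rule ", x$rule_name, "\n", sep = "")
  if (!is.null(x$per_group_sensitivity)) {
    p <- x$per_group_sensitivity
    cat(sprintf("  %s: %d/%d = %.0f%%\n", p$group, p$n_positive, p$n_total,
                100 * p$proportion), sep = "")
  }
  if (!is.na(x$pooled_sensitivity$proportion)) {
    cat(sprintf("  pooled sensitivity %.1f%%, specificity %.1f%%\n",
                100 * x$pooled_sensitivity$proportion,
                100 * x$control_specificity$proportion))
  }
  cat(sprintf("  AUC = %.2f (%s)\n", x$auc, x$auc_method))
  invisible(x)
}
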
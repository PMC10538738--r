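# Fixture builders shared across test files. Everything is constructed in
# code; no data files.

# data.frame with the full cohort schema, all optional fields missing
blank_rows <- function(n, group = "CONTROL", age = 50, sex = "F") {
  cols <- stats::setNames(rep(list(rep(NA_real_, n)), length(cohort_columns())),
                          cohort_columns())
  df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  df$subject_id <- sprintf("S%03d", seq_len(n))
  df$group <- rep(group, length.out = n)
  df$age <- rep(age, length.out = n)
  df$sex <- rep(sex, length.out = n)
  df$side <- rep("RIGHT", length.out = n)
  df$clinical_scale_name <- rep(NA_character_, n)
  df
}

make_cohort <- function(n = 1, ..., group = "CONTROL", age = 50, sex = "F") {
  df <- blank_rows(n, group = group, age = age, sex = sex)
  mods <- list(...)
  for (nm in names(mods)) df[[nm]] <- mods[[nm]]
  as_cohort(df, provenance = "test fixture")
}

# reference with a single all-adult stratum per sex and fixed cutoffs;
# cutoffs: named numeric vector "rel_biceps" etc., or a single default
fixed_reference <- function(cutoffs = NULL, default_cutoff = 1) {
  strata <- data.frame(sex = c("F", "M"), age_low = 18, age_high = 90,
                       stringsAsFactors = FALSE)
  cells <- expand.grid(muscle = muscles(), state = c("RELAXED", "CONTRACTED"),
                       stratum_index = 1:2, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  cells <- cells[cells$state == "RELAXED" |
                   cells$muscle %in% contracted_muscles(), ]
  key <- musono:::thick_col(cells$muscle, cells$state)
  cells$cutoff_cm <- default_cutoff
  if (!is.null(cutoffs)) {
    hit <- key %in% names(cutoffs)
    cells$cutoff_cm[hit] <- unname(cutoffs[key[hit]])
  }
  cells$n <- 10L
  cells$cell_method <- "EMPIRICAL_QUANTILE"
  structure(list(percentile = 5, method = "EMPIRICAL_QUANTILE",
                 min_stratum_n = 8, strata = strata, cutoffs = cells),
            class = "musono_reference")
}

# strip provenance/class for field-for-field comparison
plain <- function(x) {
  attr(x, "provenance") <- NULL
  class(x) <- "data.frame"
  rownames(x) <- NULL
  x
}

# brute-force pair-counting AUC oracle (independent of the rank path)
auc_pairs_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  cases <- scores[labels]
  ctrls <- scores[!labels]
  total <- 0
  for (x in cases) for (y in ctrls) {
    total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  total / (length(cases) * length(ctrls))
}
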
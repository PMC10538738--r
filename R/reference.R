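# Age/sex-stratified normative thickness cutoffs built from healthy
# controls. A muscle is later called "reduced" when its thickness is
# strictly below the stratum's cutoff (default: 5th percentile).

#' Default age/sex strata
#'
#' One stratum per sex and age bin. Bins default to [18,40), [40,60),
#' [60,90) years: a common stratification in sonographic normative work
#' that keeps strata adequately populated in a control cohort of ~65.
#'
#' @param age_breaks Increasing numeric vector of bin edges; bin i is
#'   `[age_breaks[i], age_breaks[i+1])` (inclusive low, exclusive high).
#' @return data.frame with columns `sex`, `age_low`, `age_high`.
#' @export
default_strata <- function(age_breaks = c(18, 40, 60, 90)) {
  stopifnot(length(age_breaks) >= 2, !is.unsorted(age_breaks, strictly = TRUE))
  k <- length(age_breaks) - 1L
  data.frame(sex = rep(.SEXES, each = k),
             age_low = rep(age_breaks[-length(age_breaks)], 2),
             age_high = rep(age_breaks[-1], 2),
             stringsAsFactors = FALSE)
}

.check_strata <- function(strata) {
  stopifnot(is.data.frame(strata),
            all(c("sex", "age_low", "age_high") %in% names(strata)))
  if (any(!strata$sex %in% .SEXES)) stop("strata sex must be F or M", call. = FALSE)
  if (any(strata$age_low >= strata$age_high)) {
    stop("strata must have age_low < age_high", call. = FALSE)
  }
  for (s in unique(strata$sex)) {
    b <- strata[strata$sex == s, ]
    b <- b[order(b$age_low), ]
    if (nrow(b) > 1 && any(b$age_high[-nrow(b)] > b$age_low[-1] + 1e-9)) {
      stop("strata for sex ", s, " overlap", call. = FALSE)
    }
  }
  strata
}

# index of the stratum containing each (sex, age); NA when uncovered.
# bin edges are inclusive-low, exclusive-high.
.stratum_index <- function(strata, sex, age) {
  idx <- rep(NA_integer_, length(sex))
  for (i in seq_len(nrow(strata))) {
    hit <- sex == strata$sex[i] & age >= strata$age_low[i] & age < strata$age_high[i]
    idx[hit & !is.na(hit)] <- i
  }
  idx
}

.gaussian_cutoff <- function(vals, percentile) {
  mean(vals) + stats::qnorm(percentile / 100) * stats::sd(vals)
}

#' Build a normative thickness reference from healthy controls
#'
#' For every (muscle, state, sex, age-stratum) cell with data, estimates the
#' thickness percentile cutoff (default: 5th) from control measurements.
#' `EMPIRICAL_QUANTILE` uses the type-7 linear-interpolation quantile
#' (order-statistic position `p*(n-1)+1`); `GAUSSIAN_PARAMETRIC` uses
#' `mean + qnorm(p/100) * sd` (for the 5th percentile, mean - 1.6449 sd).
#' Cells with fewer than `min_stratum_n` observations fall back to the
#' Gaussian form with a warning, since thin strata make empirical tail
#' quantiles unstable.
#'
#' @param controls A `musono_cohort` containing only CONTROL rows.
#' @param strata Stratum table as from [default_strata()].
#' @param percentile Percentile in (0, 100); default 5.
#' @param method `"EMPIRICAL_QUANTILE"` (default) or `"GAUSSIAN_PARAMETRIC"`.
#' @param min_stratum_n Minimum per-cell n for the empirical quantile
#'   (default 8).
#' @return A `musono_reference` object.
#' @export
build_reference <- function(controls, strata = default_strata(), percentile = 5,
                            method = c("EMPIRICAL_QUANTILE", "GAUSSIAN_PARAMETRIC"),
                            min_stratum_n = 8) {
  method <- match.arg(method)
  stopifnot(inherits(controls, "musono_cohort"))
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must lie strictly between 0 and 100", call. = FALSE)
  }
  if (nrow(controls) == 0) stop("no control records supplied", call. = FALSE)
  if (any(controls$group != "CONTROL")) {
    stop("reference building accepts CONTROL rows only; found ",
         paste(unique(setdiff(controls$group, "CONTROL")), collapse = ", "),
         call. = FALSE)
  }
  strata <- .check_strata(strata)

  idx <- .stratum_index(strata, controls$sex, controls$age)
  if (anyNA(idx)) {
    stop("control ages outside configured strata: subject(s) ",
         paste(controls$subject_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  stratum_label <- function(i) {
    sprintf("%s [%g,%g)", strata$sex[i], strata$age_low[i], strata$age_high[i])
  }
  thin <- which(tabulate(idx, nbins = nrow(strata)) < 2)
  if (length(thin) > 0) {
    stop("too few controls in stratum ",
         paste(vapply(thin, stratum_label, character(1)), collapse = "; "),
         call. = FALSE)
  }

  cells <- expand.grid(muscle = .MUSCLES, state = .STATES,
                       stratum_index = seq_len(nrow(strata)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[cells$state == "RELAXED" | cells$muscle %in% .CONTRACTED_MUSCLES, ]

  fallbacks <- character(0)
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    m <- cells$muscle[r]; st <- cells$state[r]; si <- cells$stratum_index[r]
    vals <- controls[[thick_col(m, st)]][idx == si]
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    if (n < 2) return(NULL)  # unpopulated cell
    cell_method <- method
    if (method == "EMPIRICAL_QUANTILE" && n < min_stratum_n) {
      cell_method <- "GAUSSIAN_PARAMETRIC"
      fallbacks <<- c(fallbacks, sprintf("%s/%s in %s (n=%d)", m, st,
                                         stratum_label(si), n))
    }
    cutoff <- if (cell_method == "EMPIRICAL_QUANTILE") {
      stats::quantile(vals, percentile / 100, type = 7, names = FALSE)
    } else {
      .gaussian_cutoff(vals, percentile)
    }
    if (cutoff <= 0) {
      warning("non-positive ", cell_method, " cutoff for ", m, "/", st, " in ",
              stratum_label(si), "; floored at 0.001 cm", call. = FALSE)
      cutoff <- 0.001
    }
    data.frame(muscle = m, state = st, stratum_index = si,
               cutoff_cm = cutoff, n = n, cell_method = cell_method,
               stringsAsFactors = FALSE)
  })
  cutoffs <- do.call(rbind, rows)
  if (is.null(cutoffs) || nrow(cutoffs) == 0) {
    stop("no populated reference cells", call. = FALSE)
  }
  if (length(fallbacks) > 0) {
    warning(length(fallbacks), " cell(s) below min_stratum_n = ", min_stratum_n,
            " fell back to GAUSSIAN_PARAMETRIC: ",
            paste(utils::head(fallbacks, 5), collapse = "; "),
            if (length(fallbacks) > 5) "; ...", call. = FALSE)
  }
  rownames(cutoffs) <- NULL
  structure(list(percentile = percentile, method = method,
                 min_stratum_n = min_stratum_n, strata = strata,
                 cutoffs = cutoffs),
            class = "musono_reference")
}

#' Look up a normative cutoff
#'
#' Returns the thickness cutoff (cm) for one muscle, state, sex and age.
#' Ages outside the configured strata raise an error (no extrapolation);
#' bin edges are inclusive at the low edge.
#'
#' @param ref A `musono_reference`.
#' @param muscle One of [muscles()].
#' @param state `"RELAXED"` or `"CONTRACTED"`.
#' @param sex `"F"` or `"M"`.
#' @param age Age in years.
#' @return Cutoff in cm.
#' @export
lookup_cutoff <- function(ref, muscle, state, sex, age) {
  stopifnot(inherits(ref, "musono_reference"))
  muscle <- match.arg(muscle, .MUSCLES)
  state <- match.arg(state, .STATES)
  sex <- match.arg(sex, .SEXES)
  if (state == "CONTRACTED" && !(muscle %in% .CONTRACTED_MUSCLES)) {
    stop(muscle, " is not assessed in the contracted state", call. = FALSE)
  }
  si <- .stratum_index(ref$strata, sex, age)
  if (is.na(si)) {
    stop("age ", age, " (sex ", sex, ") outside configured strata; ",
         "no extrapolation is performed", call. = FALSE)
  }
  hit <- ref$cutoffs$muscle == muscle & ref$cutoffs$state == state &
    ref$cutoffs$stratum_index == si
  if (!any(hit)) {
    stop("no populated cutoff for ", muscle, "/", state, " in stratum ",
         sprintf("%s [%g,%g)", sex, ref$strata$age_low[si], ref$strata$age_high[si]),
         call. = FALSE)
  }
  ref$cutoffs$cutoff_cm[hit]
}

#' Serialize a normative reference to JSON
#'
#' @param ref A `musono_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_reference <- function(ref, path) {
  stopifnot(inherits(ref, "musono_reference"))
  payload <- list(
    percentile = ref$percentile, method = ref$method,
    min_stratum_n = ref$min_stratum_n,
    strata = ref$strata,
    cutoffs = ref$cutoffs
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Load a normative reference from JSON, re-validating all invariants
#'
#' @param path Path to a JSON file written by [save_reference()].
#' @return A `musono_reference`.
#' @export
load_reference <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  strata <- .check_strata(as.data.frame(raw$strata))
  cutoffs <- as.data.frame(raw$cutoffs)
  need <- c("muscle", "state", "stratum_index", "cutoff_cm", "n")
  if (!all(need %in% names(cutoffs))) stop("malformed reference JSON", call. = FALSE)
  if (is.null(cutoffs$cell_method)) cutoffs$cell_method <- raw$method
  if (any(cutoffs$cutoff_cm <= 0)) stop("reference has non-positive cutoffs", call. = FALSE)
  if (any(!cutoffs$muscle %in% .MUSCLES) || any(!cutoffs$state %in% .STATES)) {
    stop("reference has unknown muscle or state labels", call. = FALSE)
  }
  bad <- cutoffs$state == "CONTRACTED" & !(cutoffs$muscle %in% .CONTRACTED_MUSCLES)
  if (any(bad)) {
    stop("contracted cutoff present for non-contracted-capable muscle", call. = FALSE)
  }
  if (any(cutoffs$stratum_index < 1 | cutoffs$stratum_index > nrow(strata))) {
    stop("cutoff stratum_index out of range", call. = FALSE)
  }
  if (raw$percentile <= 0 || raw$percentile >= 100) {
    stop("reference percentile out of range", call. = FALSE)
  }
  structure(list(percentile = raw$percentile, method = raw$method,
                 min_stratum_n = raw$min_stratum_n %||% 8,
                 strata = strata, cutoffs = cutoffs),
            class = "musono_reference")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.musono_reference <- function(x, ...) {
  cat("<musono_reference> percentile ", x$percentile, ", method ", x$method,
      "\n  ", nrow(x$strata), " strata, ", nrow(x$cutoffs),
      " populated cutoff cells\n", sep = "")
  invisible(x)
}
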
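# Cohort data model: one row per subject, fixed column schema, strict
# validation. Missing cells are NA throughout -- never zero.

#' Cohort file column schema
#'
#' Fixed column order for subject-level cohort tables: identifiers and
#' demographics, relaxed thickness for the eight muscles (cm), contracted
#' thickness for the four contracted-capable muscles (cm), per-muscle
#' fasciculation presence observed in a 15-second scan window (0/1),
#' ten MRC movement scores, and an optional clinical scale.
#'
#' @return Character vector of the 39 column names.
#' @export
cohort_columns <- function() {
  c("subject_id", "group", "age", "sex", "bmi", "disease_duration", "side",
    thick_col(.MUSCLES, "RELAXED"),
    thick_col(.CONTRACTED_MUSCLES, "CONTRACTED"),
    fasc_col(.MUSCLES),
    paste0("mrc_", .MRC_MOVEMENTS),
    "clinical_scale_name", "clinical_scale_value")
}

.NUMERIC_COLS <- function() {
  c("age", "bmi", "disease_duration",
    thick_col(.MUSCLES, "RELAXED"),
    thick_col(.CONTRACTED_MUSCLES, "CONTRACTED"),
    paste0("mrc_", .MRC_MOVEMENTS),
    "clinical_scale_value")
}

.THICK_COLS <- function() {
  c(thick_col(.MUSCLES, "RELAXED"), thick_col(.CONTRACTED_MUSCLES, "CONTRACTED"))
}

# collect validation problems as "row <i>, column <name>: <why>"
.problem <- function(rows, col, why) {
  sprintf("row %s, column '%s': %s", rows, col, why)
}

.parse_numeric <- function(x, col, problems) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad) > 0) {
    problems$add(.problem(bad, col, sprintf("not a number ('%s')", x[bad])))
  }
  out[x == "" | is.na(x)] <- NA_real_
  out
}

.problem_collector <- function() {
  msgs <- character(0)
  list(add = function(m) msgs <<- c(msgs, m),
       all = function() msgs)
}

#' Validate and class a subject-level cohort table
#'
#' Checks every invariant of the cohort schema: known group/sex/side labels,
#' positive ages, non-negative thicknesses, fasciculation flags in
#' \{0, 1, NA\}, MRC scores on the half-point 0-5 grid, unique subject ids,
#' and absent disease duration for controls. A single consolidated warning
#' is emitted when contracted thickness falls below relaxed thickness for
#' the same muscle (observational noise; the row is kept).
#'
#' @param df A data.frame with the columns of [cohort_columns()].
#' @param provenance Free-text source tag stored on the returned object.
#' @return The validated table, classed `musono_cohort`.
#' @export
as_cohort <- function(df, provenance = "in-memory") {
  cols <- cohort_columns()
  if (!identical(names(df), cols)) {
    missing <- setdiff(cols, names(df))
    extra   <- setdiff(names(df), cols)
    stop("malformed header: ",
         if (length(missing)) paste0("missing columns [",
                                     paste(missing, collapse = ", "), "] "),
         if (length(extra)) paste0("unexpected columns [",
                                   paste(extra, collapse = ", "), "] "),
         if (!length(missing) && !length(extra)) "columns out of order",
         call. = FALSE)
  }
  problems <- .problem_collector()
  n <- nrow(df)

  chr <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & x == ""] <- NA_character_
    x
  }
  df$subject_id <- chr(df$subject_id)
  df$group <- chr(df$group)
  df$sex <- chr(df$sex)
  df$side <- chr(df$side)
  df$clinical_scale_name <- chr(df$clinical_scale_name)

  for (col in .NUMERIC_COLS()) {
    df[[col]] <- .parse_numeric(as.character(df[[col]]), col, problems)
  }
  for (col in fasc_col(.MUSCLES)) {
    raw <- if (is.logical(df[[col]])) as.character(as.integer(df[[col]]))
           else as.character(df[[col]])
    raw[is.na(raw) | raw == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & (is.na(num) | !(num %in% c(0, 1))))
    if (length(bad) > 0) {
      problems$add(.problem(bad, col, sprintf("must be 0, 1 or empty ('%s')", raw[bad])))
    }
    df[[col]] <- num == 1
  }

  if (n > 0) {
    bad <- which(is.na(df$subject_id))
    if (length(bad)) problems$add(.problem(bad, "subject_id", "empty"))
    dup <- which(duplicated(df$subject_id) & !is.na(df$subject_id))
    if (length(dup)) {
      problems$add(.problem(dup, "subject_id",
                            sprintf("duplicate id '%s'", df$subject_id[dup])))
    }
    bad <- which(!is.na(df$group) & !(df$group %in% .GROUPS))
    if (length(bad)) {
      problems$add(.problem(bad, "group",
                            sprintf("unknown group label '%s'", df$group[bad])))
    }
    bad <- which(is.na(df$group))
    if (length(bad)) problems$add(.problem(bad, "group", "missing"))
    bad <- which(is.na(df$age) | df$age <= 0)
    if (length(bad)) problems$add(.problem(bad, "age", "must be a positive number"))
    bad <- which(!is.na(df$sex) & !(df$sex %in% .SEXES))
    if (length(bad)) problems$add(.problem(bad, "sex", "must be F or M"))
    bad <- which(is.na(df$sex))
    if (length(bad)) problems$add(.problem(bad, "sex", "missing"))
    bad <- which(!is.na(df$side) & !(df$side %in% .SIDES))
    if (length(bad)) problems$add(.problem(bad, "side", "must be RIGHT or LEFT"))
    bad <- which(!is.na(df$bmi) & df$bmi <= 0)
    if (length(bad)) problems$add(.problem(bad, "bmi", "must be positive"))
    bad <- which(!is.na(df$disease_duration) & df$disease_duration < 0)
    if (length(bad)) problems$add(.problem(bad, "disease_duration", "must be non-negative"))
    bad <- which(df$group %in% "CONTROL" & !is.na(df$disease_duration))
    if (length(bad)) {
      problems$add(.problem(bad, "disease_duration", "must be absent for CONTROL"))
    }
    for (col in .THICK_COLS()) {
      bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
      if (length(bad)) {
        problems$add(.problem(bad, col,
                              sprintf("negative thickness (%g cm)", df[[col]][bad])))
      }
    }
    # decimals are admitted (plus/minus grades, group-mean records)
    for (col in paste0("mrc_", .MRC_MOVEMENTS)) {
      v <- df[[col]]
      bad <- which(!is.na(v) & (v < 0 | v > 5))
      if (length(bad)) {
        problems$add(.problem(bad, col, "MRC score must lie in [0, 5]"))
      }
    }
  }

  msgs <- problems$all()
  if (length(msgs) > 0) {
    stop("invalid cohort table (", length(msgs), " problem(s)):\n  ",
         paste(utils::head(msgs, 20), collapse = "\n  "),
         if (length(msgs) > 20) "\n  ...", call. = FALSE)
  }

  # contracted < relaxed is physiologically odd but observed; warn once
  n_flip <- 0L
  for (m in .CONTRACTED_MUSCLES) {
    rel <- df[[thick_col(m, "RELAXED")]]
    con <- df[[thick_col(m, "CONTRACTED")]]
    n_flip <- n_flip + sum(!is.na(rel) & !is.na(con) & con < rel)
  }
  if (n_flip > 0) {
    warning(n_flip, " muscle observation(s) have contracted thickness below ",
            "relaxed thickness (kept; observational noise)", call. = FALSE)
  }

  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("musono_cohort", "data.frame"))
}

#' Read a subject-level cohort file
#'
#' Reads a UTF-8 delimited text file (comma by default; tab accepted) with
#' the fixed column schema of [cohort_columns()] and validates it via
#' [as_cohort()]. Empty cells become missing values, never zeros; every
#' malformed input is rejected with row/column coordinates.
#'
#' @param path Path to the cohort file.
#' @param sep Field separator; `NULL` (default) sniffs comma vs tab from
#'   the header line.
#' @return A validated `musono_cohort`.
#' @export
read_cohort <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          colClasses = "character", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = NULL,
                          comment.char = "", blank.lines.skip = TRUE)
  as_cohort(df, provenance = path)
}

.fmt_cell <- function(x) {
  if (is.logical(x)) {
    out <- ifelse(is.na(x), "", ifelse(x, "1", "0"))
  } else if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "" else format(v, digits = 15, trim = TRUE, scientific = FALSE)
    }, character(1))
  } else {
    out <- ifelse(is.na(x), "", as.character(x))
  }
  out
}

#' Write a cohort table to delimited text
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(t, f))` reproduces
#' `t` field for field, including missing-value patterns.
#'
#' @param table A `musono_cohort`.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "musono_cohort"))
  out <- as.data.frame(lapply(table, .fmt_cell), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(table)
  for (col in names(out)) {
    if (any(grepl(sep, out[[col]], fixed = TRUE))) {
      stop("field in column '", col, "' contains the separator; refusing to write",
           call. = FALSE)
    }
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' @export
print.musono_cohort <- function(x, ...) {
  counts <- table(factor(x$group, levels = .GROUPS))
  cat("<musono_cohort> ", nrow(x), " subjects (",
      paste(sprintf("%s=%d", names(counts), as.integer(counts)), collapse = ", "),
      ")\n  provenance: ", attr(x, "provenance"), "\n", sep = "")
  invisible(x)
}
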
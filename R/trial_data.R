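# Domain types and file I/O for per-subject trial records.

pp_fields <- c("subject_id", "study", "arm", "marijuana_days", "tes", "tes_max")
pp_study_levels <- c("historical", "current")
pp_arm_levels <- c("placebo", "active")

#' Treatment Effectiveness Score from an ordered urine panel
#'
#' The TES assigns one point for each cocaine-negative urine sample and no
#' points for positive or missing samples, so a subject followed for `k`
#' scheduled collections scores in `[0, k]`.
#'
#' @param urine_results Character vector with entries `"negative"`,
#'   `"positive"` or `"missing"`, in collection order (the score is in fact
#'   permutation-invariant).
#' @return Integer count of negative samples.
#' @examples
#' compute_tes(c("negative", "positive", "missing", "negative"))
#' @export
compute_tes <- function(urine_results) {
  if (length(urine_results) == 0) {
    return(0L)
  }
  if (!is.character(urine_results)) {
    pp_stop("urine results must be a character vector")
  }
  bad <- !(urine_results %in% c("negative", "positive", "missing"))
  if (any(bad)) {
    i <- which(bad)[1]
    pp_stop(sprintf(
      "unrecognized urine result '%s' at position %d", urine_results[i], i
    ))
  }
  sum(urine_results == "negative")
}

# Per-row invariant check; returns "" for valid rows, else a reason.
row_problems <- function(df) {
  reason <- character(nrow(df))
  flag <- function(bad, why) {
    ifelse(bad & reason == "", why, reason)
  }
  na_any <- Reduce(`|`, lapply(df[pp_fields], is.na))
  reason <- flag(na_any, "missing value")
  reason <- flag(!df$study %in% pp_study_levels & reason == "",
                 "study not in {historical, current}")
  reason <- flag(!df$arm %in% pp_arm_levels & reason == "",
                 "arm not in {placebo, active}")
  num_bad <- !is_count(df$marijuana_days) | df$marijuana_days > 30
  reason <- flag(num_bad & reason == "", "marijuana_days outside 0..30")
  reason <- flag((!is_count(df$tes_max, lo = 1)) & reason == "",
                 "tes_max must be a positive integer")
  reason <- flag((!is_count(df$tes) | df$tes > df$tes_max) & reason == "",
                 "tes outside 0..tes_max")
  reason
}

#' Construct a validated trial dataset
#'
#' A `trial_dataset` is a tibble of complete subject records with columns
#' `subject_id`, `study` (`"historical"`/`"current"`), `arm`
#' (`"placebo"`/`"active"`), `marijuana_days` (integer days of use in the
#' past 30), `tes` (count of cocaine-negative urines) and `tes_max` (the
#' maximum attainable score for that subject's study).
#'
#' @param records Data frame with the six required columns.
#' @param label Short label for reports.
#' @return A `trial_dataset` tibble.
#' @export
trial_dataset <- function(records, label = "dataset") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(pp_fields, names(records))
  if (length(missing_cols)) {
    pp_stop(paste("missing required column(s):",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0) {
    pp_stop("a trial dataset must contain at least one record")
  }
  records$subject_id <- as.character(records$subject_id)
  for (col in c("marijuana_days", "tes", "tes_max")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }
  bad <- row_problems(records)
  if (any(bad != "")) {
    i <- which(bad != "")[1]
    pp_stop(sprintf("invalid record %d (%s): %s", i, records$subject_id[i], bad[i]))
  }
  for (col in c("marijuana_days", "tes", "tes_max")) {
    records[[col]] <- as.integer(records[[col]])
  }
  out <- tibble::as_tibble(records[pp_fields])
  attr(out, "label") <- label
  class(out) <- c("trial_dataset", class(out))
  out
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset '%s': %d records (%d placebo / %d active)>\n",
              attr(x, "label"), nrow(x),
              sum(x$arm == "placebo"), sum(x$arm == "active")))
  NextMethod()
}

#' Concatenate trial datasets
#'
#' @param ... `trial_dataset` objects.
#' @param label Label for the combined dataset.
#' @export
bind_trials <- function(..., label = "combined") {
  parts <- list(...)
  df <- do.call(rbind, lapply(parts, function(d) as.data.frame(d[pp_fields])))
  trial_dataset(df, label = label)
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("\t", first)) "\t" else ","
}

#' Read a trial dataset from a delimited text file
#'
#' Reads a comma- (default) or tab-delimited file with a header row, binds
#' arbitrary column headers to the required fields through `mapping`, and
#' applies a complete-case policy: rows with missing cells or invariant
#' violations are dropped with a warning naming them, never silently.
#'
#' @param path Path to the file.
#' @param mapping Named character vector mapping required field names to
#'   column headers in the file, e.g. `c(tes = "score")`.  Unmapped fields
#'   default to their own names.
#' @param delim Field delimiter; guessed from the first line when `NULL`.
#' @param label Dataset label; defaults to the file name.
#' @return A `trial_dataset`; the number of dropped rows is available as
#'   `attr(x, "n_dropped")`.
#' @export
read_dataset <- function(path, mapping = NULL, delim = NULL, label = NULL) {
  if (!file.exists(path)) {
    pp_stop(paste("file not found:", path), class = "pp_io_error")
  }
  if (is.null(delim)) delim <- sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  cols <- setNames(pp_fields, pp_fields)
  if (!is.null(mapping)) {
    unknown <- setdiff(names(mapping), pp_fields)
    if (length(unknown)) {
      pp_stop(paste("mapping refers to unknown field(s):",
                    paste(unknown, collapse = ", ")))
    }
    cols[names(mapping)] <- mapping
  }
  absent <- cols[!cols %in% names(raw)]
  if (length(absent)) {
    pp_stop(sprintf("column(s) not found in %s: %s", path,
                    paste(absent, collapse = ", ")))
  }
  df <- as.data.frame(raw[unname(cols)], stringsAsFactors = FALSE)
  names(df) <- pp_fields
  for (col in c("marijuana_days", "tes", "tes_max")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  problems <- row_problems(df)
  drop <- problems != ""
  if (all(drop)) {
    pp_stop(paste("zero valid rows in", path))
  }
  if (any(drop)) {
    shown <- head(which(drop), 5)
    warning(sprintf(
      "dropped %d invalid row(s) from %s [row %s]", sum(drop), path,
      paste(sprintf("%d: %s", shown, problems[shown]), collapse = "; ")
    ), call. = FALSE)
  }
  out <- trial_dataset(df[!drop, , drop = FALSE],
                       label = label %||% basename(path))
  attr(out, "n_dropped") <- sum(drop)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trial dataset to a delimited text file
#'
#' Counts are serialized as plain integers so that
#' `read_dataset(write_dataset(d))` reproduces `d` field-for-field.
#'
#' @param dataset A `trial_dataset`.
#' @param path Destination path.
#' @param delim Field delimiter (`","` or `"\t"`).
#' @export
write_dataset <- function(dataset, path, delim = ",") {
  if (!inherits(dataset, "trial_dataset") || nrow(dataset) == 0) {
    pp_stop("write_dataset requires a non-empty trial_dataset")
  }
  df <- as.data.frame(dataset[pp_fields])
  tryCatch(
    readr::write_delim(df, path, delim = delim),
    error = function(e) {
      pp_stop(paste("cannot write", path, ":", conditionMessage(e)),
              class = "pp_io_error")
    }
  )
  invisible(path)
}

# Design-matrix view used by the likelihood and the sampler.
as_design <- function(dataset, offset = FALSE) {
  med <- as.numeric(dataset$arm == "active")
  list(
    y = as.numeric(dataset$tes),
    med = med,
    mj = as.numeric(dataset$marijuana_days),
    off = if (offset) log(as.numeric(dataset$tes_max)) else rep(0, nrow(dataset))
  )
}
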
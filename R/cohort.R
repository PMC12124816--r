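#' Column schema for patient tables
#'
#' Declares how the columns of a delimited patient table map onto the
#' canonical field names used throughout the package, and how hormone-receptor
#' status arrives (raw immunohistochemistry percentages or a precomputed
#' positive/negative flag).
#'
#' Canonical fields: \code{patient_id}, \code{age} (years), \code{bmi}
#' (kg/m2), \code{tumor_size} (mm), \code{sbr_grade} (1--3),
#' \code{n_nodes} (involved lymph nodes), \code{er_percent} and
#' \code{pr_percent} (\% stained cells) or \code{hr_positive} (0/1),
#' \code{hemoglobin} (g/dL), \code{lymphocytes} (G/L),
#' \code{has_comorbidity}, \code{received_chemo}, \code{followup_months},
#' \code{death}, \code{relapse}.
#'
#' @param ... named overrides, e.g. \code{age = "age_at_dx"}.
#' @param hr_mode \code{"percent"} (default) if ER/PR arrive as percentages,
#'   \code{"flag"} if a precomputed \code{hr_positive} column is supplied.
#' @return an object of class \code{"cohort_schema"}.
#' @export
cohort_schema <- function(..., hr_mode = c("percent", "flag")) {
  hr_mode <- match.arg(hr_mode)
  fields <- c("patient_id", "age", "bmi", "tumor_size", "sbr_grade",
              "n_nodes", "er_percent", "pr_percent", "hr_positive",
              "hemoglobin", "lymphocytes", "has_comorbidity",
              "received_chemo", "followup_months", "death", "relapse",
              "true_cluster")
  map <- stats::setNames(as.list(fields), fields)
  dots <- list(...)
  bad <- setdiff(names(dots), fields)
  if (length(bad))
    stop_oncotwin("unknown schema field(s): ", paste(bad, collapse = ", "),
                  class = "oncotwin_schema_error")
  map[names(dots)] <- dots
  structure(list(map = map, hr_mode = hr_mode), class = "cohort_schema")
}

# source fields for the 9 predictors, depending on HR coding
predictor_source_fields <- function(schema) {
  hr <- if (schema$hr_mode == "percent") c("er_percent", "pr_percent") else "hr_positive"
  c("age", "bmi", "tumor_size", "sbr_grade", "n_nodes", hr,
    "hemoglobin", "lymphocytes", "has_comorbidity")
}

MISSING_MARKERS <- c("", "na", "nan")

parse_numeric <- function(x) {
  x <- trimws(x)
  x[tolower(x) %in% MISSING_MARKERS] <- NA
  suppressWarnings(as.numeric(x))
}

parse_logical <- function(x) {
  x <- tolower(trimws(x))
  x[x %in% MISSING_MARKERS] <- NA
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read a patient cohort from a delimited text file
#'
#' Reads one patient per row, renames columns to the canonical schema and
#' parses values; unparseable or marked-missing cells (empty, \code{NA},
#' \code{NaN}, case-insensitive) become \code{NA}.  Row count is preserved.
#'
#' @param path path to a delimited text file with a header row.
#' @param schema a \code{\link{cohort_schema}}.
#' @param sep field separator (default comma).
#' @return a \code{data.frame} with canonical columns, one row per patient.
#' @export
read_cohort <- function(path, schema = cohort_schema(), sep = ",") {
  if (!file.exists(path))
    stop_oncotwin("file not found: ", path, class = "oncotwin_io_error")
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0)
    stop_oncotwin("empty cohort file: ", path, class = "oncotwin_empty_error")
  mandatory <- c(predictor_source_fields(schema), "followup_months", "death")
  for (f in mandatory) {
    src <- schema$map[[f]]
    if (!src %in% names(raw))
      stop_oncotwin("mandatory column missing: '", src, "' (field ", f, ")",
                    class = "oncotwin_schema_error")
  }
  as_cohort_df(raw, schema)
}

as_cohort_df <- function(raw, schema) {
  numeric_fields <- c("age", "bmi", "tumor_size", "sbr_grade", "n_nodes",
                      "er_percent", "pr_percent", "hemoglobin", "lymphocytes",
                      "followup_months", "true_cluster")
  logical_fields <- c("hr_positive", "has_comorbidity", "received_chemo",
                      "death", "relapse")
  out <- data.frame(row = seq_len(nrow(raw)))
  for (f in names(schema$map)) {
    src <- schema$map[[f]]
    if (!src %in% names(raw)) next
    col <- raw[[src]]
    out[[f]] <- if (f %in% numeric_fields) parse_numeric(col)
                else if (f %in% logical_fields) parse_logical(col)
                else { col[tolower(trimws(col)) %in% MISSING_MARKERS] <- NA; col }
  }
  out$row <- NULL
  if (is.null(out$patient_id)) out$patient_id <- sprintf("P%04d", seq_len(nrow(raw)))
  attr(out, "hr_mode") <- schema$hr_mode
  out
}

#' Write a cohort back to delimited text
#'
#' @param cohort a cohort \code{data.frame}.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  utils::write.table(cohort, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Eligibility filter: resolvable 5-year outcome in women aged 70+
#'
#' Retains patients aged at least 70 whose 5-year vital status is known:
#' either at least 60 months of follow-up, or death within 60 months (a
#' death at exactly 60 months counts as death within 5 years).  Order is
#' preserved; the filter is idempotent.
#'
#' @param cohort a cohort \code{data.frame}.
#' @return the filtered \code{data.frame}.
#' @export
eligibility_filter <- function(cohort) {
  fu <- cohort$followup_months
  death <- cohort$death
  keep <- !is.na(cohort$age) & cohort$age >= 70 &
    !is.na(fu) & fu >= 0 & !is.na(death) &
    (fu >= 60 | (death & fu <= 60))
  cohort[keep, , drop = FALSE]
}

#' Complete-case filter on the nine predictors
#'
#' Retains exactly the patients with all nine predictor source fields
#' non-missing.  Treatment and outcome fields are not predictors and do not
#' affect retention.
#'
#' @param cohort a cohort \code{data.frame}.
#' @param schema the schema the cohort was read with; defaults to the
#'   \code{hr_mode} recorded on the cohort.
#' @return the filtered \code{data.frame}.
#' @export
complete_case_filter <- function(cohort, schema = NULL) {
  hr_mode <- if (!is.null(schema)) schema$hr_mode
             else attr(cohort, "hr_mode") %||% "percent"
  fields <- predictor_source_fields(list(hr_mode = hr_mode))
  miss <- setdiff(fields, names(cohort))
  if (length(miss))
    stop_oncotwin("cohort lacks predictor column(s): ",
                  paste(miss, collapse = ", "), class = "oncotwin_schema_error")
  ok <- rowSums(is.na(cohort[fields])) == 0
  cohort[ok, , drop = FALSE]
}

#' Hormone-receptor status from ER/PR staining percentages
#'
#' Positive (1) when estrogen or progesterone receptor is present in at
#' least 10\% of tumor cells; otherwise 0 (triple negative in a
#' HER2-negative cohort).  Vectorized; the 10\% boundary is inclusive.
#'
#' @param er_percent,pr_percent percentages in [0, 100].
#' @return integer vector of 0/1.
#' @export
derive_hr_status <- function(er_percent, pr_percent) {
  vals <- c(er_percent, pr_percent)
  if (any(!is.na(vals) & (vals < 0 | vals > 100)))
    stop_oncotwin("ER/PR percentages must lie in [0, 100]",
                  class = "oncotwin_domain_error")
  as.integer(er_percent >= 10 | pr_percent >= 10)
}

#' Binarize the Scarff-Bloom-Richardson grade
#'
#' Grade 3 is high (1); grades 1--2 are low (0).
#'
#' @param sbr integer vector with values in \{1, 2, 3\}.
#' @return integer vector of 0/1.
#' @export
binarize_grade <- function(sbr) {
  if (any(!is.na(sbr) & !sbr %in% c(1, 2, 3)))
    stop_oncotwin("SBR grade must be 1, 2 or 3",
                  class = "oncotwin_domain_error")
  as.integer(sbr == 3)
}

#' Encode complete-case patients as the nine-predictor matrix
#'
#' Deterministic encoding of each patient into the 9 predictors used by all
#' downstream stages: age, tumor size, high grade (0/1), involved nodes,
#' HR-positive (0/1), hemoglobin, lymphocytes, BMI, comorbidity (0/1).
#' Treatment fields and creatinine are deliberately excluded.
#'
#' @param cohort a complete-case cohort \code{data.frame}.
#' @return numeric matrix with one row per patient and 9 named columns.
#' @export
predictor_matrix <- function(cohort) {
  hr_mode <- attr(cohort, "hr_mode") %||%
    (if (!is.null(cohort$er_percent)) "percent" else "flag")
  hr <- if (hr_mode == "percent")
    derive_hr_status(cohort$er_percent, cohort$pr_percent)
  else as.integer(cohort$hr_positive)
  x <- cbind(age = cohort$age,
             tumor_size = cohort$tumor_size,
             grade_high = binarize_grade(cohort$sbr_grade),
             n_nodes = cohort$n_nodes,
             hr_positive = hr,
             hemoglobin = cohort$hemoglobin,
             lymphocytes = cohort$lymphocytes,
             bmi = cohort$bmi,
             comorbidity = as.integer(cohort$has_comorbidity))
  if (anyNA(x))
    stop_oncotwin("incomplete record(s): predictors contain missing values; ",
                  "apply complete_case_filter() first",
                  class = "oncotwin_incomplete_error")
  rownames(x) <- cohort$patient_id
  x
}

#' Encode a single patient record
#'
#' @param record a one-row cohort \code{data.frame}.
#' @return named numeric vector of length 9.
#' @export
to_predictor_vector <- function(record) {
  drop(predictor_matrix(record)[1, ])
}

#' Five-year outcome labels
#'
#' \code{survived_5y} is \code{FALSE} exactly when death occurred within 60
#' months of diagnosis.  \code{in_reference_class} marks the good-outcome
#' patients (alive at 5 years with no documented relapse) used to calibrate
#' the reference model; a missing relapse flag is treated as no relapse.
#'
#' @param cohort an eligibility-filtered cohort \code{data.frame}.
#' @return \code{data.frame} with logical columns \code{survived_5y},
#'   \code{in_reference_class}.
#' @export
outcome_5y <- function(cohort) {
  died_5y <- cohort$death & cohort$followup_months <= 60
  relapse <- !is.na(cohort$relapse) & cohort$relapse
  data.frame(survived_5y = !died_5y,
             in_reference_class = !died_5y & !relapse)
}

AGE_BIN_STARTS <- c(70, 75, 80, 85, 90)
AGE_BIN_LABELS <- c("70-74", "75-79", "80-84", "85-89", ">90")

# Grouped-median interpolation on 5-year age bins: L + ((N/2 - F)/f) * w,
# with lower real boundary L = bin start - 0.5; the open top bin is treated
# as 90-94.
grouped_median <- function(counts, starts = AGE_BIN_STARTS, width = 5) {
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  cum <- cumsum(counts)
  i <- which(cum >= n / 2)[1]
  f_below <- if (i == 1) 0 else cum[i - 1]
  unname(starts[i] - 0.5 + ((n / 2 - f_below) / counts[i]) * width)
}

#' Summarize a cohort (Table-1 style)
#'
#' Age-bin counts (70-74 / 75-79 / 80-84 / 85-89 / >90), grouped-median age
#' by linear interpolation within the median bin (rounded to the nearest
#' year), chemotherapy percentage (rounded to the nearest integer), and
#' complete-case count.
#'
#' @param cohort a non-empty cohort \code{data.frame}.
#' @return an object of class \code{"cohort_summary"}.
#' @export
summarize_cohort <- function(cohort) {
  if (is.null(cohort) || nrow(cohort) == 0)
    stop_oncotwin("cannot summarize an empty cohort",
                  class = "oncotwin_empty_error")
  age <- cohort$age[!is.na(cohort$age)]
  bins <- c(sum(age < 75), sum(age >= 75 & age < 80), sum(age >= 80 & age < 85),
            sum(age >= 85 & age < 90), sum(age >= 90))
  names(bins) <- AGE_BIN_LABELS
  chemo <- sum(!is.na(cohort$received_chemo) & cohort$received_chemo)
  structure(list(
    n_total = nrow(cohort),
    n_complete = nrow(complete_case_filter(cohort)),
    age_bin_counts = bins,
    grouped_median_age = round(grouped_median(bins)),
    pct_chemo = round(100 * chemo / nrow(cohort))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat("  patients:           ", x$n_total, "\n")
  cat("  complete cases:     ", x$n_complete, "\n")
  cat("  grouped median age: ", x$grouped_median_age, "years\n")
  cat("  chemotherapy:       ", x$pct_chemo, "%\n")
  cat("  age bins:\n")
  print(x$age_bin_counts)
  invisible(x)
}

#' Write a cohort summary as JSON
#'
#' @param summary a \code{\link{summarize_cohort}} result.
#' @param path output path.
#' @export
write_cohort_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
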
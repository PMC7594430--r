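# Sample metadata: diagnostic group labels, twin pairing, and ADHD Rating
# Scale scores. The twin cohort carries a pair id that must occur exactly
# twice, once per diagnostic group; rating-scale raw subscales are bounded by
# the instrument range (0-27 per 9-item subscale, totals up to 54).

SHEET_COLUMNS <- c(
  "sample_id", "cohort", "group", "pair_id",
  "adhd_rs_inattention", "adhd_rs_hyperactivity", "adhd_rs_total",
  "adhd_rs_tscore", "prior_diagnosis"
)

#' Construct and validate a sample sheet
#'
#' @param df Data frame with columns `sample_id`, `cohort`
#'   (`"case_control"` or `"twins"`), `group` (`"affected"` or
#'   `"unaffected"`), and optionally `pair_id` (required for twins),
#'   `adhd_rs_inattention`, `adhd_rs_hyperactivity`, `adhd_rs_total`,
#'   `adhd_rs_tscore`, `prior_diagnosis`. Missing clinical fields are `NA`,
#'   never zero.
#' @return The validated data frame with class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in setdiff(SHEET_COLUMNS, names(df))) {
    df[[col]] <- if (col == "prior_diagnosis") NA else NA_real_
  }
  df <- df[, SHEET_COLUMNS]
  df$cohort <- tolower(as.character(df$cohort))
  df$group <- tolower(as.character(df$group))
  df$sample_id <- as.character(df$sample_id)
  df$pair_id <- as.character(df$pair_id)
  df$pair_id[!nzchar(df$pair_id) | is.na(df$pair_id)] <- NA_character_
  for (col in c("adhd_rs_inattention", "adhd_rs_hyperactivity",
                "adhd_rs_total", "adhd_rs_tscore")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$prior_diagnosis <- as.logical(df$prior_diagnosis)
  validate_sample_sheet(df)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

validate_sample_sheet <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    cdeg_stop("duplicated sample ids in sample sheet", "cdeg_format_error")
  }
  if (!all(df$cohort %in% c("case_control", "twins"))) {
    cdeg_stop("cohort must be 'case_control' or 'twins'", "cdeg_format_error")
  }
  if (!all(df$group %in% c("affected", "unaffected"))) {
    cdeg_stop("group must be 'affected' or 'unaffected'", "cdeg_format_error")
  }
  for (col in c("adhd_rs_inattention", "adhd_rs_hyperactivity")) {
    bad <- !is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 27)
    if (any(bad)) {
      cdeg_stop(sprintf("%s outside the instrument range [0, 27]", col),
                "cdeg_format_error")
    }
  }
  bad_tot <- !is.na(df$adhd_rs_total) & (df$adhd_rs_total < 0 | df$adhd_rs_total > 54)
  if (any(bad_tot)) {
    cdeg_stop("adhd_rs_total outside [0, 54]", "cdeg_format_error")
  }
  tw <- df[df$cohort == "twins", , drop = FALSE]
  if (nrow(tw)) {
    if (anyNA(tw$pair_id)) {
      cdeg_stop("twins cohort requires a pair_id for every sample",
                "cdeg_design_error")
    }
    tab <- table(tw$pair_id)
    if (any(tab != 2L)) {
      cdeg_stop(sprintf("pair_id(s) not occurring exactly twice: %s",
                        paste(names(tab)[tab != 2L], collapse = ", ")),
                "cdeg_design_error")
    }
    split_grp <- split(tw$group, tw$pair_id)
    ok <- vapply(split_grp, function(g) {
      setequal(g, c("affected", "unaffected"))
    }, logical(1))
    if (!all(ok)) {
      cdeg_stop(sprintf("pair(s) without one affected and one unaffected member: %s",
                        paste(names(split_grp)[!ok], collapse = ", ")),
                "cdeg_design_error")
    }
  }
  invisible(df)
}

#' Read a sample sheet from a comma-separated file
#'
#' Enum columns are case-insensitive; empty strings in optional clinical
#' fields are surfaced as `NA` (absent), never as zero.
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("NA", ""))
  need <- c("sample_id", "cohort", "group")
  if (!all(need %in% names(df))) {
    cdeg_stop("sample sheet must contain sample_id, cohort, group",
              "cdeg_format_error")
  }
  sample_sheet(df)
}

#' Write a sample sheet to CSV
#'
#' @param sheet A [sample_sheet()].
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  out <- as.data.frame(sheet)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Split a twins sheet into an ordered pair table: one row per pair with the
# affected and unaffected sample ids.
twin_pairs <- function(sheet) {
  tw <- sheet[sheet$cohort == "twins", , drop = FALSE]
  if (!nrow(tw)) cdeg_stop("no twin samples in sheet", "cdeg_design_error")
  validate_sample_sheet(tw)
  ids <- sort(unique(tw$pair_id))
  aff <- vapply(ids, function(p) {
    tw$sample_id[tw$pair_id == p & tw$group == "affected"]
  }, character(1))
  una <- vapply(ids, function(p) {
    tw$sample_id[tw$pair_id == p & tw$group == "unaffected"]
  }, character(1))
  data.frame(pair_id = ids, affected = aff, unaffected = una,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Named group factor (affected/unaffected) aligned to the columns of cm.
group_labels <- function(cm, sheet) {
  idx <- match(cm$sample_ids, sheet$sample_id)
  if (anyNA(idx)) {
    cdeg_stop("count matrix contains samples absent from the sample sheet",
              "cdeg_design_error")
  }
  factor(sheet$group[idx], levels = c("unaffected", "affected"))
}
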
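# ---- canonicalization helpers -------------------------------------------------

#' Canonicalize a MedDRA-style preferred term
#'
#' Trims leading/trailing whitespace and collapses internal runs of whitespace
#' to a single space. Matching against event dictionaries is case-insensitive
#' on the canonical form.
#'
#' @param pt character vector of preferred terms.
#' @return character vector of canonical terms.
#' @export
canonical_pt <- function(pt) {
  pt <- gsub("[[:space:]]+", " ", as.character(pt))
  trimws(pt)
}

pt_key <- function(pt) tolower(canonical_pt(pt))

norm_drug_name <- function(x) tolower(trimws(as.character(x)))

# ATC codes: 1, 3, 4, 5 or 7 character prefixes of the full 7-character code
ATC_PATTERN <- "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"

#' Test whether strings are lexically valid ATC codes or prefixes
#'
#' A valid code is a prefix of the 7-character ATC pattern
#' (letter, two digits, letter, letter, two digits) cut at a level boundary,
#' e.g. "N", "N06", "N06A", "N06AB", "N06AB04".
#'
#' @param x character vector.
#' @return logical vector.
#' @export
is_valid_atc <- function(x) {
  grepl(ATC_PATTERN, toupper(trimws(as.character(x))))
}

split_atc <- function(cell) {
  # semicolon-separated cell -> uppercase character vector (possibly empty)
  out <- toupper(trimws(strsplit(as.character(cell), ";", fixed = TRUE)[[1]]))
  out[nzchar(out)]
}

join_atc <- function(codes) paste(sort(unique(toupper(codes))), collapse = ";")

SEX_LEVELS <- c("F", "M")
ROLE_LEVELS <- c("suspect", "concomitant", "interacting")
#' Default geographic regions
#' @export
DEFAULT_REGIONS <- c("Africa", "Americas", "Asia", "Europe", "Oceania")

# ---- report_set ---------------------------------------------------------------

#' Construct a report set
#'
#' A `report_set` is the in-memory form of an ICSR line listing: three linked
#' tables (reports, drug entries, event entries) joined by `report_id`.
#'
#' @param reports data.frame with columns `report_id`, `age_years` (integer or
#'   NA), `sex` ("F", "M" or NA), `region`.
#' @param drugs data.frame with columns `report_id`, `drug_name` (normalized
#'   lowercase), `atc_codes` (semicolon-separated string, possibly empty) and
#'   `role` (suspect/concomitant/interacting).
#' @param events data.frame with columns `report_id`, `pt`.
#' @param provenance free-text label recording where the data came from.
#' @param validate if TRUE (default), enforce the structural invariants:
#'   unique report ids, at least one event per report, no dangling keys,
#'   ages inside [0, 130].
#' @return an object of class `report_set` with elements `reports`, `drugs`,
#'   `events`, `provenance` and derived `counters`.
#' @export
report_set <- function(reports, drugs, events, provenance = "unspecified",
                       validate = TRUE) {
  reports <- as.data.frame(reports, stringsAsFactors = FALSE)
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)

  reports$report_id <- as.character(reports$report_id)
  reports$age_years <- suppressWarnings(as.integer(reports$age_years))
  sex <- as.character(reports$sex)
  sex[!is.na(sex) & !(sex %in% SEX_LEVELS)] <- NA
  reports$sex <- sex
  reports$region <- as.character(reports$region)

  if (nrow(drugs)) {
    drugs$report_id <- as.character(drugs$report_id)
    drugs$drug_name <- norm_drug_name(drugs$drug_name)
    drugs$atc_codes <- as.character(drugs$atc_codes)
    drugs$role <- as.character(drugs$role)
  } else {
    drugs <- data.frame(report_id = character(), drug_name = character(),
                        atc_codes = character(), role = character(),
                        stringsAsFactors = FALSE)
  }
  if (nrow(events)) {
    events$report_id <- as.character(events$report_id)
    events$pt <- canonical_pt(events$pt)
    events$.pt_key <- tolower(events$pt)  # cached match key
  } else {
    events <- data.frame(report_id = character(), pt = character(),
                         .pt_key = character(), stringsAsFactors = FALSE)
  }

  if (validate) {
    dup <- unique(reports$report_id[duplicated(reports$report_id)])
    if (length(dup)) {
      stop("integrity error: duplicate report_id: ",
           paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
    }
    for (tbl in list(drugs = drugs, events = events)) {
      dangling <- setdiff(unique(tbl$report_id), reports$report_id)
      if (length(dangling)) {
        stop("integrity error: rows reference absent report_id: ",
             paste(utils::head(dangling, 5L), collapse = ", "), call. = FALSE)
      }
    }
    no_event <- setdiff(reports$report_id, unique(events$report_id))
    if (length(no_event)) {
      stop("integrity error: reports without any event entry: ",
           paste(utils::head(no_event, 5L), collapse = ", "), call. = FALSE)
    }
    bad_age <- !is.na(reports$age_years) &
      (reports$age_years < 0L | reports$age_years > 130L)
    if (any(bad_age)) {
      stop("integrity error: age_years outside [0, 130] for report_id: ",
           paste(utils::head(reports$report_id[bad_age], 5L), collapse = ", "),
           call. = FALSE)
    }
    bad_role <- nrow(drugs) && any(!drugs$role %in% ROLE_LEVELS)
    if (isTRUE(bad_role)) {
      stop("format error: drug role must be one of ",
           paste(ROLE_LEVELS, collapse = "/"), call. = FALSE)
    }
  }

  structure(
    list(reports = reports, drugs = drugs, events = events,
         provenance = provenance,
         counters = list(n_reports = nrow(reports),
                         n_missing_sex = sum(is.na(reports$sex)),
                         n_missing_age = sum(is.na(reports$age_years)))),
    class = "report_set"
  )
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set> ", x$counters$n_reports, " reports (",
      nrow(x$drugs), " drug rows, ", nrow(x$events), " event rows)\n",
      "  provenance: ", x$provenance, "\n",
      "  missing sex: ", x$counters$n_missing_sex,
      ", missing age: ", x$counters$n_missing_age, "\n", sep = "")
  invisible(x)
}

#' Number of reports in a report set
#' @param x a `report_set`.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "report_set"))
  nrow(x$reports)
}

# Collapse duplicate (report_id, drug_name) rows keeping the most causal role
# (suspect > interacting > concomitant) and the union of ATC codes.
collapse_drug_rows <- function(drugs) {
  if (!nrow(drugs)) return(drugs)
  key <- paste(drugs$report_id, drugs$drug_name, sep = "\r")
  if (!anyDuplicated(key)) return(drugs)
  rank <- match(drugs$role, c("suspect", "interacting", "concomitant"))
  ord <- order(key, rank)
  drugs <- drugs[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  atc <- vapply(split(drugs$atc_codes, factor(key, levels = unique(key))),
                function(cells) join_atc(unlist(lapply(cells, split_atc))),
                character(1))
  out <- drugs[first, , drop = FALSE]
  out$atc_codes <- unname(atc)
  rownames(out) <- NULL
  out
}

# ---- drug dictionary ----------------------------------------------------------

#' Read a drug dictionary (drug name to ATC codes)
#'
#' @param path CSV file with columns `drug_name` and `atc_codes`
#'   (semicolon-separated). Defaults to the dictionary shipped with the
#'   package, which covers common antidepressants, opioid analgesics,
#'   bisphosphonates, psychotropic co-medications and background drugs.
#' @return named list mapping normalized drug name to a character vector of
#'   ATC codes, with class `drug_dictionary`.
#' @export
read_drug_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "drug_dictionary.csv", package = "pvror",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_name", "atc_codes")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("format error: drug dictionary missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  nm <- norm_drug_name(df$drug_name)
  dict <- lapply(df$atc_codes, split_atc)
  names(dict) <- nm
  bad <- !vapply(dict, function(x) all(is_valid_atc(x)), logical(1))
  if (any(bad)) {
    stop("format error: invalid ATC code for drug(s): ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  }
  class(dict) <- "drug_dictionary"
  dict
}

resolve_atc <- function(drugs, drug_dictionary) {
  # Fill empty atc_codes cells from the dictionary; unknown names stay empty.
  if (!nrow(drugs)) return(drugs)
  cells <- drugs$atc_codes
  cells[is.na(cells)] <- ""
  empty <- !nzchar(trimws(cells))
  if (any(empty) && !is.null(drug_dictionary)) {
    dict_joined <- vapply(drug_dictionary, join_atc, character(1))
    hit <- match(drugs$drug_name[empty], names(drug_dictionary))
    cells[empty] <- ifelse(is.na(hit), "", dict_joined[hit])
    unknown <- unique(drugs$drug_name[empty][is.na(hit)])
    if (length(unknown)) {
      message("drug name(s) not in dictionary, ATC left empty: ",
              paste(utils::head(unknown, 10L), collapse = ", "))
    }
  }
  # normalize (sort, dedupe, uppercase) once per distinct cell value
  u <- unique(cells)
  norm_u <- vapply(u, function(cell) join_atc(split_atc(cell)), character(1))
  drugs$atc_codes <- unname(norm_u[match(cells, u)])
  drugs
}

# ---- CSV line-listing I/O -----------------------------------------------------

read_checked_csv <- function(path, required_cols, what) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = NULL)
  miss <- setdiff(required_cols, names(df))
  if (length(miss)) {
    stop("format error in ", what, " (", path, "): missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read an ICSR line listing from three CSV files
#'
#' The line-listing dialect has one reports table (`report_id`, `age_years`,
#' `sex`, `region`), one drug table (`report_id`, `drug_name`, `atc_codes`
#' semicolon-separated, `role`) and one event table (`report_id`, `pt`).
#' Empty `age_years`/`sex` cells become missing values. Drug rows with an
#' empty ATC cell are resolved through `drug_dictionary`; unknown drug names
#' keep an empty ATC set and are reported with a message. Duplicate rows for
#' the same report and drug are collapsed to one entry keeping the most
#' causal role (suspect > interacting > concomitant).
#'
#' @param reports_path,drugs_path,events_path paths to the three CSV files.
#' @param drug_dictionary a `drug_dictionary` (default: the packaged one), or
#'   NULL to skip resolution.
#' @return a validated [report_set()].
#' @export
read_reports <- function(reports_path, drugs_path, events_path,
                         drug_dictionary = read_drug_dictionary()) {
  rep_df <- read_checked_csv(reports_path,
                             c("report_id", "age_years", "sex", "region"),
                             "reports table")
  drug_df <- read_checked_csv(drugs_path,
                              c("report_id", "drug_name", "atc_codes", "role"),
                              "drugs table")
  ev_df <- read_checked_csv(events_path, c("report_id", "pt"), "events table")

  rep_df$age_years[!nzchar(trimws(rep_df$age_years))] <- NA
  rep_df$sex[!nzchar(trimws(rep_df$sex))] <- NA

  drug_df$drug_name <- norm_drug_name(drug_df$drug_name)
  drug_df <- resolve_atc(drug_df, drug_dictionary)
  drug_df <- collapse_drug_rows(drug_df)

  report_set(rep_df, drug_df, ev_df,
             provenance = paste0("read:", reports_path))
}

#' Write a report set as the three line-listing CSV files
#'
#' Inverse of [read_reports()]: `read_reports(write_reports(s))` reproduces
#' `s` field for field. Missing age and sex are written as empty cells; ATC
#' sets are semicolon-joined.
#'
#' @param x a `report_set`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named character vector of the three file paths.
#' @export
write_reports <- function(x, out_dir) {
  stopifnot(inherits(x, "report_set"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create directory ", out_dir, call. = FALSE)
  }
  paths <- c(reports = file.path(out_dir, "reports.csv"),
             drugs = file.path(out_dir, "drugs.csv"),
             events = file.path(out_dir, "events.csv"))
  rep_df <- x$reports
  rep_df$age_years <- ifelse(is.na(rep_df$age_years), "",
                             as.character(rep_df$age_years))
  rep_df$sex <- ifelse(is.na(rep_df$sex), "", rep_df$sex)
  utils::write.csv(rep_df, paths[["reports"]], row.names = FALSE, na = "")
  utils::write.csv(x$drugs, paths[["drugs"]], row.names = FALSE, na = "")
  utils::write.csv(x$events[, c("report_id", "pt")], paths[["events"]],
                   row.names = FALSE, na = "")
  invisible(paths)
}
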
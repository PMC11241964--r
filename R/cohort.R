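# Cohort construction: eligibility filtering, case/exposure labeling,
# confounder design matrix, exclusion accounting.

new_exclusion_log <- function() {
  data.frame(filter = character(), n_before = integer(),
             n_excluded = integer(), n_after = integer(),
             stringsAsFactors = FALSE)
}

add_exclusion <- function(log, filter, n_before, n_after) {
  rbind(log, data.frame(filter = filter, n_before = n_before,
                        n_excluded = n_before - n_after, n_after = n_after,
                        stringsAsFactors = FALSE))
}

subset_report_set <- function(x, keep_ids) {
  report_set(x$reports[x$reports$report_id %in% keep_ids, , drop = FALSE],
             x$drugs[x$drugs$report_id %in% keep_ids, , drop = FALSE],
             x$events[x$events$report_id %in% keep_ids, , drop = FALSE],
             provenance = x$provenance, validate = FALSE)
}

#' Restrict a report set to a minimum age
#'
#' Keeps reports whose age is recorded and at least `min_age` (inclusive).
#' Reports with missing age are excluded at this step and counted in the log.
#'
#' @param x a `report_set`.
#' @param min_age minimum age in years (default 65).
#' @param log an existing exclusion log to chain onto (optional).
#' @return list with elements `reports` (filtered `report_set`) and
#'   `exclusions` (the chained exclusion log).
#' @export
restrict_age <- function(x, min_age = 65, log = new_exclusion_log()) {
  stopifnot(inherits(x, "report_set"), min_age >= 0)
  keep <- !is.na(x$reports$age_years) & x$reports$age_years >= min_age
  out <- subset_report_set(x, x$reports$report_id[keep])
  list(reports = out,
       exclusions = add_exclusion(log, paste0("age >= ", min_age),
                                  nrow(x$reports), sum(keep)))
}

#' Complete-case filter on required covariates
#'
#' Drops reports with a missing value of any required variable (`sex` and/or
#' `region`). Emits a warning when more than 1\% of reports are dropped for a
#' variable, the conventional threshold above which imputation would be
#' considered instead.
#'
#' @param x a `report_set`.
#' @param required_vars subset of c("sex", "region").
#' @param log an existing exclusion log to chain onto.
#' @return list with `reports` and `exclusions` as in [restrict_age()].
#' @export
apply_complete_case <- function(x, required_vars = "sex",
                                log = new_exclusion_log()) {
  stopifnot(inherits(x, "report_set"),
            all(required_vars %in% c("sex", "region")))
  keep <- rep(TRUE, nrow(x$reports))
  for (v in required_vars) {
    miss <- is.na(x$reports[[v]]) | !nzchar(trimws(x$reports[[v]]))
    if (nrow(x$reports) && mean(miss) > 0.01) {
      warning(sprintf("%.1f%% of reports missing '%s' (> 1%%); %s",
                      100 * mean(miss), v,
                      "complete-case exclusion may be consequential"),
              call. = FALSE)
    }
    keep <- keep & !miss
  }
  out <- subset_report_set(x, x$reports$report_id[keep])
  lbl <- if (length(required_vars)) {
    paste0("complete case (", paste(required_vars, collapse = ", "), ")")
  } else "complete case (none)"
  list(reports = out,
       exclusions = add_exclusion(log, lbl, nrow(x$reports), sum(keep)))
}

#' Label case status under a composite event definition
#'
#' A report is a case if and only if any of its event preferred terms belongs
#' to the definition's term set (canonicalized, case-insensitive match).
#'
#' @param x a `report_set`.
#' @param event_definition an [event_definition()].
#' @return named integer vector (0/1) indexed by `report_id`.
#' @export
label_cases <- function(x, event_definition) {
  stopifnot(inherits(x, "report_set"),
            inherits(event_definition, "event_definition"))
  term_keys <- pt_key(event_definition$terms)
  hit_ids <- unique(x$events$report_id[x$events$.pt_key %in% term_keys])
  stats::setNames(as.integer(x$reports$report_id %in% hit_ids),
                  x$reports$report_id)
}

# Vectorized ATC prefix test on semicolon-joined code cells. Prefixes are
# uppercase alphanumerics, so the pattern needs no escaping.
atc_cell_has_prefix <- function(cells, prefixes) {
  if (!length(prefixes)) return(rep(FALSE, length(cells)))
  grepl(paste0("(^|;)(", paste(toupper(prefixes), collapse = "|"), ")"),
        cells)
}

# Which drug rows match a selector (class label via class_map, or drug name)?
drug_rows_matching <- function(drugs, selector, class_map) {
  if (selector %in% names(class_map)) {
    cls <- class_map[[selector]]
    drugs$drug_name %in% cls$drugs |
      atc_cell_has_prefix(drugs$atc_codes, cls$atc_prefixes)
  } else {
    drugs$drug_name == norm_drug_name(selector)
  }
}

#' Label drug exposure
#'
#' A report is exposed if any of its drug entries matches the selector — a
#' class label resolved through the class map, or a single drug name — in
#' any role (suspect, concomitant or interacting alike).
#'
#' @param x a `report_set`.
#' @param selector class label (e.g. "SSRI") or drug name (e.g. "citalopram").
#' @param class_map a `class_map`; selectors in ALL CAPS that are not in the
#'   map raise an error (they look like class labels, not drug names).
#' @return named integer vector (0/1) indexed by `report_id`.
#' @export
label_exposure <- function(x, selector, class_map = default_class_map()) {
  stopifnot(inherits(x, "report_set"), is.character(selector),
            length(selector) == 1L)
  if (!selector %in% names(class_map) && selector == toupper(selector) &&
      grepl("[A-Z]", selector)) {
    stop("unknown class label '", selector, "' (known: ",
         paste(names(class_map), collapse = ", "), ")", call. = FALSE)
  }
  hit <- drug_rows_matching(x$drugs, selector, class_map)
  hit_ids <- unique(x$drugs$report_id[hit])
  stats::setNames(as.integer(x$reports$report_id %in% hit_ids),
                  x$reports$report_id)
}

#' Frequently reported antidepressants, by class
#'
#' Counts, over the whole report set (before any case restriction), the
#' number of distinct reports mentioning each antidepressant drug, and
#' returns the drugs mentioned in strictly more than `threshold` reports,
#' grouped by class in class-map order. A drug mentioned twice in the same
#' report counts once.
#'
#' @param x a `report_set`.
#' @param class_map a `class_map`.
#' @param threshold report-count threshold (strict inequality; default 1000).
#' @return named list (one element per antidepressant class present) of
#'   character vectors of drug names, ordered by descending report count.
#' @export
frequent_drugs <- function(x, class_map = default_class_map(),
                           threshold = 1000L) {
  stopifnot(inherits(x, "report_set"), threshold >= 1)
  drugs <- x$drugs
  if (!nrow(drugs)) return(stats::setNames(list(), character()))
  counts <- tapply(drugs$report_id, drugs$drug_name,
                   function(ids) length(unique(ids)))
  ad_classes <- intersect(AD_CLASSES, names(class_map))
  out <- list()
  for (lbl in ad_classes) {
    in_class <- names(counts)[vapply(names(counts), function(dn) {
      rows <- drugs$drug_name == dn
      cell <- drugs$atc_codes[rows][1]
      lbl %in% map_drug_to_classes(dn, split_atc(cell), class_map)
    }, logical(1))]
    keep <- in_class[counts[in_class] > threshold]
    if (length(keep)) {
      out[[lbl]] <- keep[order(-counts[keep], keep)]
    }
  }
  out
}

#' Build the logistic-regression design matrix
#'
#' Assembles the covariate matrix of the adjusted analysis: one 0/1 exposure
#' column per selector (class label or drug name), one 0/1 column per
#' confounder (ATC-prefix match over the report's drugs for `drug_atc`,
#' preferred-term membership for `event_pt`), and dummy-coded demographics —
#' age band 75+ (reference 65-74), sex M (reference F), and region dummies
#' with the most frequent region as reference. Missing region becomes its own
#' "Unknown" level. Constant confounder or demographic columns are dropped
#' and logged; a constant exposure column is an error since its effect is not
#' estimable.
#'
#' When an exposure selector's drugs fall inside a `drug_atc` confounder's
#' prefix (e.g. a natural-opium-alkaloid exposure inside the opioid N02
#' confounder), that confounder column is computed excluding the exposure's
#' matching drug entries, to avoid built-in collinearity; this is logged.
#'
#' @param x a filtered `report_set`.
#' @param exposure_selectors character vector of class labels or drug names.
#' @param confounder_specs data.frame of confounder specs
#'   ([default_confounders()]); pass a zero-row frame for none.
#' @param class_map a `class_map`.
#' @param include_age_band include the age-band dummy (FALSE inside age
#'   subgroups, where it is constant by construction).
#' @param drop_confounders labels of confounders to omit (e.g. the
#'   hyponatremia term when it is part of the outcome).
#' @return object of class `design_matrix`: list with `X` (numeric matrix,
#'   rownames = report ids), `roles` (named character vector, "exposure" or
#'   "adjustment"), `dropped` (character vector of dropped constant columns)
#'   and `notes` (character vector of log messages).
#' @export
build_design_matrix <- function(x, exposure_selectors,
                                confounder_specs = default_confounders(),
                                class_map = default_class_map(),
                                include_age_band = TRUE,
                                drop_confounders = character()) {
  stopifnot(inherits(x, "report_set"))
  if (anyNA(x$reports$age_years) || anyNA(x$reports$sex)) {
    stop("report set has missing age or sex; apply restrict_age() and ",
         "apply_complete_case() before building the design matrix",
         call. = FALSE)
  }
  ids <- x$reports$report_id
  n <- length(ids)
  cols <- list()
  roles <- character()
  notes <- character()

  for (sel in exposure_selectors) {
    cols[[sel]] <- as.numeric(label_exposure(x, sel, class_map))
    roles[sel] <- "exposure"
  }

  # demographics
  if (include_age_band) {
    cols[["age_band_75plus"]] <- as.numeric(x$reports$age_years >= 75)
    roles["age_band_75plus"] <- "adjustment"
  }
  cols[["sex_M"]] <- as.numeric(x$reports$sex == "M")
  roles["sex_M"] <- "adjustment"
  region <- x$reports$region
  region[is.na(region) | !nzchar(trimws(region))] <- "Unknown"
  reg_tab <- sort(table(region), decreasing = TRUE)
  ref_region <- names(reg_tab)[1]
  for (lv in setdiff(names(reg_tab), ref_region)) {
    nm <- paste0("region_", lv)
    cols[[nm]] <- as.numeric(region == lv)
    roles[nm] <- "adjustment"
  }
  notes <- c(notes, paste0("reference levels: age 65-74, sex F, region ",
                           ref_region))

  # confounders
  cf <- confounder_specs[!confounder_specs$label %in% drop_confounders, ,
                         drop = FALSE]
  if (length(drop_confounders)) {
    notes <- c(notes, paste0("confounder(s) dropped by request: ",
                             paste(drop_confounders, collapse = ", ")))
  }
  exposure_row_hit <- if (length(exposure_selectors)) {
    Reduce(`|`, lapply(exposure_selectors, function(sel)
      drug_rows_matching(x$drugs, sel, class_map)))
  } else rep(FALSE, nrow(x$drugs))

  for (i in seq_len(nrow(cf))) {
    lbl <- cf$label[i]
    if (cf$kind[i] == "event_pt") {
      hit_ids <- unique(x$events$report_id[
        x$events$.pt_key == pt_key(cf$matcher[i])])
    } else if (cf$kind[i] == "drug_atc") {
      atc_hit <- atc_cell_has_prefix(x$drugs$atc_codes, cf$matcher[i])
      overlap <- atc_hit & exposure_row_hit
      if (any(overlap)) {
        atc_hit <- atc_hit & !exposure_row_hit
        notes <- c(notes, paste0(
          "confounder '", lbl, "' (", cf$matcher[i], ") computed excluding ",
          sum(overlap), " drug row(s) matching the exposure selectors"))
      }
      hit_ids <- unique(x$drugs$report_id[atc_hit])
    } else next  # demographic kinds handled above
    cols[[paste0("cf_", lbl)]] <- as.numeric(ids %in% hit_ids)
    roles[paste0("cf_", lbl)] <- "adjustment"
  }

  X <- do.call(cbind, cols)
  rownames(X) <- ids

  const <- apply(X, 2L, function(v) length(unique(v)) < 2L)
  if (any(const)) {
    const_names <- colnames(X)[const]
    bad_expo <- const_names[roles[const_names] == "exposure"]
    if (length(bad_expo)) {
      stop("constant exposure column (effect not estimable): ",
           paste(bad_expo, collapse = ", "), call. = FALSE)
    }
    notes <- c(notes, paste0("constant adjustment column(s) dropped: ",
                             paste(const_names, collapse = ", ")))
    X <- X[, !const, drop = FALSE]
    roles <- roles[colnames(X)]
  }

  structure(list(X = X, roles = roles,
                 dropped = if (any(const)) const_names else character(),
                 notes = notes),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$X), " reports x ", ncol(x$X), " columns (",
      sum(x$roles == "exposure"), " exposure, ",
      sum(x$roles == "adjustment"), " adjustment)\n", sep = "")
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}
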
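# Orchestration of the case/non-case study: primary, per-drug, age-subgroup,
# concomitant-event, sensitivity and control analyses, plus exports.

analysis_row <- function(analysis_id, outcome_definition, exposure,
                         tab, crude, adjusted, flags = "") {
  data.frame(
    analysis_id = analysis_id,
    outcome_definition = outcome_definition,
    exposure = exposure,
    n_exposed_cases = tab$a,
    a = tab$a, b = tab$b, c = tab$c, d = tab$d,
    crude_or = crude$point, crude_lo = crude$ci_low, crude_hi = crude$ci_high,
    crude_signal = crude$signal,
    adj_or = if (is.null(adjusted)) NA_real_ else adjusted$point,
    adj_lo = if (is.null(adjusted)) NA_real_ else adjusted$ci_low,
    adj_hi = if (is.null(adjusted)) NA_real_ else adjusted$ci_high,
    signal = if (is.null(adjusted)) NA_character_ else adjusted$signal,
    low_count = crude$low_count_flag ||
      (!is.null(adjusted) && adjusted$low_count_flag),
    flags = flags,
    stringsAsFactors = FALSE
  )
}

prepare_cohort <- function(x, config) {
  step1 <- restrict_age(x, config$min_age)
  step2 <- apply_complete_case(step1$reports, "sex", step1$exclusions)
  list(reports = step2$reports, exclusions = step2$exclusions)
}

ad_class_labels <- function(config) {
  intersect(AD_CLASSES, names(config$class_map))
}

correction_of <- function(config) config$model$zero_cell_correction

# One analysis over a fixed outcome and a set of exposure selectors.
# joint = TRUE fits a single model carrying all selectors; FALSE fits one
# model per selector. `extra_selectors` are carried as covariates in per-
# selector models (used by run_per_drug to keep the other class indicators).
run_block <- function(cohort, cases, selectors, config, analysis_id,
                      outcome_name, joint = TRUE,
                      include_age_band = TRUE,
                      drop_confounders = character(),
                      extra_selectors_fn = NULL) {
  rows <- list()
  vif <- NULL
  correction <- correction_of(config)

  fit_one <- function(active_selectors) {
    design <- build_design_matrix(
      cohort, active_selectors, config$confounders, config$class_map,
      include_age_band = include_age_band,
      drop_confounders = drop_confounders)
    fit <- fit_logistic(design, cases,
                        tolerance = config$model$tolerance,
                        max_iter = config$model$max_iter)
    list(design = design, fit = fit)
  }

  if (joint) {
    tabs <- lapply(selectors, function(sel)
      ror_table(cases, label_exposure(cohort, sel, config$class_map)))
    names(tabs) <- selectors
    # exposures with no exposed case cannot enter the model (quasi-separation
    # toward -Inf); their rows keep the zero-cell-corrected crude estimate
    estimable <- selectors[vapply(tabs, function(t) t$a > 0L, logical(1))]
    skipped <- setdiff(selectors, estimable)
    m <- if (length(estimable)) {
      tryCatch(fit_one(estimable), error = function(e) e)
    } else simpleError("no estimable exposure")
    model_failed <- inherits(m, "error")
    if (!model_failed) vif <- compute_vif(m$design)
    for (sel in selectors) {
      tab <- tabs[[sel]]
      crude <- crude_ror(tab, correction)
      adj <- NULL
      flags <- ""
      if (sel %in% skipped) {
        flags <- "zero_exposed_cases"
      } else if (model_failed) {
        flags <- paste0("model_error: ", conditionMessage(m))
      } else {
        adj <- adjusted_ror(m$fit, sel, tab$a)
      }
      rows[[sel]] <- analysis_row(analysis_id, outcome_name, sel, tab,
                                  crude, adj, flags)
    }
  } else {
    for (sel in selectors) {
      expo <- label_exposure(cohort, sel, config$class_map)
      tab <- ror_table(cases, expo)
      crude <- crude_ror(tab, correction)
      active <- sel
      if (!is.null(extra_selectors_fn)) {
        active <- c(sel, extra_selectors_fn(sel))
      }
      adj <- NULL
      flags <- ""
      m <- tryCatch(fit_one(active), error = function(e) e)
      if (inherits(m, "error")) {
        flags <- paste0("model_error: ", conditionMessage(m))
      } else {
        adj <- adjusted_ror(m$fit, sel, tab$a)
        if (is.null(vif)) vif <- compute_vif(m$design)
      }
      rows[[sel]] <- analysis_row(analysis_id, outcome_name, sel, tab,
                                  crude, adj, flags)
    }
  }
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  list(table = tbl, vif = vif)
}

#' Primary analysis: antidepressant classes vs delirium reporting
#'
#' Applies the age restriction and the complete-case filter, labels cases
#' under the primary delirium definition, and estimates the crude and
#' confounder-adjusted r-OR of each antidepressant class. With
#' `config$joint_exposure_model = TRUE` (default) all six class indicators
#' enter one multivariate model; otherwise one model is fitted per class.
#'
#' @param x a `report_set` (unfiltered).
#' @param config a [study_config()].
#' @return list with `table` (the analysis data.frame), `vif` (VIF table of
#'   the adjusted model) and `exclusions` (exclusion log).
#' @export
run_primary <- function(x, config = study_config()) {
  ch <- prepare_cohort(x, config)
  cases <- label_cases(ch$reports, config$event_definitions$primary)
  out <- run_block(ch$reports, cases, ad_class_labels(config), config,
                   analysis_id = "primary", outcome_name = "primary",
                   joint = config$joint_exposure_model)
  c(out, list(exclusions = ch$exclusions))
}

#' Per-drug analysis of frequently reported antidepressants
#'
#' Selects antidepressants mentioned in strictly more than
#' `config$frequent_drug_threshold` reports (counted before the age
#' restriction, over the whole report set), then fits one adjusted model per
#' drug: the drug indicator plus the confounders and the indicators of the
#' *other* five classes; the drug's own class indicator is excluded to avoid
#' double-counting the drug's exposure. Rows are grouped by class in
#' class-map order.
#'
#' @inheritParams run_primary
#' @return list with `table`, `vif` and `exclusions`.
#' @export
run_per_drug <- function(x, config = study_config()) {
  freq <- frequent_drugs(x, config$class_map, config$frequent_drug_threshold)
  ch <- prepare_cohort(x, config)
  cases <- label_cases(ch$reports, config$event_definitions$primary)
  classes <- ad_class_labels(config)
  tables <- list()
  vif <- NULL
  for (lbl in names(freq)) {
    others <- setdiff(classes, lbl)
    out <- run_block(
      ch$reports, cases, freq[[lbl]], config,
      analysis_id = paste0("per_drug:", lbl), outcome_name = "primary",
      joint = FALSE,
      extra_selectors_fn = function(sel) others)
    out$table$flags <- ifelse(nzchar(out$table$flags), out$table$flags,
                              paste0("class=", lbl))
    tables[[lbl]] <- out$table
    if (is.null(vif)) vif <- out$vif
  }
  tbl <- if (length(tables)) do.call(rbind, tables) else {
    empty <- analysis_row("per_drug", "primary", "none",
                          list(a = 0L, b = 0L, c = 0L, d = 0L),
                          list(point = NA_real_, ci_low = NA_real_,
                               ci_high = NA_real_, signal = NA_character_,
                               low_count_flag = FALSE), NULL)
    empty[0, , drop = FALSE]
  }
  rownames(tbl) <- NULL
  list(table = tbl, vif = vif,
       exclusions = ch$exclusions, frequent = freq)
}

#' Age-subgroup analysis
#'
#' Repeats the primary analysis within each configured age band. The
#' age-band dummy is dropped from the adjustment set inside a band (it is
#' constant there by construction); `analysis_id` records the band.
#'
#' @inheritParams run_primary
#' @return list with `table` (rows per class and band) and `exclusions`.
#' @export
run_age_subgroups <- function(x, config = study_config()) {
  ch <- prepare_cohort(x, config)
  tables <- list()
  for (band in config$age_bands) {
    lo <- band[1]; hi <- band[2]
    band_id <- paste0("age:", lo, "-", ifelse(is.finite(hi), hi, "plus"))
    in_band <- !is.na(ch$reports$reports$age_years) &
      ch$reports$reports$age_years >= lo & ch$reports$reports$age_years <= hi
    sub <- subset_report_set(ch$reports,
                             ch$reports$reports$report_id[in_band])
    cases <- label_cases(sub, config$event_definitions$primary)
    out <- run_block(sub, cases, ad_class_labels(config), config,
                     analysis_id = band_id, outcome_name = "primary",
                     joint = config$joint_exposure_model,
                     include_age_band = FALSE)
    tables[[band_id]] <- out$table
  }
  tbl <- do.call(rbind, tables)
  rownames(tbl) <- NULL
  list(table = tbl, exclusions = ch$exclusions)
}

#' Concomitant delirium-hyponatremia analysis
#'
#' The outcome is a report that is a case under the primary delirium
#' definition AND reports "Hyponatraemia" among its events. The hyponatremia
#' confounder is removed from the adjustment set (it is part of the outcome).
#' Zero-cell rows carry the low-count flag and a crude estimate under the
#' zero-cell correction.
#'
#' @inheritParams run_primary
#' @return list with `table`, `vif` and `exclusions`.
#' @export
run_concomitant <- function(x, config = study_config()) {
  ch <- prepare_cohort(x, config)
  delirium <- label_cases(ch$reports, config$event_definitions$primary)
  hypo <- label_cases(ch$reports,
                      event_definition("hyponatraemia", "Hyponatraemia"))
  cases <- as.integer(delirium == 1L & hypo == 1L)
  names(cases) <- names(delirium)
  hypo_cf <- config$confounders$label[
    config$confounders$kind == "event_pt" &
      pt_key(config$confounders$matcher) == pt_key("Hyponatraemia")]
  out <- run_block(ch$reports, cases, ad_class_labels(config), config,
                   analysis_id = "concomitant_hyponatremia",
                   outcome_name = "primary+hyponatraemia",
                   joint = config$joint_exposure_model,
                   drop_confounders = hypo_cf)
  c(out, list(exclusions = ch$exclusions))
}

#' Sensitivity analyses over alternative delirium definitions
#'
#' Repeats the primary analysis under the three sensitivity definitions and
#' summarizes concordance: classes whose adjusted signal status differs from
#' the primary analysis are marked discordant.
#'
#' @inheritParams run_primary
#' @param primary_table optional primary-analysis table (recomputed if NULL).
#' @return list with `table` (rows per class and definition, flag column
#'   marks discordance) and `exclusions`.
#' @export
run_sensitivity <- function(x, config = study_config(), primary_table = NULL) {
  ch <- prepare_cohort(x, config)
  if (is.null(primary_table)) primary_table <- run_primary(x, config)$table
  defs <- config$event_definitions[setdiff(names(config$event_definitions),
                                           "primary")]
  tables <- list()
  for (nm in names(defs)) {
    cases <- label_cases(ch$reports, defs[[nm]])
    out <- run_block(ch$reports, cases, ad_class_labels(config), config,
                     analysis_id = paste0("sensitivity:", nm),
                     outcome_name = nm,
                     joint = config$joint_exposure_model)
    primary_sig <- primary_table$signal[
      match(out$table$exposure, primary_table$exposure)]
    out$table$flags <- ifelse(out$table$signal == primary_sig,
                              "concordant", "discordant")
    tables[[nm]] <- out$table
  }
  tbl <- do.call(rbind, tables)
  rownames(tbl) <- NULL
  list(table = tbl, exclusions = ch$exclusions)
}

#' Positive/negative control validation
#'
#' Computes the adjusted r-OR of the positive-control exposure (natural
#' opium alkaloids by default) and the negative-control exposure
#' (bisphosphonates) under the primary delirium outcome, one model per
#' control. The opioid confounder column is computed excluding the
#' positive-control drugs (see [build_design_matrix()]). Validation passes
#' when the positive control is a signal and the negative control is not. A
#' control with no exposed report is "not_evaluable" (never a silent pass).
#'
#' @inheritParams run_primary
#' @return object of class `control_validation`: list with `positive`,
#'   `negative` (each a list with `estimate`, `status`) and `pass`.
#' @export
run_controls <- function(x, config = study_config()) {
  ch <- prepare_cohort(x, config)
  cases <- label_cases(ch$reports, config$event_definitions$primary)
  eval_control <- function(label) {
    expo <- label_exposure(ch$reports, label, config$class_map)
    if (sum(expo) == 0L) {
      return(list(estimate = NULL, status = "not_evaluable"))
    }
    tab <- ror_table(cases, expo)
    est <- tryCatch({
      design <- build_design_matrix(ch$reports, label, config$confounders,
                                    config$class_map)
      fit <- fit_logistic(design, cases,
                          tolerance = config$model$tolerance,
                          max_iter = config$model$max_iter)
      adjusted_ror(fit, label, tab$a)
    }, error = function(e) e)
    if (inherits(est, "error")) {
      return(list(estimate = NULL,
                  status = paste0("not_evaluable: ", conditionMessage(est))))
    }
    list(estimate = est, status = est$signal)
  }
  pos <- eval_control(config$controls$positive)
  neg <- eval_control(config$controls$negative)
  structure(list(positive = pos, negative = neg,
                 pass = identical(pos$status, "signal") &&
                   identical(neg$status, "no_signal"),
                 exclusions = ch$exclusions),
            class = "control_validation")
}

#' @export
print.control_validation <- function(x, ...) {
  fmt <- function(side, nm) {
    if (is.null(side$estimate)) {
      cat(sprintf("  %s control: %s\n", nm, side$status))
    } else {
      cat(sprintf("  %s control: %.2f [%.2f-%.2f] -> %s\n", nm,
                  side$estimate$point, side$estimate$ci_low,
                  side$estimate$ci_high, side$status))
    }
  }
  cat("<control_validation>", if (x$pass) "PASS" else "FAIL", "\n")
  fmt(x$positive, "positive")
  fmt(x$negative, "negative")
  invisible(x)
}

#' Run the full case/non-case study
#'
#' Orchestrates the requested analyses over one report set and one
#' configuration, producing a single study object that print/summary methods
#' and [export_results()] understand.
#'
#' @param x a `report_set`.
#' @param config a [study_config()].
#' @param analyses subset of c("primary", "per_drug", "age", "concomitant",
#'   "sensitivity", "controls").
#' @return object of class `pv_study`: list with `tables` (named list of
#'   analysis data.frames), `results` (all rows bound together), `controls`
#'   (a `control_validation` or NULL), `vif`, `exclusions`, `config`.
#' @export
run_study <- function(x, config = study_config(),
                      analyses = c("primary", "per_drug", "age",
                                   "concomitant", "sensitivity", "controls")) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  tables <- list()
  vif <- NULL
  exclusions <- NULL
  controls <- NULL

  primary <- NULL
  if ("primary" %in% analyses) {
    primary <- run_primary(x, config)
    tables$primary <- primary$table
    vif <- primary$vif
    exclusions <- primary$exclusions
  }
  if ("per_drug" %in% analyses) {
    pd <- run_per_drug(x, config)
    tables$per_drug <- pd$table
    if (is.null(vif)) vif <- pd$vif
    if (is.null(exclusions)) exclusions <- pd$exclusions
  }
  if ("age" %in% analyses) {
    tables$age <- run_age_subgroups(x, config)$table
  }
  if ("concomitant" %in% analyses) {
    tables$concomitant <- run_concomitant(x, config)$table
  }
  if ("sensitivity" %in% analyses) {
    tables$sensitivity <- run_sensitivity(
      x, config, primary_table = if (is.null(primary)) NULL else primary$table
    )$table
  }
  if ("controls" %in% analyses) {
    controls <- run_controls(x, config)
    if (is.null(exclusions)) exclusions <- controls$exclusions
  }
  results <- do.call(rbind, c(tables, list(make.row.names = FALSE)))

  structure(list(tables = tables, results = results, controls = controls,
                 vif = vif, exclusions = exclusions, config = config,
                 n_input_reports = n_reports(x)),
            class = "pv_study")
}

#' @export
print.pv_study <- function(x, ...) {
  cat("<pv_study>", x$n_input_reports, "input reports;",
      if (!is.null(x$exclusions)) paste(x$exclusions$n_after[nrow(x$exclusions)],
                                        "in cohort;") else "",
      if (is.null(x$results)) 0L else nrow(x$results), "analysis rows\n")
  cat("  analyses:", paste(names(x$tables), collapse = ", "), "\n")
  if (!is.null(x$controls)) {
    cat("  control validation:", if (x$controls$pass) "PASS" else "FAIL", "\n")
  }
  invisible(x)
}

#' @export
summary.pv_study <- function(object, digits = 2, ...) {
  df <- object$results
  if (!is.null(df) && nrow(df)) {
    df$crude <- sprintf("%.*f [%.*f-%.*f]", digits, df$crude_or,
                        digits, df$crude_lo, digits, df$crude_hi)
    df$adjusted <- ifelse(
      is.na(df$adj_or), "-",
      sprintf("%.*f [%.*f-%.*f]", digits, df$adj_or,
              digits, df$adj_lo, digits, df$adj_hi))
    df <- df[, c("analysis_id", "exposure", "n_exposed_cases",
                 "crude", "adjusted", "signal")]
  }
  structure(list(results = df, controls = object$controls,
                 exclusions = object$exclusions),
            class = "summary.pv_study")
}

#' @export
print.summary.pv_study <- function(x, ...) {
  if (!is.null(x$exclusions)) {
    cat("Cohort construction:\n")
    print(x$exclusions, row.names = FALSE)
    cat("\n")
  }
  cat("Reporting odds ratios (adjusted signal rule: lower 95% bound > 1):\n")
  print(x$results, row.names = FALSE)
  if (!is.null(x$controls)) {
    cat("\n")
    print(x$controls)
  }
  invisible(x)
}

# Polynomial rolling hash (mod 2^31) over the JSON form of the config; a
# provenance fingerprint, not a cryptographic hash.
config_hash <- function(config) {
  js <- as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      force = TRUE, digits = NA))
  bytes <- utf8ToInt(js)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Export study results
#'
#' Writes `results.csv` (the full analysis table), `forest.tsv` (label,
#' point, lo, hi, group — one row per analysis row, ready for forest
#' plotting), `exclusions.csv`, `vif.csv`, and `run_manifest.json` carrying
#' the seed, a config fingerprint, the package version and the number of
#' tests performed. Identical input and configuration produce byte-identical
#' files.
#'
#' @param study a `pv_study`.
#' @param out_dir output directory (created if needed).
#' @param formats subset of c("csv", "json", "forest_tsv", "markdown").
#' @return invisibly, character vector of written paths.
#' @export
export_results <- function(study, out_dir,
                           formats = c("csv", "json", "forest_tsv")) {
  stopifnot(inherits(study, "pv_study"))
  formats <- match.arg(formats, c("csv", "json", "forest_tsv", "markdown"),
                       several.ok = TRUE)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create directory ", out_dir,
                  call. = FALSE)
  }
  paths <- character()
  res <- study$results
  if (is.null(res)) {
    res <- data.frame(analysis_id = character(), exposure = character(),
                      adj_or = numeric(), adj_lo = numeric(),
                      adj_hi = numeric(), crude_or = numeric(),
                      crude_lo = numeric(), crude_hi = numeric())
  }

  if ("csv" %in% formats) {
    p <- file.path(out_dir, "results.csv")
    utils::write.csv(format_result_table(res), p, row.names = FALSE, na = "")
    paths <- c(paths, p)
    if (!is.null(study$exclusions)) {
      pe <- file.path(out_dir, "exclusions.csv")
      utils::write.csv(study$exclusions, pe, row.names = FALSE)
      paths <- c(paths, pe)
    }
    if (!is.null(study$vif)) {
      pv <- file.path(out_dir, "vif.csv")
      utils::write.csv(study$vif, pv, row.names = FALSE)
      paths <- c(paths, pv)
    }
  }
  if ("forest_tsv" %in% formats) {
    p <- file.path(out_dir, "forest.tsv")
    adj <- !is.na(res$adj_or)
    forest <- data.frame(
      label = paste0(res$exposure, " (", res$analysis_id, ")"),
      point = ifelse(adj, res$adj_or, res$crude_or),
      lo = ifelse(adj, res$adj_lo, res$crude_lo),
      hi = ifelse(adj, res$adj_hi, res$crude_hi),
      group = res$analysis_id,
      stringsAsFactors = FALSE)
    utils::write.table(format_result_table(forest), p, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if ("markdown" %in% formats) {
    p <- file.path(out_dir, "results.md")
    s <- summary(study)
    lines <- c("| analysis | exposure | exposed cases | crude | adjusted | signal |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %d | %s | %s | %s |",
                       s$results$analysis_id, s$results$exposure,
                       s$results$n_exposed_cases, s$results$crude,
                       s$results$adjusted, s$results$signal))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  if ("json" %in% formats) {
    p <- file.path(out_dir, "run_manifest.json")
    manifest <- list(
      seed = study$config$seed,
      config_hash = config_hash(study$config),
      package = "pvror",
      version = as.character(utils::packageVersion("pvror")),
      n_input_reports = study$n_input_reports,
      n_tests_performed = sum(!is.na(res$adj_or)),
      analyses = names(study$tables),
      exclusions = study$exclusions,
      vif = study$vif,
      control_pass = if (is.null(study$controls)) NULL else study$controls$pass
    )
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    paths <- c(paths, p)
  }
  invisible(paths)
}

# fixed 15-significant-digit formatting so exports are byte-stable across
# platforms and locales
format_result_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), NA_character_,
           formatC(v, digits = 15, format = "g"))
  })
  df
}
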
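# Study configuration: defaults, YAML loading, validation.

#' Construct a study configuration
#'
#' Collects every analysis choice of the case/non-case study: the composite
#' event definitions (primary plus three sensitivity definitions), the
#' antidepressant class map, the confounder dictionary, the control classes,
#' the age restriction and bands, the frequent-drug threshold, logistic-model
#' options and the seed.
#'
#' @param event_definitions named list of [event_definition()] objects; must
#'   include `primary`.
#' @param class_map a `class_map` ([default_class_map()]).
#' @param confounders data.frame of confounder specs ([default_confounders()]).
#' @param controls named list with `positive` and `negative` class labels.
#' @param min_age minimum age in years for cohort eligibility (default 65).
#' @param age_bands list of two-element numeric vectors partitioning
#'   `[min_age, Inf)`; default bands 65-74 and 75+.
#' @param frequent_drug_threshold per-drug report-count threshold for the
#'   per-drug analysis; drugs mentioned in strictly more than this many
#'   reports are analyzed (default 1000).
#' @param model list of logistic-fit options: `tolerance` (relative deviance
#'   change, default 1e-8), `max_iter` (default 100), `zero_cell_correction`
#'   ("haldane_anscombe" or "none").
#' @param joint_exposure_model if TRUE (default) the primary analysis fits one
#'   joint model with all six class indicators; if FALSE, one model per class.
#' @param seed integer seed recorded in exports.
#' @return object of class `study_config`.
#' @export
study_config <- function(event_definitions = default_event_definitions(),
                         class_map = default_class_map(),
                         confounders = default_confounders(),
                         controls = list(positive = "POS_CONTROL",
                                         negative = "NEG_CONTROL"),
                         min_age = 65L,
                         age_bands = list(c(65, 74), c(75, Inf)),
                         frequent_drug_threshold = 1000L,
                         model = list(tolerance = 1e-8, max_iter = 100L,
                                      zero_cell_correction = "haldane_anscombe"),
                         joint_exposure_model = TRUE,
                         seed = 20260921L) {
  if (!"primary" %in% names(event_definitions)) {
    stop("config validation error at event_definitions: 'primary' definition ",
         "is required", call. = FALSE)
  }
  for (nm in names(event_definitions)) {
    ed <- event_definitions[[nm]]
    if (!inherits(ed, "event_definition")) {
      event_definitions[[nm]] <- event_definition(nm, ed$terms %||% ed)
    }
  }
  validate_class_map(class_map)
  validate_confounders(confounders)
  for (side in c("positive", "negative")) {
    if (!controls[[side]] %in% names(class_map)) {
      stop("config validation error at controls.", side, ": class label '",
           controls[[side]], "' not in class_map", call. = FALSE)
    }
  }
  lo <- vapply(age_bands, `[`, numeric(1), 1L)
  hi <- vapply(age_bands, `[`, numeric(1), 2L)
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]; age_bands <- age_bands[ord]
  if (lo[1] != min_age || any(lo[-1] != hi[-length(hi)] + 1) ||
      hi[length(hi)] != Inf) {
    stop("config validation error at age_bands: bands must partition [",
         min_age, ", Inf)", call. = FALSE)
  }
  model$tolerance <- model$tolerance %||% 1e-8
  model$max_iter <- as.integer(model$max_iter %||% 100L)
  model$zero_cell_correction <- model$zero_cell_correction %||% "haldane_anscombe"
  if (!model$zero_cell_correction %in% c("haldane_anscombe", "none")) {
    stop("config validation error at model.zero_cell_correction: must be ",
         "'haldane_anscombe' or 'none'", call. = FALSE)
  }

  structure(list(event_definitions = event_definitions,
                 class_map = class_map,
                 confounders = confounders,
                 controls = controls,
                 min_age = as.integer(min_age),
                 age_bands = age_bands,
                 frequent_drug_threshold = as.integer(frequent_drug_threshold),
                 model = model,
                 joint_exposure_model = isTRUE(joint_exposure_model),
                 seed = as.integer(seed)),
            class = "study_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  event definitions:",
      paste(names(x$event_definitions), collapse = ", "), "\n")
  cat("  primary terms:",
      paste(x$event_definitions$primary$terms, collapse = " | "), "\n")
  cat("  classes:", paste(setdiff(names(x$class_map), CONTROL_CLASSES),
                          collapse = ", "), "\n")
  cat("  controls: positive =", x$controls$positive,
      ", negative =", x$controls$negative, "\n")
  cat("  min age:", x$min_age, "; bands:",
      paste(vapply(x$age_bands, function(b)
        paste0("[", b[1], ",", ifelse(is.finite(b[2]), b[2], "Inf"), "]"),
        character(1)), collapse = " "), "\n")
  cat("  confounders:", nrow(x$confounders),
      "; frequent-drug threshold:", x$frequent_drug_threshold, "\n")
  cat("  joint exposure model:", x$joint_exposure_model,
      "; seed:", x$seed, "\n")
  invisible(x)
}

#' Load a study configuration from a YAML (or JSON) file
#'
#' Any key absent from the file falls back to the package default, so an
#' empty file yields the full default configuration. Recognized top-level
#' keys: `event_definitions` (map name -> list of terms), `class_map` (map
#' label -> list with `drugs` and/or `atc_prefixes`), `confounders` (list of
#' `{label, kind, matcher}`), `controls`, `min_age`, `age_bands`,
#' `frequent_drug_threshold`, `model`, `joint_exposure_model`, `seed`.
#'
#' @param path YAML/JSON file path, or NULL for pure defaults.
#' @return validated `study_config`.
#' @export
load_study_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()

  unknown <- setdiff(names(raw),
                     c("event_definitions", "class_map", "confounders",
                       "controls", "age", "min_age", "age_bands",
                       "frequent_drug_threshold", "model",
                       "joint_exposure_model", "seed"))
  if (length(unknown)) {
    stop("config validation error at ", unknown[1], ": unknown key",
         call. = FALSE)
  }

  defs <- default_event_definitions()
  if (!is.null(raw$event_definitions)) {
    for (nm in names(raw$event_definitions)) {
      terms <- unlist(raw$event_definitions[[nm]])
      if (!length(terms)) {
        stop("config validation error at event_definitions.", nm,
             ": empty event definition", call. = FALSE)
      }
      defs[[nm]] <- event_definition(nm, terms)
    }
  }

  cm <- default_class_map()
  if (!is.null(raw$class_map)) {
    for (lbl in names(raw$class_map)) {
      if (!lbl %in% c(AD_CLASSES, CONTROL_CLASSES)) {
        stop("config validation error at class_map.", lbl,
             ": unknown class label (valid: ",
             paste(c(AD_CLASSES, CONTROL_CLASSES), collapse = ", "), ")",
             call. = FALSE)
      }
      entry <- raw$class_map[[lbl]]
      cm[[lbl]] <- list(
        drugs = norm_drug_name(unlist(entry$drugs) %||% character()),
        atc_prefixes = toupper(unlist(entry$atc_prefixes) %||% character())
      )
    }
  }

  cf <- default_confounders()
  if (!is.null(raw$confounders)) {
    cf <- do.call(rbind, lapply(raw$confounders, function(e) {
      data.frame(label = e$label %||% NA_character_,
                 kind = e$kind %||% NA_character_,
                 matcher = e$matcher %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }

  age <- raw$age %||% list()
  min_age <- raw$min_age %||% age$min %||% 65L
  bands <- raw$age_bands %||% age$bands
  age_bands <- if (is.null(bands)) list(c(65, 74), c(75, Inf)) else {
    lapply(bands, function(b) {
      b <- unlist(b)
      c(as.numeric(b[1]), if (is.na(b[2]) || b[2] %in% c("Inf", ".inf"))
        Inf else as.numeric(b[2]))
    })
  }

  controls <- utils::modifyList(list(positive = "POS_CONTROL",
                                     negative = "NEG_CONTROL"),
                                raw$controls %||% list())
  model <- utils::modifyList(list(tolerance = 1e-8, max_iter = 100L,
                                  zero_cell_correction = "haldane_anscombe"),
                             raw$model %||% list())

  study_config(event_definitions = defs, class_map = cm, confounders = cf,
               controls = controls, min_age = min_age, age_bands = age_bands,
               frequent_drug_threshold = raw$frequent_drug_threshold %||% 1000L,
               model = model,
               joint_exposure_model = raw$joint_exposure_model %||% TRUE,
               seed = raw$seed %||% 20260921L)
}
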
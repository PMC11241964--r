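# Study vocabularies: antidepressant class map, composite event definitions,
# confounder dictionary. All are configurable; these are the package defaults.

AD_CLASSES <- c("NSMRI", "SSRI", "SNRI", "MAOI", "ALPHA2", "OTHER")
CONTROL_CLASSES <- c("POS_CONTROL", "NEG_CONTROL")

#' Default antidepressant class map
#'
#' Maps each analysis class to drug names and/or ATC prefixes. Tricyclics and
#' related non-selective monoamine reuptake inhibitors (NSMRI) are ATC N06AA;
#' SSRIs are N06AB; MAOIs are N06AF (non-selective) plus N06AG (MAO-A
#' selective). SNRIs and alpha-2-adrenergic receptor antagonists have no ATC
#' level of their own (both sit in N06AX), so they are enumerated by name,
#' and the remaining N06AX members form the "other antidepressants" class.
#' The positive control class is natural opium alkaloids (N02AA); the
#' negative control class is bisphosphonates (M05BA).
#'
#' @return a `class_map`: named list with elements `drugs` (character vector)
#'   and `atc_prefixes` (character vector) per class label.
#' @export
default_class_map <- function() {
  cm <- list(
    NSMRI = list(drugs = character(), atc_prefixes = "N06AA"),
    SSRI = list(drugs = character(), atc_prefixes = "N06AB"),
    SNRI = list(drugs = c("venlafaxine", "desvenlafaxine", "duloxetine",
                          "milnacipran", "levomilnacipran"),
                atc_prefixes = character()),
    MAOI = list(drugs = character(), atc_prefixes = c("N06AF", "N06AG")),
    ALPHA2 = list(drugs = c("mirtazapine", "mianserin", "setiptiline"),
                  atc_prefixes = character()),
    OTHER = list(drugs = c("trazodone", "bupropion", "vortioxetine",
                           "agomelatine", "tianeptine", "nefazodone",
                           "vilazodone", "reboxetine", "hypericum"),
                 atc_prefixes = character()),
    POS_CONTROL = list(drugs = character(), atc_prefixes = "N02AA"),
    NEG_CONTROL = list(drugs = character(), atc_prefixes = "M05BA")
  )
  class(cm) <- "class_map"
  cm
}

validate_class_map <- function(cm, drug_dictionary = NULL,
                               where = "class_map") {
  known <- c(AD_CLASSES, CONTROL_CLASSES)
  unknown <- setdiff(names(cm), known)
  if (length(unknown)) {
    stop("config validation error at ", where, ": unknown class label(s): ",
         paste(unknown, collapse = ", "), " (valid: ",
         paste(known, collapse = ", "), ")", call. = FALSE)
  }
  for (lbl in names(cm)) {
    pfx <- cm[[lbl]]$atc_prefixes
    bad <- pfx[!is_valid_atc(pfx)]
    if (length(bad)) {
      stop("config validation error at ", where, ".", lbl,
           ".atc_prefixes: malformed ATC prefix: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  # the six antidepressant classes must be pairwise disjoint at drug-name level
  if (!is.null(drug_dictionary)) {
    members <- lapply(intersect(AD_CLASSES, names(cm)), function(lbl) {
      by_name <- cm[[lbl]]$drugs
      pfx <- cm[[lbl]]$atc_prefixes
      by_atc <- if (length(pfx)) {
        names(drug_dictionary)[vapply(drug_dictionary, function(codes) {
          any(outer(codes, pfx, startsWith))
        }, logical(1))]
      } else character()
      unique(c(by_name, by_atc))
    })
    all_members <- unlist(members)
    dup <- unique(all_members[duplicated(all_members)])
    if (length(dup)) {
      stop("config validation error at ", where,
           ": antidepressant classes overlap at drug-name level: ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
  }
  invisible(cm)
}

#' Map one drug entry to its analysis classes
#'
#' A class label matches if the drug name is listed for that class, or if any
#' of the entry's ATC codes starts with one of the class's ATC prefixes.
#' Drug-name matches are checked first, ATC prefixes second; the result is
#' the union. Non-matching drugs return an empty set.
#'
#' @param drug_name normalized drug name (string).
#' @param atc_codes character vector of ATC codes for the drug.
#' @param class_map a `class_map` (default [default_class_map()]).
#' @return character vector of class labels (possibly empty).
#' @export
map_drug_to_classes <- function(drug_name, atc_codes = character(),
                                class_map = default_class_map()) {
  drug_name <- norm_drug_name(drug_name)
  atc_codes <- toupper(atc_codes)
  hits <- vapply(class_map, function(cls) {
    if (drug_name %in% cls$drugs) return(TRUE)
    length(cls$atc_prefixes) > 0 && length(atc_codes) > 0 &&
      any(outer(atc_codes, cls$atc_prefixes, startsWith))
  }, logical(1))
  names(class_map)[hits]
}

#' Default composite event definitions for delirium
#'
#' The primary definition covers the preferred terms "Delirium",
#' "Confusional state" and "Disorientation". Three sensitivity definitions
#' bracket it: (i) drops "Disorientation"; (ii) adds "Circadian rhythm sleep
#' disorder"; (iii) further adds "Hallucinations". The four definitions nest:
#' (i) is a subset of primary, which is a subset of (ii), which is a subset
#' of (iii).
#'
#' @return named list of `event_definition` objects (`primary`, `sens_i`,
#'   `sens_ii`, `sens_iii`).
#' @export
default_event_definitions <- function() {
  defs <- list(
    primary = event_definition("primary",
                               c("Delirium", "Confusional state",
                                 "Disorientation")),
    sens_i = event_definition("sens_i", c("Delirium", "Confusional state")),
    sens_ii = event_definition("sens_ii",
                               c("Delirium", "Confusional state",
                                 "Disorientation",
                                 "Circadian rhythm sleep disorder")),
    sens_iii = event_definition("sens_iii",
                                c("Delirium", "Confusional state",
                                  "Disorientation",
                                  "Circadian rhythm sleep disorder",
                                  "Hallucinations"))
  )
  defs
}

#' Construct an event definition
#'
#' @param name definition label.
#' @param terms non-empty character vector of preferred terms; a report is a
#'   case under the definition if any of its event terms matches one of these
#'   (canonicalized, case-insensitive).
#' @return object of class `event_definition`.
#' @export
event_definition <- function(name, terms) {
  terms <- canonical_pt(terms)
  terms <- terms[nzchar(terms)]
  if (!length(terms)) {
    stop("config validation error: event definition '", name,
         "' has no terms", call. = FALSE)
  }
  structure(list(name = name, terms = terms), class = "event_definition")
}

#' Default confounder dictionary
#'
#' The adjustment set of the delirium study: co-prescriptions identified by
#' ATC prefix (opioids N02, antipsychotics N05A, anxiolytics N05B, hypnotics
#' N05C) and delirium-associated illnesses identified by a single preferred
#' term each, using the MedDRA spellings ("Hyponatraemia", "Hypoglycaemia").
#' Age band, sex and region are demographic adjustment factors handled by the
#' design-matrix builder, not listed here.
#'
#' @return data.frame with columns `label`, `kind` ("drug_atc" or
#'   "event_pt") and `matcher` (ATC prefix or preferred term).
#' @export
default_confounders <- function() {
  data.frame(
    label = c("opioids", "antipsychotics", "anxiolytics", "hypnotics",
              "constipation", "urinary_retention", "alcohol_use",
              "infection", "drug_misuse", "dementia", "dehydration",
              "hyponatraemia", "anticholinergic_syndrome", "hypoglycaemia",
              "seizure", "drug_abuse", "drug_dependence", "drug_withdrawal",
              "cns_vascular_disorder", "hearing_impaired", "visual_impairment"),
    kind = c(rep("drug_atc", 4), rep("event_pt", 17)),
    matcher = c("N02", "N05A", "N05B", "N05C",
                "Constipation", "Urinary retention", "Alcohol use",
                "Infection", "Drug misuse", "Dementia", "Dehydration",
                "Hyponatraemia", "Anticholinergic syndrome", "Hypoglycaemia",
                "Seizure", "Drug abuse", "Drug dependence",
                "Drug withdrawal syndrome", "Cerebrovascular accident",
                "Hypoacusis", "Visual impairment"),
    stringsAsFactors = FALSE
  )
}

validate_confounders <- function(cf, where = "confounders") {
  need <- c("label", "kind", "matcher")
  miss <- setdiff(need, names(cf))
  if (length(miss)) {
    stop("config validation error at ", where, ": missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad_kind <- setdiff(unique(cf$kind), c("drug_atc", "event_pt", "demographic"))
  if (length(bad_kind)) {
    stop("config validation error at ", where, ".kind: unknown kind: ",
         paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  atc <- cf$matcher[cf$kind == "drug_atc"]
  if (any(!is_valid_atc(atc))) {
    stop("config validation error at ", where, ".matcher: malformed ATC ",
         "prefix: ", paste(atc[!is_valid_atc(atc)], collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(trimws(cf$matcher[cf$kind == "event_pt"])))) {
    stop("config validation error at ", where,
         ".matcher: empty preferred term", call. = FALSE)
  }
  dup <- unique(cf$label[duplicated(cf$label)])
  if (length(dup)) {
    stop("config validation error at ", where, ": duplicate label(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  invisible(cf)
}

# Background (non-case) preferred terms used by the synthetic generator.
BACKGROUND_PTS <- c(
  "Nausea", "Rash", "Dizziness", "Headache", "Vomiting", "Pruritus",
  "Diarrhoea", "Fatigue", "Dyspnoea", "Oedema peripheral", "Cough",
  "Anaemia", "Hypotension", "Hypertension", "Pyrexia", "Arthralgia",
  "Renal impairment", "Fall", "Somnolence", "Dry mouth"
)
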
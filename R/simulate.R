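# Synthetic ICSR generator with known ground-truth drug -> event effects.
#
# Generative model (all on the logit scale, per report i):
#   confounders  Z_ij ~ Bernoulli(pi_j)
#   exposures    X_id ~ Bernoulli(plogis(alpha_d + sum_j delta_dj Z_ij))
#   case status  Y_i  ~ Bernoulli(plogis(beta0 + sum_d beta_d X_id + sum_j gamma_j Z_ij))
#   hyponatremia H_i  ~ Bernoulli(plogis(eta0 + sum_d eta_d X_id))
# so exp(beta_d) is exactly the conditional (adjusted) odds ratio the
# multivariate analysis estimates, and exp(eta_d) the hyponatremia-pathway OR.

#' Construct a synthetic-data generator configuration
#'
#' @param n_reports number of reports to generate.
#' @param drugs data.frame with columns `drug_name` and `alpha` (baseline
#'   exposure prevalence on the logit scale).
#' @param beta0 case-model intercept (logit of the baseline case probability).
#' @param beta named numeric vector of per-drug case log-odds-ratios; every
#'   name must appear in `drugs$drug_name`. Missing drugs get 0.
#' @param confounders data.frame (possibly empty) with columns `label`,
#'   `kind` ("event_pt" adds the PT to the report's events; "drug" adds a
#'   concomitant drug entry), `matcher` (the PT string or drug name),
#'   `prevalence` (pi_j), `gamma` (case-model log-OR), and one `delta_<drug>`
#'   column per generated drug (exposure-model log-OR), or a single `delta`
#'   column applied to all drugs.
#' @param eta0,eta hyponatremia-model intercept and named per-drug log-ORs.
#' @param p_age_band probability of the 65-74 age band (default 0.41, the
#'   observed share in large ICSR databases for this age range).
#' @param p_female probability of female sex (default 0.54).
#' @param p_sex_missing probability that sex is missing (default 0.005).
#' @param region_weights named 5-vector of region sampling weights, summing
#'   to 1.
#' @param case_terms named weight vector over the delirium preferred terms a
#'   case reports (one term is drawn per case).
#' @param background_pts character vector of non-case preferred terms;
#'   reports with an otherwise empty event list draw 1-3 of these.
#' @param role_probs named probabilities for drug roles
#'   (suspect/concomitant/interacting).
#' @param scenario free-text scenario label carried into the ground truth.
#' @param seed integer seed; the single RNG stream is drawn in a fixed order
#'   (demographics, confounders, drugs, case, hyponatremia, events).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_reports,
                             drugs,
                             beta0 = stats::qlogis(0.10),
                             beta = numeric(),
                             confounders = NULL,
                             eta0 = -Inf,
                             eta = numeric(),
                             p_age_band = 0.41,
                             p_female = 0.54,
                             p_sex_missing = 0.005,
                             region_weights = c(Africa = 0.05, Americas = 0.45,
                                                Asia = 0.10, Europe = 0.35,
                                                Oceania = 0.05),
                             case_terms = c("Delirium" = 0.3,
                                            "Confusional state" = 0.5,
                                            "Disorientation" = 0.2),
                             background_pts = BACKGROUND_PTS,
                             role_probs = c(suspect = 0.70,
                                            concomitant = 0.25,
                                            interacting = 0.05),
                             scenario = "custom",
                             seed = 1L) {
  if (!is.numeric(n_reports) || length(n_reports) != 1L || n_reports < 1) {
    stop("generator config error: n_reports must be a positive integer",
         call. = FALSE)
  }
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_name", "alpha") %in% names(drugs)))
  drugs$drug_name <- norm_drug_name(drugs$drug_name)
  if (anyDuplicated(drugs$drug_name)) {
    stop("generator config error: duplicate drug in drugs table", call. = FALSE)
  }
  unknown_beta <- setdiff(names(beta), drugs$drug_name)
  if (length(unknown_beta)) {
    stop("generator config error: case_model names a drug not in drugs: ",
         paste(unknown_beta, collapse = ", "), call. = FALSE)
  }
  full_beta <- stats::setNames(rep(0, nrow(drugs)), drugs$drug_name)
  full_beta[names(beta)] <- beta
  full_eta <- stats::setNames(rep(0, nrow(drugs)), drugs$drug_name)
  unknown_eta <- setdiff(names(eta), drugs$drug_name)
  if (length(unknown_eta)) {
    stop("generator config error: hyponatremia_model names a drug not in ",
         "drugs: ", paste(unknown_eta, collapse = ", "), call. = FALSE)
  }
  full_eta[names(eta)] <- eta

  probs <- c(p_age_band = p_age_band, p_female = p_female,
             p_sex_missing = p_sex_missing)
  if (any(probs < 0 | probs > 1)) {
    stop("generator config error: probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (length(region_weights) != 5L ||
      abs(sum(region_weights) - 1) > 1e-9 || any(region_weights < 0)) {
    stop("generator config error: region_weights must be a 5-vector of ",
         "non-negative weights summing to 1", call. = FALSE)
  }
  if (is.null(names(region_weights))) names(region_weights) <- DEFAULT_REGIONS

  if (is.null(confounders) || !nrow(as.data.frame(confounders))) {
    confounders <- data.frame(label = character(), kind = character(),
                              matcher = character(), prevalence = numeric(),
                              gamma = numeric(), stringsAsFactors = FALSE)
  } else {
    confounders <- as.data.frame(confounders, stringsAsFactors = FALSE)
    stopifnot(all(c("label", "kind", "matcher", "prevalence", "gamma")
                  %in% names(confounders)))
    if (any(confounders$prevalence < 0 | confounders$prevalence > 1)) {
      stop("generator config error: confounder prevalence must lie in [0, 1]",
           call. = FALSE)
    }
    if (any(!confounders$kind %in% c("event_pt", "drug"))) {
      stop("generator config error: confounder kind must be 'event_pt' or ",
           "'drug'", call. = FALSE)
    }
  }
  # one delta column per drug (delta_<drug>); a plain `delta` column fans out
  delta <- matrix(0, nrow(confounders), nrow(drugs),
                  dimnames = list(confounders$label, drugs$drug_name))
  if (nrow(confounders)) {
    if ("delta" %in% names(confounders)) {
      delta[] <- confounders$delta
    }
    for (d in drugs$drug_name) {
      col <- paste0("delta_", d)
      if (col %in% names(confounders)) delta[, d] <- confounders[[col]]
    }
  }

  if (abs(sum(role_probs) - 1) > 1e-9) {
    stop("generator config error: role_probs must sum to 1", call. = FALSE)
  }
  case_terms <- case_terms / sum(case_terms)

  structure(list(n_reports = as.integer(n_reports), drugs = drugs,
                 beta0 = beta0, beta = full_beta, confounders = confounders,
                 delta = delta, eta0 = eta0, eta = full_eta,
                 p_age_band = p_age_band, p_female = p_female,
                 p_sex_missing = p_sex_missing,
                 region_weights = region_weights, case_terms = case_terms,
                 background_pts = background_pts, role_probs = role_probs,
                 scenario = scenario, seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> scenario:", x$scenario, "| n =", x$n_reports,
      "| seed =", x$seed, "\n")
  cat("  drugs:", paste0(x$drugs$drug_name, " (OR ",
                         format(exp(x$beta), digits = 3), ")",
                         collapse = ", "), "\n")
  if (nrow(x$confounders)) {
    cat("  confounders:", paste(x$confounders$label, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ground truth of a generator configuration
#'
#' @param config a `generator_config`.
#' @return object of class `ground_truth`: data.frame keyed like
#'   `config$drugs` with the true adjusted odds ratio `true_or = exp(beta_d)`
#'   and the true hyponatremia-pathway odds ratio `true_hypo_or =
#'   exp(eta_d)`, plus a `scenario` attribute.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  gt <- data.frame(drug_name = config$drugs$drug_name,
                   true_or = unname(exp(config$beta)),
                   true_hypo_or = unname(exp(config$eta)),
                   stringsAsFactors = FALSE)
  attr(gt, "scenario") <- config$scenario
  class(gt) <- c("ground_truth", "data.frame")
  gt
}

#' Generate a synthetic ICSR database
#'
#' Draws `config$n_reports` reports from the logistic generative process
#' described in [generator_config()], in a fixed order from one seeded RNG
#' stream: demographics, confounder indicators, drug exposures, case status,
#' hyponatremia status, then event assembly. Every case reports one delirium
#' term; hyponatremic reports add "Hyponatraemia"; event-type confounders add
#' their PT; reports whose event list would otherwise be empty draw 1-3
#' background terms. Exposed drugs get a sampled role; drug-type confounders
#' enter as concomitant entries. ATC codes are resolved through the packaged
#' drug dictionary.
#'
#' @param config a `generator_config`.
#' @param drug_dictionary dictionary used to attach ATC codes.
#' @return list with elements `reports` (a [report_set()]) and `truth`
#'   (a `ground_truth`).
#' @export
generate_reports <- function(config,
                             drug_dictionary = read_drug_dictionary()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_reports
  drugs <- config$drugs$drug_name
  D <- length(drugs)
  cf <- config$confounders
  J <- nrow(cf)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  # 1. demographics
  band_young <- stats::rbinom(n, 1L, config$p_age_band) == 1L
  age <- integer(n)
  age[band_young] <- sample(65:74, sum(band_young), replace = TRUE)
  age[!band_young] <- sample(75:95, sum(!band_young), replace = TRUE)
  sex_missing <- stats::rbinom(n, 1L, config$p_sex_missing) == 1L
  female <- stats::rbinom(n, 1L, config$p_female) == 1L
  sex <- ifelse(sex_missing, NA_character_, ifelse(female, "F", "M"))
  region <- sample(names(config$region_weights), n, replace = TRUE,
                   prob = config$region_weights)

  # 2. confounder indicators
  Z <- matrix(0L, n, J, dimnames = list(NULL, cf$label))
  for (j in seq_len(J)) Z[, j] <- stats::rbinom(n, 1L, cf$prevalence[j])

  # 3. drug exposures
  X <- matrix(0L, n, D, dimnames = list(NULL, drugs))
  lin_x <- matrix(rep(config$drugs$alpha, each = n), n, D)
  if (J) lin_x <- lin_x + Z %*% config$delta
  for (d in seq_len(D)) X[, d] <- stats::rbinom(n, 1L, stats::plogis(lin_x[, d]))

  # 4. case status
  lin_y <- rep(config$beta0, n)
  if (D) lin_y <- lin_y + drop(X %*% config$beta)
  if (J) lin_y <- lin_y + drop(Z %*% cf$gamma)
  Y <- stats::rbinom(n, 1L, stats::plogis(lin_y)) == 1L

  # 5. hyponatremia status
  lin_h <- rep(config$eta0, n)
  if (D) lin_h <- lin_h + drop(X %*% config$eta)
  H <- stats::rbinom(n, 1L, stats::plogis(lin_h)) == 1L

  report_id <- sprintf("R%07d", seq_len(n))

  # 6. events (assembled column-wise; all residual randomness drawn here)
  ev_id <- character(0); ev_pt <- character(0)
  case_pt <- character(n)
  if (any(Y)) {
    case_pt[Y] <- sample(names(config$case_terms), sum(Y), replace = TRUE,
                         prob = config$case_terms)
  }
  ev_id <- c(ev_id, report_id[Y]); ev_pt <- c(ev_pt, case_pt[Y])
  ev_id <- c(ev_id, report_id[H])
  ev_pt <- c(ev_pt, rep("Hyponatraemia", sum(H)))
  ev_cf <- which(cf$kind == "event_pt")
  for (j in ev_cf) {
    hit <- Z[, j] == 1L
    ev_id <- c(ev_id, report_id[hit])
    ev_pt <- c(ev_pt, rep(cf$matcher[j], sum(hit)))
  }
  has_event <- report_id %in% unique(ev_id)
  need_bg <- !has_event
  if (any(need_bg)) {
    k <- sample(1:3, sum(need_bg), replace = TRUE)
    bg_id <- rep(report_id[need_bg], k)
    bg_pt <- sample(config$background_pts, sum(k), replace = TRUE)
    ev_id <- c(ev_id, bg_id); ev_pt <- c(ev_pt, bg_pt)
  }
  events <- data.frame(report_id = ev_id, pt = ev_pt,
                       stringsAsFactors = FALSE)
  events <- events[order(match(events$report_id, report_id)), , drop = FALSE]
  rownames(events) <- NULL

  # drug rows: exposures with sampled roles, then drug-type confounders
  dr_id <- character(0); dr_name <- character(0); dr_role <- character(0)
  for (d in seq_len(D)) {
    hit <- X[, d] == 1L
    n_hit <- sum(hit)
    if (!n_hit) next
    roles <- sample(names(config$role_probs), n_hit, replace = TRUE,
                    prob = config$role_probs)
    dr_id <- c(dr_id, report_id[hit])
    dr_name <- c(dr_name, rep(drugs[d], n_hit))
    dr_role <- c(dr_role, roles)
  }
  for (j in which(cf$kind == "drug")) {
    hit <- Z[, j] == 1L
    dr_id <- c(dr_id, report_id[hit])
    dr_name <- c(dr_name, rep(norm_drug_name(cf$matcher[j]), sum(hit)))
    dr_role <- c(dr_role, rep("concomitant", sum(hit)))
  }
  drug_df <- data.frame(report_id = dr_id, drug_name = dr_name,
                        atc_codes = "", role = dr_role,
                        stringsAsFactors = FALSE)
  drug_df <- suppressMessages(resolve_atc(drug_df, drug_dictionary))
  drug_df <- collapse_drug_rows(drug_df)
  drug_df <- drug_df[order(match(drug_df$report_id, report_id),
                           drug_df$drug_name), , drop = FALSE]
  rownames(drug_df) <- NULL

  reports_df <- data.frame(report_id = report_id, age_years = age,
                           sex = sex, region = region,
                           stringsAsFactors = FALSE)
  rs <- report_set(reports_df, drug_df, events,
                   provenance = paste0("synthetic:", config$scenario,
                                       ":seed", config$seed))
  list(reports = rs, truth = ground_truth(config))
}

#' Preset generator scenarios
#'
#' Named, fully specified generator configurations used for validation:
#' \describe{
#'   \item{null}{six class-representative antidepressants, all effects zero
#'     (every true OR is 1); baseline case prevalence 10\%.}
#'   \item{single_effect}{one drug (citalopram, baseline exposure 20\%) with
#'     true adjusted OR 3; no confounders; baseline case prevalence 8\%.}
#'   \item{confounded}{one drug with true direct OR 1, plus a dementia
#'     confounder (prevalence 0.30) with case effect log 3 and exposure
#'     effect log 3, inducing a spurious crude association.}
#'   \item{study_like}{six antidepressant classes with heterogeneous true
#'     ORs, opioid (morphine) co-prescription confounding, a dementia
#'     confounder, and an SSRI hyponatremia pathway; demographics match the
#'     41\%/59\% age-band split and 54\% female share.}
#'   \item{controls}{morphine (natural opium alkaloid, positive control) with
#'     true OR 3 and alendronate (bisphosphonate, negative control) with true
#'     OR 1.}
#' }
#'
#' @param name one of "null", "single_effect", "confounded", "study_like",
#'   "controls".
#' @param n_reports number of reports (default 20000).
#' @param seed integer seed (default 1).
#' @return a `generator_config`.
#' @export
preset_scenario <- function(name, n_reports = 20000L, seed = 1L) {
  valid <- c("null", "single_effect", "confounded", "study_like", "controls")
  if (!is.character(name) || length(name) != 1L || !name %in% valid) {
    stop("unknown preset '", name, "'; valid presets: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  study_drugs <- data.frame(
    drug_name = c("amitriptyline", "citalopram", "venlafaxine",
                  "moclobemide", "mirtazapine", "trazodone"),
    alpha = stats::qlogis(c(0.02, 0.05, 0.02, 0.005, 0.015, 0.05)),
    stringsAsFactors = FALSE
  )
  switch(
    name,
    null = generator_config(
      n_reports = n_reports, drugs = study_drugs,
      beta0 = stats::qlogis(0.10), scenario = "null", seed = seed),
    single_effect = generator_config(
      n_reports = n_reports,
      drugs = data.frame(drug_name = "citalopram",
                         alpha = stats::qlogis(0.20)),
      beta0 = stats::qlogis(0.08), beta = c(citalopram = log(3)),
      scenario = "single_effect", seed = seed),
    confounded = generator_config(
      n_reports = n_reports,
      drugs = data.frame(drug_name = "citalopram",
                         alpha = stats::qlogis(0.10)),
      beta0 = stats::qlogis(0.08), beta = c(citalopram = 0),
      confounders = data.frame(label = "dementia", kind = "event_pt",
                               matcher = "Dementia", prevalence = 0.30,
                               gamma = log(3), delta = log(3),
                               stringsAsFactors = FALSE),
      scenario = "confounded", seed = seed),
    study_like = generator_config(
      n_reports = n_reports, drugs = study_drugs,
      beta0 = stats::qlogis(0.08),
      beta = c(amitriptyline = log(2.0), citalopram = log(1.5),
               venlafaxine = 0, moclobemide = log(3.0),
               mirtazapine = log(1.3), trazodone = log(1.5)),
      confounders = data.frame(
        label = c("dementia", "opioid_rx"),
        kind = c("event_pt", "drug"),
        matcher = c("Dementia", "morphine"),
        prevalence = c(0.05, 0.25),
        gamma = c(log(3), log(2)),
        delta = c(log(2), log(1.5)),
        stringsAsFactors = FALSE),
      eta0 = stats::qlogis(0.02), eta = c(citalopram = log(4)),
      p_age_band = 0.41, p_female = 0.54,
      scenario = "study_like", seed = seed),
    controls = generator_config(
      n_reports = n_reports,
      drugs = data.frame(drug_name = c("morphine", "alendronate"),
                         alpha = stats::qlogis(c(0.20, 0.05))),
      beta0 = stats::qlogis(0.08),
      beta = c(morphine = log(3), alendronate = 0),
      scenario = "controls", seed = seed)
  )
}
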
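# Fixtures built in code: a tiny handcrafted line listing and helpers to
# expand 2x2 tables into report-level vectors.

# Two elderly reports: one SSRI-exposed delirium case, one unexposed rash.
tiny_report_set <- function() {
  report_set(
    reports = data.frame(
      report_id = c("R1", "R2"),
      age_years = c(70L, 81L),
      sex = c("F", "M"),
      region = c("Europe", "Americas"),
      stringsAsFactors = FALSE),
    drugs = data.frame(
      report_id = c("R1", "R1", "R2"),
      drug_name = c("citalopram", "morphine", "metformin"),
      atc_codes = c("N06AB04", "N02AA01", "A10BA02"),
      role = c("concomitant", "suspect", "suspect"),
      stringsAsFactors = FALSE),
    events = data.frame(
      report_id = c("R1", "R2"),
      pt = c("Confusional state", "Rash"),
      stringsAsFactors = FALSE),
    provenance = "fixture")
}

write_tiny_csvs <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  writeLines(c("report_id,age_years,sex,region",
               "R1,70,F,Europe",
               "R2,81,,Americas"),
             file.path(dir, "reports.csv"))
  writeLines(c("report_id,drug_name,atc_codes,role",
               "R1,citalopram,,concomitant",
               "R1,morphine,N02AA01,suspect",
               "R2,metformin,,suspect"),
             file.path(dir, "drugs.csv"))
  writeLines(c("report_id,pt",
               "R1,Confusional  state",
               "R1,Hyponatraemia",
               "R2,Rash"),
             file.path(dir, "events.csv"))
  dir
}

# Expand a 2x2 table (a exposed cases, b unexposed cases, c exposed
# non-cases, d unexposed non-cases) into case/exposure vectors.
expand_table <- function(a, b, c, d) {
  list(cases = c(rep(1L, a + b), rep(0L, c + d)),
       exposure = c(rep(1L, a), rep(0L, b), rep(1L, c), rep(0L, d)))
}

# Independent closed-form oracle for the crude OR and Woolf CI, written
# directly from the definition (kept separate from the package's estimator).
oracle_woolf <- function(a, b, c, d, z = 1.96) {
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(or = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se))
}
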
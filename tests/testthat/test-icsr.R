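# Data model, dictionaries, CSV line-listing I/O.

test_that("reading the line listing joins the three tables correctly", {
  dir <- write_tiny_csvs()
  rs <- read_reports(file.path(dir, "reports.csv"),
                     file.path(dir, "drugs.csv"),
                     file.path(dir, "events.csv"))
  expect_s3_class(rs, "report_set")
  expect_equal(n_reports(rs), 2L)
  expect_equal(nrow(rs$drugs), 3L)
  # empty ATC cell resolved through the dictionary
  expect_equal(rs$drugs$atc_codes[rs$drugs$drug_name == "citalopram"],
               "N06AB04")
  # empty sex cell becomes missing and is counted
  expect_true(is.na(rs$reports$sex[rs$reports$report_id == "R2"]))
  expect_equal(rs$counters$n_missing_sex, 1L)
  # internal whitespace in a PT is collapsed
  expect_true("Confusional state" %in% rs$events$pt)
})

test_that("integrity errors name the offending keys", {
  dir <- write_tiny_csvs()
  ev <- file.path(dir, "events.csv")
  writeLines(c(readLines(ev), "R99,Dizziness"), ev)
  expect_error(
    read_reports(file.path(dir, "reports.csv"), file.path(dir, "drugs.csv"),
                 ev),
    "R99")

  dir2 <- write_tiny_csvs()
  rp <- file.path(dir2, "reports.csv")
  writeLines(c(readLines(rp), "R1,77,M,Asia"), rp)
  expect_error(
    read_reports(rp, file.path(dir2, "drugs.csv"),
                 file.path(dir2, "events.csv")),
    "duplicate report_id.*R1")
})

test_that("missing required columns and event-less reports are rejected", {
  dir <- write_tiny_csvs()
  dg <- file.path(dir, "drugs.csv")
  writeLines(c("report_id,drug_name,role", "R1,citalopram,suspect"), dg)
  expect_error(
    read_reports(file.path(dir, "reports.csv"), dg,
                 file.path(dir, "events.csv")),
    "atc_codes")

  expect_error(
    report_set(
      data.frame(report_id = "R1", age_years = 70, sex = "F",
                 region = "Europe"),
      data.frame(report_id = character(), drug_name = character(),
                 atc_codes = character(), role = character()),
      data.frame(report_id = character(), pt = character())),
    "without any event")
})

test_that("write then read is the identity on report-set contents", {
  g <- generate_reports(preset_scenario("study_like", 100, seed = 42))
  dir <- withr::local_tempdir()
  write_reports(g$reports, dir)
  back <- read_reports(file.path(dir, "reports.csv"),
                       file.path(dir, "drugs.csv"),
                       file.path(dir, "events.csv"))
  expect_identical(back$reports, g$reports$reports)
  expect_identical(back$drugs, g$reports$drugs)
  expect_identical(back$events, g$reports$events)
  expect_identical(back$counters, g$reports$counters)
})

test_that("an empty report set round-trips as header-only files", {
  empty <- report_set(
    data.frame(report_id = character(), age_years = integer(),
               sex = character(), region = character()),
    data.frame(report_id = character(), drug_name = character(),
               atc_codes = character(), role = character()),
    data.frame(report_id = character(), pt = character()))
  dir <- withr::local_tempdir()
  write_reports(empty, dir)
  for (f in c("reports.csv", "drugs.csv", "events.csv")) {
    expect_length(readLines(file.path(dir, f)), 1L)
  }
  back <- read_reports(file.path(dir, "reports.csv"),
                       file.path(dir, "drugs.csv"),
                       file.path(dir, "events.csv"))
  expect_equal(n_reports(back), 0L)
})

test_that("multi-code ATC cells are semicolon-joined and round-trip as sets", {
  rs <- report_set(
    data.frame(report_id = "R1", age_years = 70, sex = "F",
               region = "Europe"),
    data.frame(report_id = "R1", drug_name = "fentanyl",
               atc_codes = "N02AB03;N01AH01", role = "suspect"),
    data.frame(report_id = "R1", pt = "Nausea"))
  dir <- withr::local_tempdir()
  write_reports(rs, dir)
  back <- read_reports(file.path(dir, "reports.csv"),
                       file.path(dir, "drugs.csv"),
                       file.path(dir, "events.csv"))
  expect_setequal(strsplit(back$drugs$atc_codes, ";")[[1]],
                  c("N01AH01", "N02AB03"))
})

test_that("duplicate drug rows collapse to the most causal role", {
  rs <- report_set(
    data.frame(report_id = "R1", age_years = 70, sex = "F",
               region = "Europe"),
    data.frame(report_id = c("R1", "R1"),
               drug_name = c("citalopram", "citalopram"),
               atc_codes = c("N06AB04", "N06AB04"),
               role = c("concomitant", "suspect")),
    data.frame(report_id = "R1", pt = "Nausea"))
  collapsed <- pvror:::collapse_drug_rows(rs$drugs)
  expect_equal(nrow(collapsed), 1L)
  expect_equal(collapsed$role, "suspect")
})

test_that("drug-to-class mapping follows names then ATC prefixes", {
  cm <- default_class_map()
  expect_equal(map_drug_to_classes("citalopram", "N06AB04", cm), "SSRI")
  expect_equal(map_drug_to_classes("morphine", "N02AA01", cm), "POS_CONTROL")
  expect_equal(map_drug_to_classes("mirtazapine", "N06AX11", cm), "ALPHA2")
  expect_equal(map_drug_to_classes("venlafaxine", "N06AX16", cm), "SNRI")
  expect_equal(map_drug_to_classes("trazodone", "N06AX05", cm), "OTHER")
  expect_length(map_drug_to_classes("metformin", "A10BA02", cm), 0L)
  # order of a report's drug list cannot matter: mapping is per-drug
  expect_equal(map_drug_to_classes("moclobemide", "N06AG02", cm), "MAOI")
})

test_that("ATC lexical validation accepts level prefixes only", {
  expect_true(all(is_valid_atc(c("N", "N06", "N06A", "N06AB", "N06AB04"))))
  expect_false(any(is_valid_atc(c("N0", "N06ABX", "6N06", "N06AB045", ""))))
})
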
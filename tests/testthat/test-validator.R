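test_that("normalization maps surface dialects onto canonical tokens", {
  rec <- normalize_record(list(record_id = "r1", topography = "C50.1",
                               morphology = "8050/2", pT = "is",
                               cN = "0", tnm_edition = "7"))
  expect_identical(rec$topography, "C501")
  expect_identical(rec$morphology, "M_8050")
  expect_identical(rec$behaviour, 2L)
  expect_identical(rec$pT, "PTis")
  expect_identical(rec$cN, "CN0")
  expect_identical(rec$edition, "TNMEd7")
  expect_length(rec$findings, 0L)

  # idempotence: feeding normalized values back changes nothing
  rec2 <- normalize_record(list(record_id = "r1", topography = rec$topography,
                                morphology = rec$morphology,
                                behaviour = rec$behaviour, pT = rec$pT,
                                cN = rec$cN, tnm_edition = rec$tnm_edition))
  for (f in c("topography", "morphology", "behaviour", "pT", "cN", "edition")) {
    expect_identical(rec2[[f]], rec[[f]], info = f)
  }
})

test_that("malformed codes yield V6 findings and an invalid verdict", {
  rec <- normalize_record(list(record_id = "r2", tnm_edition = "7",
                               topography = "C50.1", morphology = "815X/3"))
  expect_length(rec$findings, 1L)
  expect_identical(rec$findings[[1]]$check_id, "V6")
  rep <- validate_record(fixture_kb(), rec)
  expect_identical(rep$verdict, "invalid")
  expect_true(is.na(rep$inferred_stage))

  # contradictory behaviour field vs morphology suffix
  rec <- normalize_record(list(record_id = "r3", morphology = "8140/3",
                               behaviour = "2"))
  expect_length(report_errors(validate_record(fixture_kb(), rec), "V6"), 1L)
})

test_that("the worked breast example validates and stages to 0", {
  kb <- fixture_kb()
  rep <- validate_record(kb, normalize_record(fig8_raw()))
  expect_identical(rep$verdict, "valid")
  expect_identical(rep$inferred_site, "TNMSiteBreast")
  expect_identical(rep$inferred_stage, "0")
  expect_length(rep$findings, 0L)

  # same record with a contradicting declared stage
  raw <- fig8_raw(); raw$stage_group <- "IV"
  rep <- validate_record(kb, normalize_record(raw))
  expect_identical(rep$verdict, "invalid")
  errs <- report_errors(rep, "V5")
  expect_length(errs, 1L)
  expect_identical(errs[[1]]$expected, "0")
})

test_that("a T code outside the space blocks IIIC and raises V2", {
  kb <- fixture_kb()
  raw <- list(record_id = "iiic", tnm_edition = "7", topography = "C50.2",
              morphology = "8500", behaviour = "3", cT = "9", cN = "3",
              cM = "0", stage_group = "IIIC")
  rep <- validate_record(kb, normalize_record(raw))
  expect_identical(rep$verdict, "invalid")
  expect_length(report_errors(rep, "V2"), 1L)
  expect_false(identical(rep$inferred_stage, "IIIC"))

  # with a T inside the space the same N3/M0 record stages IIIC
  raw$cT <- "2"
  rep <- validate_record(kb, normalize_record(raw))
  expect_identical(rep$verdict, "valid")
  expect_identical(rep$inferred_stage, "IIIC")
})

test_that("stage-0 behaviour consistency is enforced (V3)", {
  kb <- fixture_kb()
  raw <- fig8_raw(); raw$morphology <- "8050/3"
  rep <- validate_record(kb, normalize_record(raw))
  expect_identical(rep$verdict, "invalid")
  expect_length(report_errors(rep, "V3"), 1L)
  expect_identical(report_errors(rep, "V3")[[1]]$expected, "2")
})

test_that("declared stages outside the site set raise V4 without V5", {
  kb <- fixture_kb()
  raw <- fig8_raw(); raw$stage_group <- "IVA"   # valid elsewhere, not breast
  rep <- validate_record(kb, normalize_record(raw))
  expect_length(report_errors(rep, "V4"), 1L)
  expect_length(report_errors(rep, "V5"), 0L)
  expect_setequal(report_errors(rep, "V4")[[1]]$expected,
                  stage_label(query_stage_groups(kb, "TNMSiteEd7Breast")))
})

test_that("records without TNM data are unstaged, unknown sites ineligible", {
  kb <- fixture_kb()
  rep <- validate_record(kb, normalize_record(
    list(record_id = "n1", tnm_edition = "7", topography = "C50.1",
         morphology = "8500", behaviour = "3")))
  expect_identical(rep$verdict, "unstaged")
  expect_length(rep$findings, 0L)
  expect_identical(rep$inferred_site, "TNMSiteBreast")

  rep <- validate_record(kb, normalize_record(
    list(record_id = "n2", tnm_edition = "7", topography = "C99.9",
         morphology = "8500", behaviour = "3", cT = "1", cN = "0", cM = "0")))
  expect_identical(rep$verdict, "ineligible")

  # kidney resolves a generic site but no edition site exists for it
  facts <- fact_set(data.frame(role = c("hasTopography", "hasMorphology"),
                               concept = c("C649", "M_8140")))
  expect_true("TNMSiteKidney" %in% saturate(kb, facts)$facts$derived)
  rep <- validate_record(kb, normalize_record(
    list(record_id = "n3", tnm_edition = "7", topography = "C64.9",
         morphology = "8140/3", cT = "1", cN = "0", cM = "0")))
  expect_identical(rep$verdict, "ineligible")
})

test_that("X codes pass the space check but abstain from staging", {
  kb <- fixture_kb()
  raw <- list(record_id = "x1", tnm_edition = "7", topography = "C50.1",
              morphology = "8500", behaviour = "3", cT = "X", cN = "3",
              cM = "0")
  rep <- validate_record(kb, normalize_record(raw))
  expect_length(report_errors(rep), 0L)
  expect_true(is.na(rep$inferred_stage))
  expect_identical(rep$verdict, "unstaged")
})

test_that("a declared coarse stage is accepted only under leniency", {
  kb <- fixture_kb()
  raw <- list(record_id = "l1", tnm_edition = "7", topography = "C50.1",
              morphology = "8500", behaviour = "3", pT = "2", pN = "3",
              pM = "0", stage_group = "III")
  rec <- normalize_record(raw)
  strict <- validate_record(kb, rec)
  # III itself is not a breast stage row, so strict mode rejects via V4
  expect_identical(strict$verdict, "invalid")
  expect_length(report_errors(strict, "V4"), 1L)
  lenient <- validate_record(kb, rec, lenient_stage = TRUE)
  expect_identical(lenient$verdict, "valid")
  expect_identical(lenient$inferred_stage, "IIIC")
})

test_that("the age-conditioned site stages differently across the threshold", {
  kb <- fixture_kb()
  base <- list(record_id = "a1", tnm_edition = "7", topography = "C73.9",
               morphology = "8050", behaviour = "3", pT = "3", pN = "1",
               pM = "0")
  base$age <- "40"
  s40 <- infer_stage(kb, normalize_record(base))
  base$age <- "60"
  s60 <- infer_stage(kb, normalize_record(base))
  expect_identical(stage_label(s40$stage), "I")
  expect_identical(stage_label(s60$stage), "III")
  base$age <- NULL
  expect_true(is.na(infer_stage(kb, normalize_record(base))$stage))
})

test_that("batch validation preserves order and ignores block size", {
  kb <- fixture_kb()
  entries <- generate_records(kb, per_site = 12L, seed = 31L)
  recs <- lapply(entries, function(e) e$record)
  base <- validate_batch(kb, recs, block_size = 100L)
  expect_identical(vapply(base, function(r) r$record_id, character(1)),
                   vapply(recs, function(r) r$record_id, character(1)))
  set.seed(5)
  for (bs in sample(1:25, 4L)) {
    expect_identical(validate_batch(kb, recs, block_size = bs), base)
  }
  # raw records are normalized in-batch
  raw <- lapply(entries, function(e) e$raw)
  expect_identical(validate_batch(kb, raw, block_size = 7L), base)
})

test_that("reasoner and direct modes return identical reports", {
  kb <- fixture_kb()
  entries <- generate_records(kb, per_site = 30L, seed = 13L)
  recs <- lapply(entries, function(e) e$record)
  expect_identical(validate_batch(kb, recs, mode = "reasoner"),
                   validate_batch(kb, recs, mode = "direct"))
})
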
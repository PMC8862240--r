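test_that("the worked correction example proposes Tis and behaviour 2", {
  kb <- fixture_kb()
  rec <- normalize_record(list(record_id = "c1", tnm_edition = "7",
                               topography = "C50.9", morphology = "8500",
                               behaviour = "3", pT = "1", pN = "0",
                               pM = "0", stage_group = "0"))
  rep <- validate_record(kb, rec)
  props <- propose_corrections(kb, rec, rep)
  by_field <- stats::setNames(props, vapply(props, `[[`, "", "field"))
  expect_setequal(names(by_field), c("T", "behaviour"))
  expect_identical(by_field$T$values, "Tis")
  expect_true(by_field$T$unique)
  expect_identical(by_field$behaviour$values, "2")
  expect_true(by_field$behaviour$unique)

  lines <- format_corrections(kb, rec, rep, props)
  expect_length(grep(">>", lines), 4L)        # one line per parameter
  expect_length(grep("!$", lines), 2L)        # errors flagged
  expect_match(lines[grep("^  T:", lines)], "Tis !")

  fixed <- apply_corrections(kb, rec, props, rep$edition_site)
  expect_identical(validate_record(kb, fixed)$verdict, "valid")
})

test_that("records without errors yield no proposals", {
  kb <- fixture_kb()
  rec <- normalize_record(fig8_raw())
  rep <- validate_record(kb, rec)
  expect_length(propose_corrections(kb, rec, rep), 0L)
})

test_that("an any-T stage lists the whole admissible set, non-unique", {
  kb <- fixture_kb()
  rec <- normalize_record(list(record_id = "c2", tnm_edition = "7",
                               topography = "C50.1", morphology = "8500",
                               behaviour = "3", cT = "9", cN = "3",
                               cM = "0", stage_group = "IIIC"))
  rep <- validate_record(kb, rec)
  expect_length(report_errors(rep, "V2"), 1L)
  props <- propose_corrections(kb, rec, rep)
  tprop <- Filter(function(p) p$field == "T", props)[[1]]
  expect_false(tprop$unique)
  # brute force: enumerate the code space, keep values satisfying the rule
  space <- kb$code_spaces[["TNMSiteEd7Breast.hasT"]]$codes
  want <- sort(unique(tnmkb:::generic_code(space)))
  want <- want[!tnmkb:::is_x_code(want)]
  expect_setequal(tprop$values, want)
})

test_that("applying all-unique proposals restores validity across a batch", {
  kb <- fixture_kb()
  entries <- generate_records(kb, per_site = 30L, seed = 99L)
  checked <- 0L
  for (e in entries) {
    if (e$label$scenario != "corrupted_parameter") next
    rep <- validate_record(kb, e$record)
    props <- propose_corrections(kb, e$record, rep)
    if (!length(props) || !all(vapply(props, `[[`, TRUE, "unique"))) next
    fixed <- apply_corrections(kb, e$record, props, rep$edition_site)
    expect_identical(validate_record(kb, fixed)$verdict, "valid",
                     info = e$record$record_id)
    checked <- checked + 1L
  }
  expect_gt(checked, 5L)
})
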
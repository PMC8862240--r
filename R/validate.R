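#' @title Record validation and staging
#' @description
#' Validation runs a fixed battery of checks per record:
#' \itemize{
#' \item V1 site resolution: topography + morphology + edition must derive
#'   exactly one edition-specific TNM site (none: verdict `ineligible`).
#' \item V2 code space: every present T/N/M code must lie in the site's
#'   declared code space for that category; clinical and pathological codes
#'   are both checked.
#' \item V3 behaviour/stage consistency: when every stage rule of the
#'   declared stage carries one behaviour literal (stage 0 requires
#'   behaviour 2, invasive stages behaviour 3), the record's behaviour must
#'   agree.
#' \item V4 declared stage must be among the site's permissible stage
#'   groups.
#' \item V5 declared stage must equal the most specific inferred stage when
#'   the T/N/M/behaviour values permit inference; a combination deriving no
#'   stage at all is also a V5 error.
#' \item V6 format findings attached during normalization.
#' }
#' Records with no TNM data (no category codes and no declared stage) get
#' verdict `unstaged` with no findings. Staging abstains when any category
#' code is an X ("cannot be assessed") code; X codes participate in the
#' code-space check only. When both clinical and pathological codes are
#' present for a category, stage inference uses the pathological code.
#' @name record_validator
NULL

record_assertions <- function(kb, rec, include_tnm = TRUE) {
  rows <- list()
  add <- function(role, concept) {
    if (!is.na(concept) && has_concept(kb, concept)) {
      rows[[length(rows) + 1L]] <<- data.frame(role = role, concept = concept,
                                               stringsAsFactors = FALSE)
    }
  }
  add("hasTopography", rec$topography)
  add("hasMorphology", rec$morphology)
  if (!is.na(rec$behaviour)) {
    add("hasBehaviour", paste0("BehaviourCode", rec$behaviour))
  }
  if (!is.na(rec$grade)) add("hasGrade", paste0("GradeCode", rec$grade))
  add("hasTNMEdition", rec$edition)
  if (include_tnm) {
    for (category in c("T", "N", "M")) {
      add(paste0("has", category), selected_code(rec, category))
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# pathological-first selection of the code used for stage inference
selected_code <- function(rec, category) {
  p <- rec[[paste0("p", category)]]
  if (!is.na(p)) p else rec[[paste0("c", category)]]
}

# direct (reasoner-free) derivation: indexed lookups over the compiled
# rules, mirroring the programme mode that pattern-matches the asserted
# axioms instead of saturating.
direct_derive <- function(kb, facts) {
  derived <- character()
  add <- function(id) {
    a <- kb$anc[[id]]
    derived <<- unique(c(derived, if (is.null(a)) id else a))
  }
  for (r in kb$rules) {
    if (!identical(r$origin, "site")) next
    if (all(vapply(r$lhs, function(l) literal_matches(kb, l, facts),
                   logical(1)))) add(r$rhs)
  }
  for (r in kb$rules) {
    if (!identical(r$origin, "edition_site")) next
    if (r$meta$site %in% derived &&
        literal_matches(kb, lit_exists("hasTNMEdition", r$meta$edition),
                        facts)) add(r$rhs)
  }
  for (cs in kb$code_spaces) {
    if (!cs$site %in% derived) next
    codes <- facts$assertions$concept[facts$assertions$role == cs$role]
    if (any(codes %in% cs$codes)) add(cs$space_concept)
  }
  for (es in intersect(derived, names(kb$stage_index))) {
    for (i in kb$stage_index[[es]]) {
      r <- kb$rules[[i]]
      ok <- all(vapply(r$lhs, function(l) {
        if (l$type == "atomic") l$concept %in% derived
        else literal_matches(kb, l, facts)
      }, logical(1)))
      if (ok) add(r$rhs)
    }
  }
  derived
}

derive_concepts <- function(kb, rec, mode) {
  facts <- fact_set(record_assertions(kb, rec), age = rec$age)
  if (identical(mode, "reasoner")) saturate(kb, facts)$facts$derived
  else direct_derive(kb, facts)
}

#' Infer TNM site and stage group for one record
#'
#' @param kb merged knowledge base.
#' @param rec a normalized record ([normalize_record()]).
#' @param mode `"reasoner"` (saturation) or `"direct"` (indexed rule
#'   lookup); both give identical results.
#' @return list with `edition_site`, `site`, `stage` (concept ids or `NA`),
#'   `stages_derived`, `inconsistent` (TRUE when two incomparable stages
#'   were derived, which indicates a rule-authoring error), and `abstained`
#'   (TRUE when an X code blocked stage inference).
#' @export
infer_stage <- function(kb, rec, mode = c("reasoner", "direct")) {
  mode <- match.arg(mode)
  derived <- derive_concepts(kb, rec, mode)
  esites <- derived[!is.na(kb$kind_of[derived]) &
                      kb$kind_of[derived] == "edition_site"]
  esid <- if (length(esites) == 1L) esites else NA_character_
  sel <- vapply(c("T", "N", "M"), function(cc) selected_code(rec, cc),
                character(1))
  all_present <- !anyNA(sel)
  any_x <- any(!is.na(sel) & is_x_code(sel))
  stages <- stage_concepts(kb, derived)
  ms <- most_specific(kb, stages)
  inconsistent <- length(ms) > 1L
  stage <- if (all_present && !any_x && length(ms) == 1L) ms else NA_character_
  list(edition_site = esid, all_edition_sites = sort(esites),
       site = if (!is.na(esid)) kb$es_info[[esid]]$site else NA_character_,
       stage = stage, stages_derived = sort(stages),
       inconsistent = inconsistent,
       abstained = any_x && all_present)
}

new_report <- function(rec, findings, site = NA_character_,
                       edition_site = NA_character_,
                       stage = NA_character_, verdict) {
  structure(
    list(record_id = rec$record_id, findings = findings,
         inferred_site = site, edition_site = edition_site,
         inferred_stage = if (is.na(stage)) NA_character_ else stage_label(stage),
         verdict = verdict),
    class = "tnm_report")
}

report_has_error <- function(report, checks = NULL) {
  any(vapply(report$findings, function(f) {
    finding_is_error(f) && (is.null(checks) || f$check_id %in% checks)
  }, logical(1)))
}

#' Validate one record against the knowledge base
#'
#' Runs checks V1-V6 (see [record_validator]) and stage inference, in
#' either execution mode. The two modes are contract-equivalent: they must
#' return identical reports.
#'
#' @inheritParams infer_stage
#' @param lenient_stage accept a declared coarse stage (e.g. `"III"`) when
#'   a sub-stage of it (e.g. `"IIIC"`) is inferred. Default strict.
#' @return object of class `tnm_report`: findings, inferred site and stage,
#'   and a verdict in `valid` / `invalid` / `unstaged` / `ineligible`.
#' @export
validate_record <- function(kb, rec, mode = c("reasoner", "direct"),
                            lenient_stage = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(rec, "tnm_record"))
  findings <- rec$findings
  if (length(findings)) {   # V6: malformed record, excluded from staging
    return(new_report(rec, findings, verdict = "invalid"))
  }
  has_tnm <- any(!is.na(unlist(rec[TNM_CODE_FIELDS]))) ||
    !is.na(rec$declared_stage)

  inf <- infer_stage(kb, rec, mode)
  if (!has_tnm) {
    return(new_report(rec, list(), site = inf$site,
                      edition_site = inf$edition_site,
                      verdict = "unstaged"))
  }
  if (length(inf$all_edition_sites) == 0L) {
    return(new_report(rec, list(), verdict = "ineligible"))
  }
  if (length(inf$all_edition_sites) > 1L) {
    findings <- c(findings, list(new_finding(
      "V1", "error", "topography",
      paste0("record resolves to more than one TNM site: ",
             paste(inf$all_edition_sites, collapse = ", ")),
      expected = inf$all_edition_sites)))
    return(new_report(rec, findings, verdict = "invalid"))
  }
  esid <- inf$edition_site

  # V2: code-space membership for every present code, clinical and
  # pathological alike
  for (field in TNM_CODE_FIELDS) {
    code <- rec[[field]]
    if (is.na(code)) next
    role <- paste0("has", substr(field, 2, 2))
    cs <- kb$code_spaces[[paste0(esid, ".", role)]]
    if (is.null(cs)) next
    if (!code %in% cs$codes) {
      findings <- c(findings, list(new_finding(
        "V2", "error", field,
        sprintf("%s is outside the %s code space of %s", code,
                space_suffix(role), esid),
        expected = sort(cs$codes))))
    }
  }

  permitted <- query_stage_groups(kb, esid)
  v4_failed <- FALSE
  if (!is.na(rec$declared_stage)) {
    permitted_ok <- rec$declared_stage %in% permitted ||
      (lenient_stage && any(vapply(permitted, function(p) {
        rec$declared_stage %in% ancestors(kb, p)
      }, logical(1))))
    if (!permitted_ok) {   # V4
      v4_failed <- TRUE
      findings <- c(findings, list(new_finding(
        "V4", "error", "stage_group",
        sprintf("stage group %s is not recognised for site %s",
                rec$declared_stage_label, esid),
        expected = stage_label(permitted))))
    } else if (!is.na(rec$behaviour)) {         # V3
      idx <- kb$stage_index[[esid]]
      rules <- Filter(function(r) identical(r$rhs, rec$declared_stage),
                      kb$rules[idx])
      behs <- unique(unlist(lapply(rules, function(r) r$meta$slots$behaviour)))
      if (length(behs) == 1L && !is.null(behs) && rec$behaviour != behs) {
        findings <- c(findings, list(new_finding(
          "V3", "error", "behaviour",
          sprintf("behaviour %d is inconsistent with stage %s (expected %d)",
                  rec$behaviour, rec$declared_stage_label, behs),
          expected = as.character(behs))))
      }
    }
  }

  if (inf$inconsistent) {
    findings <- c(findings, list(new_finding(
      "K1", "error", NA_character_,
      paste0("incomparable stages derived (rule-authoring error): ",
             paste(stage_label(inf$stages_derived), collapse = ", ")),
      expected = stage_label(inf$stages_derived))))
  }

  # V5: declared stage versus inference
  stage_match <- NA
  if (!is.na(rec$declared_stage) && !v4_failed) {
    if (!is.na(inf$stage)) {
      stage_match <- identical(rec$declared_stage, inf$stage) ||
        (lenient_stage && rec$declared_stage %in% ancestors(kb, inf$stage))
      if (!stage_match) {
        findings <- c(findings, list(new_finding(
          "V5", "error", "stage_group",
          sprintf("declared stage %s does not match inferred stage %s",
                  rec$declared_stage_label, stage_label(inf$stage)),
          expected = stage_label(inf$stage))))
      }
    } else {
      sel <- vapply(c("T", "N", "M"), function(cc) selected_code(rec, cc),
                    character(1))
      inferable <- !anyNA(sel) && !any(is_x_code(sel)) &&
        !any(vapply(findings, function(f) f$check_id %in% c("V2", "K1"),
                    logical(1)))
      if (inferable) {
        findings <- c(findings, list(new_finding(
          "V5", "error", "stage_group",
          sprintf("no stage group is derivable for the given T/N/M/behaviour combination (declared %s)",
                  rec$declared_stage_label))))
      }
    }
  }

  has_err <- any(vapply(findings, finding_is_error, logical(1)))
  verdict <- if (has_err) "invalid"
    else if (!is.na(rec$declared_stage) && isTRUE(stage_match)) "valid"
    else if (is.na(rec$declared_stage) && !is.na(inf$stage)) "valid"
    else "unstaged"
  new_report(rec, findings, site = inf$site, edition_site = esid,
             stage = inf$stage, verdict = verdict)
}

#' Validate a batch of records in blocks
#'
#' Records are ingested block-wise: each block's facts are inserted,
#' classified and fully retracted before the next block, so the output is
#' independent of `block_size` and its order equals the input order.
#' Per-record findings are reported, never raised; the batch never aborts.
#'
#' @inheritParams validate_record
#' @param records list of raw records (named lists) or `tnm_record`s.
#' @param block_size positive number of records per ingestion block.
#' @param verbose log block boundaries and counts via [message()].
#' @return list of `tnm_report`, one per input record, in input order.
#' @export
validate_batch <- function(kb, records, block_size = 100L,
                           mode = c("reasoner", "direct"),
                           lenient_stage = FALSE, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(block_size >= 1L)
  n <- length(records)
  reports <- vector("list", n)
  starts <- seq(1L, n, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, n)
    # block session: normalize + validate, then drop (full retraction)
    block <- lapply(records[idx], function(r) {
      if (inherits(r, "tnm_record")) r else normalize_record(r)
    })
    reports[idx] <- lapply(block, validate_record, kb = kb, mode = mode,
                           lenient_stage = lenient_stage)
    if (verbose) {
      message(sprintf("block %d-%d: %d record(s) processed", min(idx),
                      max(idx), length(idx)))
    }
  }
  reports
}

#' @export
print.tnm_report <- function(x, ...) {
  cat(sprintf("record %s: verdict %s", x$record_id, x$verdict))
  if (!is.na(x$inferred_site)) {
    cat(sprintf("  site %s", sub("^TNMSite", "", x$inferred_site)))
  }
  if (!is.na(x$inferred_stage)) cat(sprintf("  stage %s", x$inferred_stage))
  cat("\n")
  for (f in x$findings) {
    cat(sprintf("  [%s/%s] %s: %s\n", f$check_id, f$severity,
                f$field %||% "-", f$message))
  }
  invisible(x)
}

# flat data.frame rendering used by the CLI report writer
reports_to_df <- function(reports) {
  rows <- list()
  for (rep in reports) {
    rows[[length(rows) + 1L]] <- data.frame(
      record_id = rep$record_id, row_type = "summary", check_id = "",
      severity = "", field = "", message = "", expected = "",
      verdict = rep$verdict,
      inferred_site = rep$inferred_site %||% "",
      inferred_stage = rep$inferred_stage %||% "",
      stringsAsFactors = FALSE)
    for (f in rep$findings) {
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = rep$record_id, row_type = "finding",
        check_id = f$check_id, severity = f$severity,
        field = f$field %||% "", message = f$message,
        expected = paste(f$expected, collapse = "|"),
        verdict = "", inferred_site = "", inferred_stage = "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
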
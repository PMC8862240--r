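#' @title Error-correction proposals
#' @description
#' When a record fails validation but its declared stage group is among the
#' site's permissible stages, the stage is assumed correct and the error is
#' assumed to lie in the other parameters. For each stage rule of the
#' declared stage the expected value set of every mismatched field is
#' computed; a proposal is unique when exactly one value satisfies the
#' rules, in which case the correction can be applied automatically.
#' @name error_correction
NULL

CORRECTION_FIELDS <- c("T", "N", "M", "behaviour", "age")

# does the record satisfy rule r's constraint on one field?
slot_satisfied <- function(kb, rec, r, field, space_codes) {
  slots <- r$meta$slots
  if (field %in% c("T", "N", "M")) {
    sl <- slots[[field]]
    if (is.null(sl)) return(TRUE)
    code <- selected_code(rec, field)
    if (is.na(code)) return(FALSE)
    if (identical(sl$kind, "any")) {
      return(code %in% space_codes[[field]])
    }
    if (!has_concept(kb, code)) return(FALSE)
    sl$value %in% ancestors(kb, code)
  } else if (field == "behaviour") {
    b <- slots$behaviour
    is.null(b) || (!is.na(rec$behaviour) && rec$behaviour == b)
  } else if (field == "age") {
    a <- slots$age
    if (is.null(a)) return(TRUE)
    if (is.na(rec$age)) return(FALSE)
    switch(a$op, `<` = rec$age < a$value, `<=` = rec$age <= a$value,
           `>` = rec$age > a$value, `>=` = rec$age >= a$value)
  } else TRUE
}

site_space_codes <- function(kb, esid) {
  out <- list()
  for (category in c("T", "N", "M")) {
    cs <- kb$code_spaces[[paste0(esid, ".has", category)]]
    out[[category]] <- if (is.null(cs)) character() else cs$codes
  }
  out
}

# expected generic values for a failing field under one rule
slot_expected <- function(kb, r, field, space_codes) {
  slots <- r$meta$slots
  if (field %in% c("T", "N", "M")) {
    sl <- slots[[field]]
    if (is.null(sl)) return(character())
    if (identical(sl$kind, "any")) {
      vals <- unique(generic_code(space_codes[[field]]))
      return(sort(vals[!is_x_code(vals)]))
    }
    sl$value
  } else if (field == "behaviour") {
    as.character(slots$behaviour)
  } else if (field == "age") {
    a <- slots$age
    paste0(a$op, a$value)
  } else character()
}

#' Propose corrections for a failed record
#'
#' Applicable when the report carries V2/V3/V5 errors and the declared
#' stage group is present and permissible for the site. Stage rules of the
#' declared stage are ranked by how few record fields violate them; for the
#' minimally violated rules, the expected value set of each violated field
#' is collected. A proposal with a single admissible value is flagged
#' unique.
#'
#' @param kb merged knowledge base.
#' @param rec a normalized `tnm_record`.
#' @param report the record's `tnm_report` from [validate_record()].
#' @return list of proposals, each `list(field, values, unique)`; empty
#'   when the record has no correctable error or no stage rule applies.
#' @export
propose_corrections <- function(kb, rec, report) {
  if (!report_has_error(report, c("V2", "V3", "V5"))) return(list())
  if (is.na(rec$declared_stage)) return(list())
  if (report_has_error(report, "V4")) return(list())
  esid <- report$edition_site
  if (is.na(esid)) return(list())
  idx <- kb$stage_index[[esid]]
  rules <- Filter(function(r) identical(r$rhs, rec$declared_stage),
                  kb$rules[idx])
  if (!length(rules)) return(list())
  spaces <- site_space_codes(kb, esid)
  fails <- lapply(rules, function(r) {
    Filter(function(f) !slot_satisfied(kb, rec, r, f, spaces),
           CORRECTION_FIELDS)
  })
  k <- min(lengths(fails))
  if (k == 0L) return(list())
  cand <- which(lengths(fails) == k)
  fields <- unique(unlist(fails[cand]))
  out <- list()
  for (f in fields) {
    vals <- character()
    for (i in cand) {
      if (f %in% fails[[i]]) {
        vals <- c(vals, slot_expected(kb, rules[[i]], f, spaces))
      }
    }
    vals <- sort(unique(vals))
    out[[length(out) + 1L]] <- list(field = f, values = vals,
                                    unique = length(vals) == 1L)
  }
  out
}

#' Apply unique correction proposals to a record
#'
#' Every proposal flagged unique is written back into the record: T/N/M
#' values replace the clinical or pathological field the original value
#' came from (pathological preferred when the field was empty), using the
#' code of the site's space that specialises the proposed generic value
#' with the same C/P prefix when available.
#'
#' @inheritParams propose_corrections
#' @param proposals result of [propose_corrections()].
#' @param edition_site the record's resolved edition site.
#' @return the corrected `tnm_record`.
#' @export
apply_corrections <- function(kb, rec, proposals, edition_site) {
  spaces <- site_space_codes(kb, edition_site)
  for (p in proposals) {
    if (!isTRUE(p$unique)) next
    v <- p$values[[1]]
    if (p$field %in% c("T", "N", "M")) {
      pfield <- paste0("p", p$field)
      cfield <- paste0("c", p$field)
      src <- if (!is.na(rec[[pfield]]) || is.na(rec[[cfield]])) pfield else cfield
      prefix <- toupper(substr(src, 1, 1))
      pool <- spaces[[p$field]]
      pool <- pool[vapply(pool, function(cd) v %in% ancestors(kb, cd),
                          logical(1))]
      pick <- pool[startsWith(pool, prefix)]
      if (!length(pick)) {
        pick <- pool
        src <- if (any(startsWith(pool, "P"))) pfield else cfield
      }
      if (length(pick)) {
        # most generic matching code of the preferred prefix
        rec[[src]] <- sort(pick)[[1]]
        other <- setdiff(c(pfield, cfield), src)
        rec[[other]] <- NA_character_
      }
    } else if (p$field == "behaviour") {
      rec$behaviour <- as.integer(v)
    }
  }
  rec
}

#' Render a correction report
#'
#' One line per staging parameter in the style `input >> expected` with a
#' highlighted `!` marking the fields found incorrect; parameters that
#' already agree repeat their value after the chevrons.
#'
#' @inheritParams apply_corrections
#' @return character vector of report lines (also printed when
#'   `print = TRUE`).
#' @param report the record's validation report.
#' @param print print the lines to the console.
#' @export
format_corrections <- function(kb, rec, report, proposals, print = FALSE) {
  prop_of <- stats::setNames(
    lapply(proposals, function(p) p$values),
    vapply(proposals, function(p) p$field, character(1)))
  lines <- sprintf("record %s  site %s  declared stage %s",
                   rec$record_id,
                   sub("^TNMSite", "", report$inferred_site %||% "?"),
                   rec$declared_stage_label)
  show <- function(label, input, field) {
    exp_vals <- prop_of[[field]]
    if (is.null(exp_vals)) {
      sprintf("  %-10s %-6s >> %s", paste0(label, ":"), input, input)
    } else {
      sprintf("  %-10s %-6s >> %s !", paste0(label, ":"), input,
              paste(exp_vals, collapse = " | "))
    }
  }
  for (category in c("T", "N", "M")) {
    code <- selected_code(rec, category)
    lines <- c(lines, show(category, if (is.na(code)) "-" else code, category))
  }
  lines <- c(lines, show("behaviour",
                         if (is.na(rec$behaviour)) "-" else rec$behaviour,
                         "behaviour"))
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
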
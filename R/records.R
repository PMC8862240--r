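#' @title Case records: normalization and CSV dialect
#' @description
#' A registry case record carries ICD-O-3 topography, morphology and
#' behaviour, optional grade and age, the TNM edition, optional clinical
#' and pathological T/N/M category codes, and an optional declared stage
#' group. Raw field values arrive in several surface dialects (dotted
#' topography `C50.1`, combined morphology `8050/2`, unprefixed category
#' codes like `1a` or `is`); normalization maps them onto the canonical
#' concept tokens used by the knowledge base. Malformed values yield a
#' format finding (check V6) and exclude the record from staging.
#' @name record_normalization
NULL

RECORD_CSV_COLUMNS <- c("record_id", "tnm_edition", "topography", "morphology",
                        "behaviour", "grade", "age",
                        "cT", "cN", "cM", "pT", "pN", "pM", "stage_group")

TNM_CODE_FIELDS <- c("cT", "cN", "cM", "pT", "pN", "pM")

new_finding <- function(check_id, severity, field, message,
                        expected = character()) {
  list(check_id = check_id, severity = severity, field = field,
       message = message, expected = expected)
}

finding_is_error <- function(f) identical(f$severity, "error")

blank_to_na <- function(x) {
  if (is.null(x) || length(x) == 0) return(NA_character_)
  x <- trimws(as.character(x[[1]]))
  if (!nzchar(x) || is.na(x)) NA_character_ else x
}

#' Stage concept id for a printed stage label, and back
#'
#' @param label stage label as printed in registry data (`"0"`, `"IA"`,
#'   `"IIIC"`, ...).
#' @return concept id, e.g. `"TNMStageIIIC"`.
#' @export
stage_concept <- function(label) paste0("TNMStage", toupper(label))

#' @rdname stage_concept
#' @param concept a stage concept id.
#' @export
stage_label <- function(concept) sub("^TNMStage", "", concept)

# generic form of a C/P-prefixed category code: PT1a -> T1a, CN0 -> N0
generic_code <- function(id) sub("^[CP](?=[TNM])", "", id, perl = TRUE)

is_x_code <- function(id) grepl("X$", id)

# normalize one T/N/M value for a given category ("T","N","M") and
# clinical/pathological prefix ("C"/"P"); NULL when malformed.
normalize_tnm_code <- function(value, category, prefix) {
  v <- toupper(gsub("[[:space:]]", "", value))
  v <- sub(paste0("^[CP]?", category), "", v)   # strip any C/P + category letter
  if (v == "IS") v <- "is"
  v <- sub("MI$", "mi", v)
  v <- sub("^([0-9])([A-E])$", "\\1\\L\\2", v, perl = TRUE)
  pat <- switch(category,
    T = "^([0-9][a-e]?|[0-9]mi|is|X)$",
    N = "^([0-9][a-e]?|[0-9]mi|X)$",
    M = "^([0-9]|X)$")
  if (!grepl(pat, v)) return(NULL)
  paste0(prefix, category, v)
}

#' Normalize a raw record into canonical form
#'
#' Strips dots from topography codes (`C50.1` to `C501`), splits combined
#' morphology/behaviour values (`8140/3` to morphology `M_8140` plus
#' behaviour 3), upper-cases T/N/M codes and attaches the C/P prefix
#' according to the clinical/pathological field of origin, and maps the
#' declared stage label to its concept. Already-normalized input passes
#' through unchanged (idempotent). Malformed values produce V6 findings.
#'
#' @param raw named list or character vector of raw field values; must
#'   contain `record_id`. Recognised fields: `r RECORD_CSV_COLUMNS`.
#' @return object of class `tnm_record` with normalized fields and any V6
#'   findings attached.
#' @export
normalize_record <- function(raw) {
  raw <- as.list(raw)
  if (is.null(raw$record_id) || !nzchar(blank_to_na(raw$record_id) %||% "")) {
    stop("record_id is required")
  }
  findings <- list()
  bad <- function(field, msg) {
    findings[[length(findings) + 1L]] <<-
      new_finding("V6", "error", field, msg)
  }
  rec <- list(record_id = blank_to_na(raw$record_id))

  ed <- blank_to_na(raw$tnm_edition)
  rec$tnm_edition <- NA_integer_
  rec$edition <- NA_character_
  if (!is.na(ed)) {
    edn <- suppressWarnings(as.integer(sub("^TNMEd", "", ed)))
    if (is.na(edn)) bad("tnm_edition", paste0("malformed TNM edition: ", ed))
    else { rec$tnm_edition <- edn; rec$edition <- paste0("TNMEd", edn) }
  }

  top <- blank_to_na(raw$topography)
  rec$topography <- NA_character_
  if (!is.na(top)) {
    t2 <- toupper(gsub("[.[:space:]]", "", top))
    if (grepl("^C[0-9]{2,3}$", t2)) rec$topography <- t2
    else bad("topography", paste0("malformed topography code: ", top))
  }

  morph <- blank_to_na(raw$morphology)
  beh <- blank_to_na(raw$behaviour)
  rec$morphology <- NA_character_
  slash_beh <- NA_character_
  if (!is.na(morph)) {
    m2 <- sub("^M[_-]", "", toupper(gsub("[[:space:]]", "", morph)))
    if (grepl("/", m2, fixed = TRUE)) {
      parts <- strsplit(m2, "/", fixed = TRUE)[[1]]
      m2 <- parts[[1]]
      slash_beh <- if (length(parts) == 2) parts[[2]] else "?"
    }
    if (grepl("^[0-9]{3,4}$", m2)) rec$morphology <- paste0("M_", m2)
    else bad("morphology", paste0("malformed morphology code: ", morph))
  }
  rec$behaviour <- NA_integer_
  eff_beh <- if (!is.na(beh)) beh else slash_beh
  if (!is.na(eff_beh)) {
    if (grepl("^[012369]$", eff_beh)) {
      rec$behaviour <- as.integer(eff_beh)
      if (!is.na(beh) && !is.na(slash_beh) && beh != slash_beh) {
        bad("behaviour", sprintf(
          "behaviour field (%s) contradicts morphology suffix (/%s)",
          beh, slash_beh))
      }
    } else bad("behaviour", paste0("malformed behaviour code: ", eff_beh))
  }

  gr <- blank_to_na(raw$grade)
  rec$grade <- NA_integer_
  if (!is.na(gr)) {
    if (grepl("^[1-49]$", gr)) rec$grade <- as.integer(gr)
    else bad("grade", paste0("malformed grade: ", gr))
  }

  ag <- blank_to_na(raw$age)
  rec$age <- NA_real_
  if (!is.na(ag)) {
    agn <- suppressWarnings(as.numeric(ag))
    if (is.na(agn) || agn < 0 || agn > 130) {
      bad("age", paste0("implausible age: ", ag))
    } else rec$age <- agn
  }

  for (field in TNM_CODE_FIELDS) {
    val <- blank_to_na(raw[[field]])
    rec[[field]] <- NA_character_
    if (!is.na(val)) {
      category <- substr(field, 2, 2)
      prefix <- toupper(substr(field, 1, 1))
      code <- normalize_tnm_code(val, category, prefix)
      if (is.null(code)) bad(field, paste0("malformed ", category,
                                           " code: ", val))
      else rec[[field]] <- code
    }
  }

  st <- blank_to_na(raw$stage_group)
  rec$declared_stage <- NA_character_
  rec$declared_stage_label <- NA_character_
  if (!is.na(st)) {
    s2 <- toupper(gsub("[[:space:]]", "", sub("^TNMStage", "", st)))
    if (grepl("^(0|(I|II|III|IV)[A-C]?)$", s2)) {
      rec$declared_stage <- stage_concept(s2)
      rec$declared_stage_label <- s2
    } else bad("stage_group", paste0("malformed stage group: ", st))
  }

  rec$findings <- findings
  structure(rec, class = "tnm_record")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' @export
print.tnm_record <- function(x, ...) {
  cat(sprintf("case record %s: top=%s morph=%s beh=%s ed=%s\n",
              x$record_id, x$topography, x$morphology, x$behaviour,
              x$edition))
  codes <- unlist(x[TNM_CODE_FIELDS])
  codes <- codes[!is.na(codes)]
  cat(sprintf("  codes: %s  declared stage: %s\n",
              if (length(codes)) paste(codes, collapse = " ") else "none",
              x$declared_stage_label))
  if (length(x$findings)) {
    cat(sprintf("  %d format finding(s)\n", length(x$findings)))
  }
  invisible(x)
}

#' Read and write the record CSV dialect
#'
#' The batch CSV has header
#' `record_id,tnm_edition,topography,morphology,behaviour,grade,age,cT,cN,cM,pT,pN,pM,stage_group`;
#' the empty string means an absent value.
#'
#' @param path file path.
#' @return `read_records_csv`: list of raw records (named character lists).
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("record_id"), names(df))
  if (length(missing_cols)) {
    stop("input CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' @rdname read_records_csv
#' @param records list of raw records (named lists of strings).
#' @export
write_records_csv <- function(records, path) {
  rows <- lapply(records, function(r) {
    vals <- vapply(RECORD_CSV_COLUMNS, function(cl) {
      v <- blank_to_na(r[[cl]])
      if (is.na(v)) "" else v
    }, character(1))
    as.data.frame(as.list(vals), stringsAsFactors = FALSE,
                  col.names = RECORD_CSV_COLUMNS)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
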
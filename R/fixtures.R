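#' @title Packaged knowledge base and independent stage-table oracle
#' @description
#' The package ships a fixture knowledge base transcribed from the printed
#' edition-7 axioms: the breast stage table with its 28-code T space, the
#' kidney site rule, the morphology groupings (mesothelioma, basal cell
#' carcinoma, adenocarcinoma under carcinoma), behaviour codes, and one
#' synthetic age-conditioned site. A second, independent transcription of
#' the breast stage table (a plain CSV consulted by direct row lookup) is
#' used as a test oracle against the rule engine.
#' @name fixtures_synthetic
NULL

.tnmkb_cache <- new.env(parent = emptyenv())

#' Build the packaged fixture knowledge base
#'
#' Loads the rule modules shipped under `extdata/kb` and merges them. The
#' result is cached per session (the merge is deterministic).
#'
#' @param force rebuild even if cached.
#' @return a `tnm_kb`.
#' @examples
#' kb <- build_paper_kb()
#' query_stage_groups(kb, "TNMSiteEd7Breast")
#' @export
build_paper_kb <- function(force = FALSE) {
  if (!force && !is.null(.tnmkb_cache$kb)) return(.tnmkb_cache$kb)
  dir <- system.file("extdata", "kb", package = "tnmkb")
  mods <- load_modules(dir)
  kb <- merge_imports("encr_fixture_root", mods)
  .tnmkb_cache$kb <- kb
  kb
}

#' The independent breast stage-table transcription
#'
#' Rows of the edition-7 breast stage-group table, one row per printed
#' combination; cells list the exact generic codes they cover, separated by
#' `;`, with `ANY` standing for the whole site-specific code space.
#'
#' @return data.frame with columns `stage`, `T`, `N`, `M`, `behaviour`.
#' @export
breast_stage_table <- function() {
  path <- system.file("extdata", "breast_ed7_stage_table.csv",
                      package = "tnmkb")
  utils::read.csv(path, colClasses = c("character", "character", "character",
                                       "character", "integer"),
                  check.names = FALSE)
}

# generic (prefix-free) code spaces for breast edition 7, transcribed
# directly from the printed axioms and table rows -- kept separate from the
# compiled KB so the oracle does not depend on the engine.
BREAST_ED7_GENERIC_SPACES <- list(
  T = c("T0", "T1", "T1a", "T1b", "T1c", "T1mi", "T2", "T3",
        "T4", "T4a", "T4b", "T4c", "T4d", "TX", "Tis"),
  N = c("N0", "N1", "N1mi", "N2", "N3", "NX"),
  M = c("M0", "M1")
)

#' Stage lookup oracle over the transcribed breast table
#'
#' Independent of the rule engine: the record's T/N/M codes are stripped of
#' their clinical/pathological prefix and looked up row by row in the
#' transcription; `ANY` cells expand to the site-specific generic code
#' space. Any X ("cannot be assessed") code abstains. Used as a test oracle
#' only.
#'
#' @param table result of [breast_stage_table()].
#' @param rec a normalized edition-7 breast `tnm_record`.
#' @return stage label (`"0"`, `"IA"`, ...) or `NA` when no row matches.
#' @export
brute_force_stage_oracle <- function(table, rec) {
  sel <- vapply(c("T", "N", "M"), function(category) {
    p <- rec[[paste0("p", category)]]
    if (!is.na(p)) p else rec[[paste0("c", category)]]
  }, character(1))
  if (anyNA(sel)) return(NA_character_)
  gen <- generic_code(sel)
  if (any(is_x_code(gen))) return(NA_character_)
  if (is.na(rec$behaviour)) return(NA_character_)
  for (i in seq_len(nrow(table))) {
    ok <- TRUE
    for (j in seq_along(c("T", "N", "M"))) {
      category <- c("T", "N", "M")[[j]]
      cell <- table[[category]][[i]]
      members <- if (identical(cell, "ANY")) {
        BREAST_ED7_GENERIC_SPACES[[category]]
      } else strsplit(cell, ";", fixed = TRUE)[[1]]
      if (!gen[[j]] %in% members) { ok <- FALSE; break }
    }
    if (ok && rec$behaviour == table$behaviour[[i]]) {
      return(table$stage[[i]])
    }
  }
  NA_character_
}
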
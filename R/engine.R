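#' @title Saturation engine
#' @description
#' Forward-chaining over the compiled GCIs: starting from a fact set (role
#' assertions plus an optional age), every rule whose left-hand side is
#' fully matched fires, adding its right-hand concept and that concept's
#' hierarchy ancestors to the derived set, until a least fixpoint is
#' reached. The result is independent of rule order because firing is
#' monotone and idempotent. An inference trace records each firing so a
#' verdict can be explained and replayed.
#' @name subsumption_engine
NULL

#' Construct a fact set
#'
#' @param assertions data.frame with columns `role`, `concept` (one row per
#'   role assertion, e.g. `hasTopography`/`C501`), or NULL.
#' @param age optional age in years.
#' @param derived previously derived concepts (normally empty).
#' @return an object of class `tnm_facts`.
#' @export
fact_set <- function(assertions = NULL, age = NA_real_, derived = character()) {
  if (is.null(assertions)) {
    assertions <- data.frame(role = character(), concept = character(),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("role", "concept") %in% names(assertions)))
  bad <- setdiff(assertions$role, TNM_ROLES)
  if (length(bad)) stop("unknown role(s) in assertions: ", paste(bad, collapse = ", "))
  for (r in c("hasTopography", "hasTNMEdition")) {
    if (sum(assertions$role == r) > 1L) {
      stop("at most one ", r, " assertion is allowed")
    }
  }
  structure(list(assertions = assertions, age = age, derived = derived),
            class = "tnm_facts")
}

#' Does a single literal match a fact set?
#'
#' An atomic literal matches when its concept has already been derived; an
#' existential `some(role, filler)` matches when some assertion on `role`
#' carries a code whose ancestor closure contains `filler`; a numeric
#' condition matches when the attribute is present and the comparison
#' holds (a missing attribute never matches).
#'
#' @param kb merged knowledge base.
#' @param lit a literal (see [rule_dsl] for the forms).
#' @param facts a `tnm_facts`.
#' @return logical scalar.
#' @export
literal_matches <- function(kb, lit, facts) {
  switch(lit$type,
    atomic = lit$concept %in% facts$derived,
    exists = {
      cands <- facts$assertions$concept[facts$assertions$role == lit$role]
      any(vapply(cands, function(d) lit$filler %in% kb$anc[[d]], logical(1)))
    },
    num = {
      v <- facts[[lit$attr]]
      if (is.null(v) || is.na(v)) return(FALSE)
      switch(lit$op, `<` = v < lit$value, `<=` = v <= lit$value,
             `>` = v > lit$value, `>=` = v >= lit$value)
    },
    stop("unknown literal type")
  )
}

#' Saturate a fact set against the knowledge base
#'
#' Computes the least fixpoint of the rule set over the facts. Each firing
#' adds the rule's right-hand concept together with its hierarchy ancestors
#' (subsumption closes upward). Termination is guaranteed because the
#' derived set grows monotonically inside the finite concept vocabulary and
#' each rule fires at most once.
#'
#' @param kb merged knowledge base.
#' @param facts a `tnm_facts`.
#' @return list with `facts` (the input with `derived` completed) and
#'   `trace` (data.frame of `rule_id`, `matched` literal descriptions, in
#'   firing order).
#' @export
saturate <- function(kb, facts) {
  stopifnot(inherits(kb, "tnm_kb"), inherits(facts, "tnm_facts"))
  fired <- logical(length(kb$rules))
  trace_ids <- character(); trace_lits <- character()
  repeat {
    changed <- FALSE
    for (i in seq_along(kb$rules)) {
      if (fired[i]) next
      r <- kb$rules[[i]]
      ok <- TRUE
      for (lit in r$lhs) {
        if (!literal_matches(kb, lit, facts)) { ok <- FALSE; break }
      }
      if (!ok) next
      fired[i] <- TRUE
      add <- kb$anc[[r$rhs]]
      if (is.null(add)) add <- r$rhs
      new <- setdiff(add, facts$derived)
      trace_ids <- c(trace_ids, r$rule_id)
      trace_lits <- c(trace_lits,
                      paste(vapply(r$lhs, lit_describe, character(1)),
                            collapse = " AND "))
      if (length(new)) {
        facts$derived <- c(facts$derived, new)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(facts = facts,
       trace = data.frame(rule_id = trace_ids, matched = trace_lits,
                          stringsAsFactors = FALSE))
}

# most specific concepts of a set under the hierarchy: members with no other
# member strictly below them.
most_specific <- function(kb, ids) {
  if (!length(ids)) return(character())
  keep <- vapply(ids, function(s) {
    !any(vapply(setdiff(ids, s), function(t) s %in% kb$anc[[t]], logical(1)))
  }, logical(1))
  ids[keep]
}

stage_concepts <- function(kb, derived) {
  derived[!is.na(kb$kind_of[derived]) & kb$kind_of[derived] == "stage"]
}

#' Permissible stage groups of an edition-specific site
#'
#' Collects the right-hand stages over every stage rule indexed to the site
#' (rules reference the site either directly or through its code-space
#' concepts).
#'
#' @param kb merged knowledge base.
#' @param site an edition-site concept id, e.g. `"TNMSiteEd7Breast"`.
#' @return sorted character vector of stage concept ids.
#' @export
query_stage_groups <- function(kb, site) {
  if (!has_concept(kb, site) || kb$kind_of[[site]] != "edition_site") {
    stop("unknown edition site: ", site)
  }
  idx <- kb$stage_index[[site]]
  if (is.null(idx)) return(character())
  sort(unique(vapply(kb$rules[idx], function(r) r$rhs, character(1))))
}

is_4digit_morph <- function(id) grepl("^M_[0-9]{4}$", id)

#' Morphology codes belonging to a category
#'
#' All code-kind descendants of the category, expanded to 4-digit codes
#' (3-digit family codes are reported through their 4-digit children). When
#' `behaviour` is given, only codes whose declared permissible behaviours
#' include that digit are kept.
#'
#' @param kb merged knowledge base.
#' @param category a morphology-category concept id, e.g. `"Mesothelioma"`.
#' @param behaviour optional behaviour digit (0-3, 6, 9).
#' @return sorted character vector of 4-digit morphology code ids.
#' @export
query_codes_in_category <- function(kb, category, behaviour = NULL) {
  if (!has_concept(kb, category) || kb$kind_of[[category]] != "category") {
    stop("unknown category: ", category)
  }
  desc <- descendants(kb, category)
  codes <- desc[!is.na(kb$kind_of[desc]) & kb$kind_of[desc] == "code" &
                  is_4digit_morph(desc)]
  if (!is.null(behaviour)) {
    keep <- vapply(codes, function(cd) {
      bs <- kb$behaviours_allowed[[cd]]
      is.null(bs) || behaviour %in% bs
    }, logical(1))
    codes <- codes[keep]
  }
  sort(unique(codes))
}

#' Morphology categories of a code, most specific first
#'
#' @param kb merged knowledge base.
#' @param code a morphology code id, e.g. `"M_8140"`.
#' @return character vector of category ids ordered by specificity (a
#'   category precedes its own ancestors).
#' @export
query_category_of_code <- function(kb, code) {
  if (!has_concept(kb, code)) stop("unknown code: ", code)
  if (is.na(kb$role_of[[code]]) || kb$role_of[[code]] != "hasMorphology") {
    stop("not a morphology code: ", code)
  }
  anc <- ancestors(kb, code)
  cats <- anc[!is.na(kb$kind_of[anc]) & kb$kind_of[anc] == "category"]
  if (!length(cats)) return(character())
  # specificity: number of category ancestors of the category itself,
  # descending (a subcategory has more ancestors than its parent)
  depth <- vapply(cats, function(cc) {
    a <- ancestors(kb, cc)
    sum(!is.na(kb$kind_of[a]) & kb$kind_of[a] == "category")
  }, numeric(1))
  cats[order(-depth, cats)]
}
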
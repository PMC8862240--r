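#' @title Module compilation: normalization and import merge
#' @description
#' Equivalence axioms and code-space declarations are normalized into
#' one-directional general concept inclusions (GCIs) at merge time, exactly
#' mirroring the remodelling of defined classes into GCIs: the reverse
#' inclusion of an equivalence is never emitted, which avoids unintended
#' equivalence inferences between distinct defined classes that happen to
#' share an expression.
#' @name kb_compiler
NULL

#' Normalize a union equivalence into general class axioms
#'
#' A morphology-category equivalence `Cat == (m1 | m2 | ... | mn)` over
#' codes of one role is remodelled into exactly `n` GCIs of the form
#' `some(role, mi) -> Cat`. Only this direction is kept; the reverse
#' inclusion is dropped deliberately.
#'
#' @param eq list with fields `lhs` (category id), `role`, `members`
#'   (character vector of code ids, all bound to `role`).
#' @param module provenance label.
#' @return list of rules, one per union member.
#' @export
normalize_equivalence <- function(eq, module = NA_character_) {
  stopifnot(is.character(eq$members), length(eq$members) >= 1L)
  if (!eq$role %in% TNM_ROLES) {
    stop("RoleMixError: unknown role in equivalence: ", eq$role)
  }
  lapply(seq_along(eq$members), function(i) {
    new_rule(
      rule_id = sprintf("equiv_%s_%d", eq$lhs, i),
      lhs = list(lit_exists(eq$role, eq$members[[i]])),
      rhs = eq$lhs,
      origin = "equivalence", module = module, definition = TRUE,
      meta = list(member = eq$members[[i]], role = eq$role)
    )
  })
}

space_suffix <- function(role) sub("^has", "", role)

space_concept_name <- function(site, role) {
  paste0(site, "CodeSpace", space_suffix(role))
}

#' Compile a code-space declaration
#'
#' The permissible T (or N, M) codes of a site and edition are wrapped in an
#' auxiliary union concept `U`; each listed code becomes a hierarchy child
#' of `U`, and one GCI `site AND some(role, U) -> <site>CodeSpace<T|N|M>` is
#' emitted. Membership of a record's code in the space is then derivable by
#' saturation, while the code list itself is kept in an index for direct
#' lookup.
#'
#' @param decl list with fields `site` (edition-site id), `role`
#'   (`hasT`/`hasN`/`hasM`), `codes` (non-empty character vector).
#' @param module provenance label.
#' @return list with `space_concept`, `union_concept`, `edges`
#'   (data.frame child/parent/role) and `rule`.
#' @export
compile_code_space <- function(decl, module = NA_character_) {
  stopifnot(length(decl$codes) >= 1L)
  space <- space_concept_name(decl$site, decl$role)
  u <- paste0(space, "Union")
  edges <- data.frame(child = decl$codes, parent = u, role = decl$role,
                      stringsAsFactors = FALSE)
  rule <- new_rule(
    rule_id = paste0("space_", space),
    lhs = list(lit_atomic(decl$site), lit_exists(decl$role, u)),
    rhs = space,
    origin = "code_space", module = module, definition = TRUE,
    meta = list(site = decl$site, role = decl$role, codes = decl$codes)
  )
  list(space_concept = space, union_concept = u, edges = edges, rule = rule)
}

# depth-first post-order over the import DAG, with cycle detection
import_closure <- function(root_id, registry) {
  order <- character(); state <- new.env(parent = emptyenv())
  visit <- function(id, chain) {
    if (id %in% chain) {
      stop("cyclic import: ", paste(c(chain, id), collapse = " -> "))
    }
    st <- state[[id]]
    if (identical(st, "done")) return(invisible())
    mod <- registry[[id]]
    if (is.null(mod)) stop("missing import: ", id)
    for (imp in mod$imports) visit(imp, c(chain, id))
    state[[id]] <- "done"
    order <<- c(order, id)
  }
  visit(root_id, character())
  order
}

expand_stage_rule <- function(sr, module) {
  # one compiled rule per combination of alternative T and N values; the
  # site literal is always present, and "any" slots contribute the site's
  # code-space concept instead of an explicit category literal.
  slot_alts <- function(slot, role) {
    if (is.null(slot)) return(list(NULL))
    if (identical(slot$kind, "any")) {
      return(list(list(kind = "any", concept = space_concept_name(sr$site, role))))
    }
    lapply(slot$values, function(v) list(kind = "code", value = v))
  }
  talts <- slot_alts(sr$T, "hasT")
  nalts <- slot_alts(sr$N, "hasN")
  malts <- slot_alts(sr$M, "hasM")
  out <- list()
  k <- 0L
  for (tv in talts) for (nv in nalts) for (mv in malts) {
    k <- k + 1L
    lhs <- list(lit_atomic(sr$site))
    slots <- list(T = tv, N = nv, M = mv,
                  behaviour = sr$behaviour, age = sr$age)
    for (cat in c("T", "N", "M")) {
      sl <- slots[[cat]]
      role <- paste0("has", cat)
      if (is.null(sl)) next
      if (sl$kind == "any") lhs <- c(lhs, list(lit_atomic(sl$concept)))
      else lhs <- c(lhs, list(lit_exists(role, sl$value)))
    }
    if (!is.null(sr$behaviour)) {
      lhs <- c(lhs, list(lit_exists("hasBehaviour",
                                    paste0("BehaviourCode", sr$behaviour))))
    }
    if (!is.null(sr$age)) {
      lhs <- c(lhs, list(lit_num("age", sr$age$op, sr$age$value)))
    }
    out[[k]] <- new_rule(
      rule_id = sprintf("stage_%s_%s_%d", sr$site, sr$stage, k),
      lhs = lhs, rhs = sr$stage, origin = "stage_rule", module = module,
      meta = list(site = sr$site, stage = sr$stage, slots = slots)
    )
  }
  out
}

#' Merge a module and its import closure into a knowledge base
#'
#' Resolves imports depth-first (the import graph must be acyclic), checks
#' that no concept is redefined by an importing module, normalizes all
#' equivalences, code spaces, site and stage-rule directives into GCI form,
#' verifies that every referenced concept is declared and role-consistent,
#' and builds the lookup indexes used by the engine. Merging is idempotent:
#' re-merging the same module set yields an identical rule set.
#'
#' @param root a `tnm_module` (or its id when `registry` is named).
#' @param registry named list of parsed modules, keyed by id.
#' @return a `tnm_kb`.
#' @export
merge_imports <- function(root, registry = list()) {
  if (inherits(root, "tnm_module")) {
    registry[[root$id]] <- root
    root_id <- root$id
  } else root_id <- root
  order <- import_closure(root_id, registry)
  mods <- registry[order]

  concepts <- data.frame(id = character(), kind = character(),
                         role = character(), module = character(),
                         stringsAsFactors = FALSE)
  edges <- data.frame(child = character(), parent = character(),
                      role = character(), stringsAsFactors = FALSE)
  rules <- list(); code_spaces <- list(); es_info <- list()
  behaviours_allowed <- list()

  for (m in mods) {
    if (nrow(m$concepts)) {
      clash <- intersect(m$concepts$id, concepts$id)
      if (length(clash)) {
        stop("concept redefinition clash in module ", m$id, ": ",
             paste(clash, collapse = ", "))
      }
      concepts <- rbind(concepts,
                        cbind(m$concepts, module = m$id,
                              stringsAsFactors = FALSE))
    }
    if (nrow(m$edges)) edges <- rbind(edges, m$edges)
    behaviours_allowed <- utils::modifyList(behaviours_allowed,
                                            m$behaviours_allowed)
    for (eq in m$equivalences) {
      rules <- c(rules, normalize_equivalence(eq, module = m$id))
      # hierarchy-of-fillers reading: union members also become hierarchy
      # children of the category, so existential matching through the
      # ancestor closure sees the category.
      edges <- rbind(edges, data.frame(child = eq$members, parent = eq$lhs,
                                       role = eq$role, stringsAsFactors = FALSE))
    }
    for (s in m$sites) {
      lhs <- list(lit_exists("hasTopography", s$topography),
                  lit_exists("hasMorphology", s$morphology))
      if (!is.na(s$grade)) lhs <- c(lhs, list(lit_exists("hasGrade", s$grade)))
      if (!is.null(s$age)) lhs <- c(lhs, list(lit_num("age", s$age$op, s$age$value)))
      rules <- c(rules, list(new_rule(
        rule_id = paste0("site_", s$id), lhs = lhs, rhs = s$id,
        origin = "site", module = m$id, definition = TRUE,
        meta = s)))
    }
    for (es in m$edition_sites) {
      rules <- c(rules, list(new_rule(
        rule_id = paste0("edsite_", es$id),
        lhs = list(lit_atomic(es$site),
                   lit_exists("hasTNMEdition", es$edition)),
        rhs = es$id, origin = "edition_site", module = m$id,
        definition = TRUE, meta = es)))
      es_info[[es$id]] <- list(site = es$site, edition = es$edition)
    }
    for (cs in m$code_spaces) {
      comp <- compile_code_space(cs, module = m$id)
      for (nm in c(comp$space_concept, comp$union_concept)) {
        if (nm %in% concepts$id) {
          stop("concept redefinition clash (code space) in module ",
               m$id, ": ", nm)
        }
        concepts[nrow(concepts) + 1L, ] <-
          c(nm, "auxiliary", cs$role, m$id)
      }
      # the space concept itself is kind code_space
      concepts$kind[concepts$id == comp$space_concept] <- "code_space"
      edges <- rbind(edges, comp$edges)
      rules <- c(rules, list(comp$rule))
      code_spaces[[paste0(cs$site, ".", cs$role)]] <-
        list(site = cs$site, role = cs$role, codes = cs$codes,
             space_concept = comp$space_concept)
    }
    for (sr in m$stage_rules) {
      rules <- c(rules, expand_stage_rule(sr, m$id))
    }
    for (ax in m$axioms) {
      rules <- c(rules, list(new_rule(
        rule_id = ax$rule_id, lhs = ax$lhs, rhs = ax$rhs,
        origin = "axiom", module = m$id)))
    }
  }

  edges <- unique(edges)
  rownames(edges) <- NULL
  # referential integrity: every edge endpoint, rule rhs, atomic concept and
  # existential filler must be declared; fillers must live in the role's
  # hierarchy (or be an auxiliary union / category of that role).
  known <- concepts$id
  missing <- setdiff(unique(c(edges$child, edges$parent)), known)
  if (length(missing)) {
    stop("undeclared concept(s) referenced in hierarchy edges: ",
         paste(missing, collapse = ", "))
  }
  role_of <- stats::setNames(concepts$role, concepts$id)
  for (r in rules) {
    if (!r$rhs %in% known) {
      stop("rule ", r$rule_id, ": undeclared rhs concept ", r$rhs)
    }
    for (lit in r$lhs) {
      if (lit$type == "atomic" && !lit$concept %in% known) {
        stop("rule ", r$rule_id, ": undeclared concept ", lit$concept)
      }
      if (lit$type == "exists") {
        if (!lit$filler %in% known) {
          stop("rule ", r$rule_id, ": undeclared filler ", lit$filler)
        }
        fr <- role_of[[lit$filler]]
        if (!is.na(fr) && fr != lit$role) {
          stop("rule ", r$rule_id, ": filler ", lit$filler,
               " is bound to role ", fr, ", not ", lit$role)
        }
      }
    }
  }
  # code-space codes must be bound to the declared role
  for (cs in code_spaces) {
    bad <- cs$codes[is.na(role_of[cs$codes]) | role_of[cs$codes] != cs$role]
    if (length(bad)) {
      stop("code space ", cs$space_concept, ": code(s) not bound to ",
           cs$role, ": ", paste(bad, collapse = ", "))
    }
  }
  # deterministic rule order (module order is already deterministic; sort by
  # canonical key within identical ids to make merges reproducible)
  new_kb(concepts = concepts, edges = edges, rules = rules,
         code_spaces = code_spaces, es_info = es_info,
         behaviours_allowed = behaviours_allowed,
         root = root_id, modules = order)
}

#' Detect definition clashes between defined classes
#'
#' Two distinct defined classes (sites, edition sites, code spaces, or
#' normalized equivalences) whose normalized left-hand sides are identical
#' would, under the equivalence reading, collapse into one class. This lists
#' every such pair; the comparison is symmetric and order-independent.
#'
#' @param kb a merged knowledge base.
#' @return list of character pairs `c(rule_id_a, rule_id_b)`; empty when all
#'   definitions are distinct.
#' @export
detect_definition_clashes <- function(kb) {
  defs <- Filter(function(r) isTRUE(r$definition), kb$rules)
  if (!length(defs)) return(list())
  keys <- vapply(defs, function(r) {
    paste(sort(vapply(r$lhs, lit_key, character(1))), collapse = " & ")
  }, character(1))
  out <- list()
  for (k in unique(keys[duplicated(keys)])) {
    idx <- which(keys == k)
    # only a clash when the implied defined classes differ
    rhs <- vapply(defs[idx], function(r) r$rhs, character(1))
    if (length(unique(rhs)) < 2) next
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (i < j && rhs[[i]] != rhs[[j]]) {
        out[[length(out) + 1L]] <- sort(c(defs[[idx[[i]]]]$rule_id,
                                          defs[[idx[[j]]]]$rule_id))
      }
    }
  }
  unique(out)
}
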
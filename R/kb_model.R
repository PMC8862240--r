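#' @title Domain model: roles, concepts, literals, hierarchies
#' @description Internal constructors and accessors for the in-memory
#'   knowledge-base model. A knowledge base holds a concept table, per-role
#'   code hierarchies (DAGs of child -> parent edges), and a list of
#'   normalized rules (general concept inclusions): a conjunction of
#'   literals entailing one atomic concept.
#' @name kb_model
NULL

# Closed enumeration of roles. Concepts of kind "code" or "category" are
# bound to exactly one of these; "stage" and "class" are pseudo-hierarchies
# used for stage concepts and free-standing auxiliary classes.
TNM_ROLES <- c("hasTopography", "hasMorphology", "hasBehaviour", "hasGrade",
               "hasT", "hasN", "hasM", "hasTNMEdition")

TNM_HIERARCHIES <- c(TNM_ROLES, "stage", "class")

TNM_KINDS <- c("code", "category", "site", "edition_site", "code_space",
               "stage", "edition", "auxiliary")

# The single numeric attribute usable in rules (units: years).
TNM_NUM_ATTRS <- c("age")
TNM_NUM_OPS <- c("<", "<=", ">", ">=")

## ---- literals --------------------------------------------------------------

lit_atomic <- function(concept) {
  list(type = "atomic", concept = concept)
}

lit_exists <- function(role, filler) {
  stopifnot(role %in% TNM_ROLES)
  list(type = "exists", role = role, filler = filler)
}

lit_num <- function(attr, op, value) {
  stopifnot(attr %in% TNM_NUM_ATTRS, op %in% TNM_NUM_OPS, is.numeric(value))
  list(type = "num", attr = attr, op = op, value = value)
}

# Canonical single-string form of a literal; used for rule identity,
# duplicate detection and definition-clash comparison.
lit_key <- function(lit) {
  switch(lit$type,
    atomic = paste0("A:", lit$concept),
    exists = paste0("E:", lit$role, ":", lit$filler),
    num    = paste0("N:", lit$attr, lit$op, lit$value),
    stop("unknown literal type: ", lit$type)
  )
}

lit_describe <- function(lit) {
  switch(lit$type,
    atomic = lit$concept,
    exists = sprintf("some(%s, %s)", lit$role, lit$filler),
    num    = sprintf("%s %s %s", lit$attr, lit$op, lit$value)
  )
}

## ---- rules -----------------------------------------------------------------

new_rule <- function(rule_id, lhs, rhs, origin, module = NA_character_,
                     definition = FALSE, meta = NULL) {
  keys <- vapply(lhs, lit_key, character(1))
  if (anyDuplicated(keys)) {
    lhs <- lhs[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
  }
  ord <- order(keys)
  structure(
    list(rule_id = rule_id, lhs = lhs[ord], rhs = rhs, origin = origin,
         module = module, definition = definition, meta = meta),
    class = "tnm_rule"
  )
}

rule_key <- function(rule) {
  paste0(paste(sort(vapply(rule$lhs, lit_key, character(1))), collapse = " & "),
         " => ", rule$rhs)
}

#' @export
print.tnm_rule <- function(x, ...) {
  cat(sprintf("<%s> %s => %s\n", x$rule_id,
              paste(vapply(x$lhs, lit_describe, character(1)),
                    collapse = " AND "),
              x$rhs))
  invisible(x)
}

## ---- knowledge base --------------------------------------------------------

# kb fields:
#   concepts: data.frame(id, kind, role, module)  (role NA for non-bound kinds)
#   edges:    data.frame(child, parent, role)     (role is a hierarchy key)
#   rules:    list of tnm_rule
#   code_spaces: named list "<edition_site>.<role>" ->
#                list(site, role, codes, space_concept)
#   es_info:  named list edition_site -> list(site, edition)
#   stage_index: named list edition_site -> integer rule indices
#   behaviours_allowed: named list morphology code -> integer vector
#   anc: environment id -> character vector of ancestors (reflexive)
new_kb <- function(concepts, edges, rules, code_spaces = list(),
                   es_info = list(), behaviours_allowed = list(),
                   root = NA_character_, modules = character()) {
  kb <- structure(
    list(root = root, modules = modules,
         concepts = concepts, edges = edges, rules = rules,
         code_spaces = code_spaces, es_info = es_info,
         behaviours_allowed = behaviours_allowed),
    class = "tnm_kb"
  )
  kb$kind_of <- stats::setNames(concepts$kind, concepts$id)
  kb$role_of <- stats::setNames(concepts$role, concepts$id)
  kb$anc <- build_ancestor_index(concepts$id, edges)
  kb$stage_index <- build_stage_index(kb)
  kb
}

build_stage_index <- function(kb) {
  idx <- list()
  for (i in seq_along(kb$rules)) {
    r <- kb$rules[[i]]
    if (identical(r$origin, "stage_rule")) {
      s <- r$meta$site
      idx[[s]] <- c(idx[[s]], i)
    }
  }
  idx
}

# Reflexive-transitive ancestor closure for every concept, memoised into an
# environment. Edges are assumed acyclic (checked by check_hierarchy_acyclic;
# a cycle would make closure ill-defined, so we guard with a depth cap).
build_ancestor_index <- function(ids, edges) {
  parents <- split(edges$parent, edges$child)
  env <- new.env(parent = emptyenv(), size = length(ids))
  n <- length(ids)
  closure <- function(id, depth) {
    if (depth > n + 1L) stop("cycle detected in hierarchy at concept ", id)
    got <- env[[id]]
    if (!is.null(got)) return(got)
    ps <- parents[[id]]
    out <- id
    for (p in ps) out <- c(out, closure(p, depth + 1L))
    out <- unique(out)
    env[[id]] <- out
    out
  }
  for (id in ids) closure(id, 0L)
  env
}

#' Reflexive-transitive ancestors of a concept
#'
#' Returns the concept itself plus every concept reachable through parent
#' edges of its hierarchy. The closure is precomputed at merge time, so
#' lookups are constant-time.
#'
#' @param kb a merged knowledge base (`tnm_kb`).
#' @param concept a concept id, e.g. `"M_9051"`.
#' @return character vector of concept ids (unordered, includes `concept`).
#' @examples
#' kb <- build_paper_kb()
#' ancestors(kb, "M_9051")   # contains M_905 and Mesothelioma
#' @export
ancestors <- function(kb, concept) {
  stopifnot(inherits(kb, "tnm_kb"))
  out <- kb$anc[[concept]]
  if (is.null(out)) {
    stop("UnknownConceptError: concept not declared in knowledge base: ",
         concept)
  }
  out
}

# descendants are needed for category queries and correction expansion;
# computed on demand (small hierarchies).
descendants <- function(kb, concept) {
  ids <- kb$concepts$id
  ids[vapply(ids, function(i) concept %in% kb$anc[[i]], logical(1))]
}

concept_kind <- function(kb, id) {
  k <- kb$kind_of[id]
  ifelse(is.na(k), NA_character_, unname(k))
}

has_concept <- function(kb, id) {
  !is.na(kb$kind_of[id])
}

#' Structural lint of the merged hierarchies
#'
#' Checks that every per-role hierarchy is acyclic and that concepts bound to
#' different roles share no hierarchy edges (role disjointness: a T code may
#' not have a topography parent, etc.). Findings are returned, not raised.
#'
#' @param kb a merged knowledge base.
#' @return character vector of human-readable violation descriptions; empty
#'   when the knowledge base is well formed.
#' @export
check_hierarchy_acyclic <- function(kb) {
  findings <- character()
  edges <- kb$edges
  # role disjointness: an edge must connect two concepts declared in the
  # same hierarchy, and that hierarchy must be the edge's own key.
  role_of <- kb$role_of
  for (i in seq_len(nrow(edges))) {
    rc <- role_of[edges$child[i]]
    rp <- role_of[edges$parent[i]]
    hc <- ifelse(is.na(rc), kb$kind_of[edges$child[i]], rc)
    hp <- ifelse(is.na(rp), kb$kind_of[edges$parent[i]], rp)
    if (!identical(unname(hc), unname(hp))) {
      findings <- c(findings, sprintf(
        "role disjointness violated: edge %s -> %s links hierarchies %s and %s",
        edges$child[i], edges$parent[i], hc, hp))
    }
  }
  # acyclicity per hierarchy via Kahn's algorithm
  for (h in unique(edges$role)) {
    e <- edges[edges$role == h, , drop = FALSE]
    nodes <- unique(c(e$child, e$parent))
    indeg <- stats::setNames(integer(length(nodes)), nodes)
    # treat edges child->parent; count per parent? direction irrelevant for
    # cycle detection, use child->parent arcs.
    for (i in seq_len(nrow(e))) indeg[e$parent[i]] <- indeg[e$parent[i]] + 1L
    queue <- names(indeg)[indeg == 0L]
    removed <- 0L
    while (length(queue)) {
      n <- queue[[1]]; queue <- queue[-1]; removed <- removed + 1L
      outs <- e$parent[e$child == n]
      for (p in outs) {
        indeg[p] <- indeg[p] - 1L
        if (indeg[p] == 0L) queue <- c(queue, p)
      }
    }
    if (removed < length(nodes)) {
      cyc <- names(indeg)[indeg > 0L]
      findings <- c(findings, sprintf(
        "cycle in %s hierarchy involving: %s", h,
        paste(sort(cyc), collapse = ", ")))
    }
  }
  findings
}

#' @export
print.tnm_kb <- function(x, ...) {
  cat("TNM knowledge base\n")
  cat(sprintf("  modules:  %s\n", paste(x$modules, collapse = ", ")))
  cat(sprintf("  concepts: %d  (%s)\n", nrow(x$concepts),
              paste(sprintf("%s=%d", names(table(x$concepts$kind)),
                            as.integer(table(x$concepts$kind))),
                    collapse = ", ")))
  cat(sprintf("  edges:    %d   rules: %d   code spaces: %d\n",
              nrow(x$edges), length(x$rules), length(x$code_spaces)))
  invisible(x)
}

#' @export
summary.tnm_kb <- function(object, ...) {
  origins <- table(vapply(object$rules, function(r) r$origin, character(1)))
  cat("TNM knowledge base summary\n")
  print(object)
  cat("  rules by origin:\n")
  for (o in names(origins)) cat(sprintf("    %-14s %d\n", o, origins[[o]]))
  invisible(object)
}
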
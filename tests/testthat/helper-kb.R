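# Shared fixtures: a small hand-built KB, a random-KB generator and a
# deliberately naive saturation oracle kept independent of the engine
# internals (it walks raw edges instead of the precomputed closure).

fixture_kb <- local({
  kb <- NULL
  function() {
    if (is.null(kb)) kb <<- build_paper_kb()
    kb
  }
})

tiny_kb_text <- '
module tiny
code hasTopography C10
code hasTopography C101 parent C10
code hasMorphology M_800
code hasMorphology M_8000 parent M_800
code hasBehaviour BehaviourCode3
code hasT T1
code hasT PT1 parent T1
code hasN N0
code hasN PN0 parent N0
code hasM M0
code hasM PM0 parent M0
edition TNMEd7
stage TNMStageI
category hasMorphology Carcinoma
attach hasMorphology M_800 Carcinoma
site TNMSiteToy topography C10 morphology Carcinoma
edition_site TNMSiteEd7Toy site TNMSiteToy edition TNMEd7
code_space TNMSiteEd7Toy hasT PT1
code_space TNMSiteEd7Toy hasN PN0
code_space TNMSiteEd7Toy hasM PM0
stage_rule TNMSiteEd7Toy TNMStageI T=T1 N=N0 M=M0 B=3
'

tiny_kb <- function() merge_imports(parse_module(tiny_kb_text, "tiny"))

# naive reflexive-transitive ancestors by repeated edge expansion
naive_ancestors <- function(edges, id) {
  out <- id
  repeat {
    nxt <- unique(c(out, edges$parent[edges$child %in% out]))
    if (length(nxt) == length(out)) return(out)
    out <- nxt
  }
}

naive_literal <- function(kb, lit, facts, derived) {
  if (lit$type == "atomic") return(lit$concept %in% derived)
  if (lit$type == "exists") {
    cands <- facts$assertions$concept[facts$assertions$role == lit$role]
    return(any(vapply(cands, function(d) {
      lit$filler %in% naive_ancestors(kb$edges, d)
    }, logical(1))))
  }
  v <- facts[[lit$attr]]
  if (is.null(v) || is.na(v)) return(FALSE)
  switch(lit$op, `<` = v < lit$value, `<=` = v <= lit$value,
         `>` = v > lit$value, `>=` = v >= lit$value)
}

# brute-force fixpoint: re-evaluates every rule from scratch each pass
naive_saturate <- function(kb, facts) {
  derived <- character()
  repeat {
    before <- length(derived)
    for (r in kb$rules) {
      if (all(vapply(r$lhs, naive_literal, logical(1),
                     kb = kb, facts = facts, derived = derived))) {
        derived <- unique(c(derived, naive_ancestors(kb$edges, r$rhs)))
      }
    }
    if (length(derived) == before) return(sort(derived))
  }
}

# random module text: two role hierarchies, auxiliary classes, <=15 axioms
random_kb_text <- function(n_codes = 10L, n_classes = 6L, n_rules = 12L) {
  lines <- c("module rand")
  codes <- list(hasT = sprintf("T%02d", seq_len(n_codes)),
                hasMorphology = sprintf("M%02d", seq_len(n_codes)))
  for (role in names(codes)) {
    ids <- codes[[role]]
    for (i in seq_along(ids)) {
      if (i > 1 && stats::runif(1) < 0.6) {
        p <- ids[sample.int(i - 1L, 1L)]
        lines <- c(lines, sprintf("code %s %s parent %s", role, ids[[i]], p))
      } else {
        lines <- c(lines, sprintf("code %s %s", role, ids[[i]]))
      }
    }
  }
  classes <- sprintf("K%02d", seq_len(n_classes))
  for (i in seq_along(classes)) {
    if (i > 1 && stats::runif(1) < 0.4) {
      lines <- c(lines, sprintf("class %s parent %s", classes[[i]],
                                classes[sample.int(i - 1L, 1L)]))
    } else lines <- c(lines, sprintf("class %s", classes[[i]]))
  }
  for (k in seq_len(sample.int(n_rules, 1L))) {
    n_lit <- sample(1:3, 1L)
    lits <- vapply(seq_len(n_lit), function(j) {
      kind <- sample(c("exists", "atomic", "num"), 1L,
                     prob = c(0.6, 0.3, 0.1))
      if (kind == "exists") {
        role <- sample(names(codes), 1L)
        sprintf("exists:%s:%s", role, sample(codes[[role]], 1L))
      } else if (kind == "atomic") {
        sprintf("atomic:%s", sample(classes, 1L))
      } else sprintf("num:age:%s:%d", sample(c("<", ">="), 1L),
                     sample(30:70, 1L))
    }, character(1))
    lines <- c(lines, sprintf("axiom ax%d %s <- %s", k,
                              sample(classes, 1L), paste(lits, collapse = " ")))
  }
  paste(lines, collapse = "\n")
}

random_facts <- function(kb) {
  codes <- kb$concepts$id[kb$concepts$kind == "code"]
  n <- sample(1:4, 1L)
  picked <- sample(codes, n)
  fact_set(data.frame(role = kb$role_of[picked], concept = picked,
                      stringsAsFactors = FALSE),
           age = if (stats::runif(1) < 0.5) sample(20:80, 1L) else NA_real_)
}

fig8_raw <- function() {
  list(record_id = "fig8", tnm_edition = "7", topography = "C50.1",
       morphology = "8050/2", pT = "is", cN = "0", cM = "0",
       stage_group = "0")
}

report_errors <- function(report, checks = NULL) {
  Filter(function(f) {
    f$severity == "error" && (is.null(checks) || f$check_id %in% checks)
  }, report$findings)
}
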
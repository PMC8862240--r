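#' @title OWL 2 functional-syntax export
#' @description
#' The compiled knowledge base can be rendered as an OWL 2 functional-syntax
#' document: hierarchy edges become `SubClassOf` between named classes,
#' normalized GCIs become `SubClassOf` with the complex expression on the
#' subclass side (`ObjectIntersectionOf` / `ObjectSomeValuesFrom`), and
#' numeric conditions become `DataSomeValuesFrom` with a datatype facet
#' restriction. The companion reader parses exactly this emission (it is
#' not a general OWL parser) so that export followed by re-import is the
#' identity on the normalized rule set.
#' @name owl_export
NULL

OWL_PREFIX <- "http://example.org/tnmkb#"

owl_facet <- function(op) {
  switch(op, `<` = "xsd:maxExclusive", `<=` = "xsd:maxInclusive",
         `>` = "xsd:minExclusive", `>=` = "xsd:minInclusive")
}

owl_facet_op <- function(facet) {
  switch(facet, maxExclusive = "<", maxInclusive = "<=",
         minExclusive = ">", minInclusive = ">=")
}

owl_class_expr <- function(lit) {
  switch(lit$type,
    atomic = paste0(":", lit$concept),
    exists = sprintf("ObjectSomeValuesFrom(:%s :%s)", lit$role, lit$filler),
    num = sprintf(
      "DataSomeValuesFrom(:%s DatatypeRestriction(xsd:decimal %s \"%s\"^^xsd:decimal))",
      lit$attr, owl_facet(lit$op), format(lit$value))
  )
}

#' Export a knowledge base as OWL 2 functional syntax
#'
#' @param kb merged knowledge base.
#' @return character scalar holding the document.
#' @export
export_owl <- function(kb) {
  lines <- c(
    sprintf("Prefix(:=<%s>)", OWL_PREFIX),
    "Prefix(xsd:=<http://www.w3.org/2001/XMLSchema#>)",
    sprintf("Ontology(<%s%s>", OWL_PREFIX, kb$root %||% "kb"))
  for (id in sort(kb$concepts$id)) {
    lines <- c(lines, sprintf("Declaration(Class(:%s))", id))
  }
  roles <- sort(unique(kb$concepts$role[!is.na(kb$concepts$role)]))
  for (r in roles) {
    lines <- c(lines, sprintf("Declaration(ObjectProperty(:%s))", r))
  }
  lines <- c(lines, "Declaration(DataProperty(:age))")
  edges <- kb$edges[order(kb$edges$child, kb$edges$parent), , drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    lines <- c(lines, sprintf("SubClassOf(:%s :%s)",
                              edges$child[i], edges$parent[i]))
  }
  rule_lines <- vapply(kb$rules, function(r) {
    exprs <- vapply(r$lhs, owl_class_expr, character(1))
    sub <- if (length(exprs) == 1L) exprs else
      sprintf("ObjectIntersectionOf(%s)", paste(sort(exprs), collapse = " "))
    sprintf("SubClassOf(%s :%s)", sub, r$rhs)
  }, character(1))
  lines <- c(lines, sort(rule_lines), ")")
  paste(lines, collapse = "\n")
}

owl_parse_expr <- function(expr) {
  expr <- trimws(expr)
  if (startsWith(expr, ":")) return(lit_atomic(sub("^:", "", expr)))
  m <- regmatches(expr, regexec(
    "^ObjectSomeValuesFrom\\(:([A-Za-z0-9_]+) :([A-Za-z0-9_]+)\\)$", expr))[[1]]
  if (length(m) == 3) return(lit_exists(m[2], m[3]))
  m <- regmatches(expr, regexec(
    "^DataSomeValuesFrom\\(:([A-Za-z0-9_]+) DatatypeRestriction\\(xsd:decimal xsd:(maxExclusive|maxInclusive|minExclusive|minInclusive) \"([0-9.]+)\"\\^\\^xsd:decimal\\)\\)$",
    expr))[[1]]
  if (length(m) == 4) return(lit_num(m[2], owl_facet_op(m[3]), as.numeric(m[4])))
  stop("unparseable class expression: ", expr)
}

# split a space-separated list of class expressions at top nesting level
split_exprs <- function(s) {
  out <- character(); depth <- 0L; cur <- ""
  for (ch in strsplit(s, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == " " && depth == 0L) {
      if (nzchar(cur)) out <- c(out, cur)
      cur <- ""
    } else cur <- paste0(cur, ch)
  }
  if (nzchar(cur)) out <- c(out, cur)
  out
}

#' Re-import an exported OWL functional-syntax document
#'
#' Parses the document structure emitted by [export_owl()] back into
#' hierarchy edges and normalized rules. Only this package's own emission
#' is supported.
#'
#' @param text character scalar or vector of lines.
#' @return list with `edges` (data.frame `child`, `parent`) and `rules`
#'   (list of rules with synthetic ids).
#' @export
parse_owl_functional <- function(text) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  edges_child <- character(); edges_parent <- character()
  rules <- list()
  for (line in text) {
    line <- trimws(line)
    if (!startsWith(line, "SubClassOf(")) next
    body <- sub("^SubClassOf\\(", "", sub("\\)$", "", line))
    parts <- split_exprs(body)
    if (length(parts) != 2) stop("unparseable SubClassOf: ", line)
    sub_expr <- parts[[1]]; super <- parts[[2]]
    if (!startsWith(super, ":")) stop("complex superclass not supported: ", line)
    rhs <- sub("^:", "", super)
    if (startsWith(sub_expr, ":")) {
      edges_child <- c(edges_child, sub("^:", "", sub_expr))
      edges_parent <- c(edges_parent, rhs)
    } else if (startsWith(sub_expr, "ObjectIntersectionOf(")) {
      inner <- sub("^ObjectIntersectionOf\\(", "", sub("\\)$", "", sub_expr))
      lhs <- lapply(split_exprs(inner), owl_parse_expr)
      rules[[length(rules) + 1L]] <- new_rule(
        rule_id = sprintf("owl_%d", length(rules) + 1L),
        lhs = lhs, rhs = rhs, origin = "owl")
    } else {
      rules[[length(rules) + 1L]] <- new_rule(
        rule_id = sprintf("owl_%d", length(rules) + 1L),
        lhs = list(owl_parse_expr(sub_expr)), rhs = rhs, origin = "owl")
    }
  }
  list(edges = data.frame(child = edges_child, parent = edges_parent,
                          stringsAsFactors = FALSE),
       rules = rules)
}

# canonical multiset of rule keys, for round-trip comparison
rule_set_canonical <- function(rules) {
  sort(vapply(rules, rule_key, character(1)))
}
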
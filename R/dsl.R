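#' @title Rule-module text format
#' @description
#' Knowledge modules are plain-text files, one directive per line, parsed
#' order-independently. `#` starts a comment; blank lines are ignored.
#' Directives:
#'
#' \preformatted{
#' module <id>
#' import <id>
#' code <role> <id> [parent <p1> [<p2> ...]] [behaviours <d1>,<d2>,...]
#' category <role> <id> [parent <p>]
#' attach <role> <child> <parent>
#' stage <id> [parent <p>]
#' edition <id>
#' class <id> [parent <p>]
#' site <id> topography <top> morphology <cat> [grade <g>] [age <op><years>]
#' edition_site <id> site <site> edition <edition>
#' code_space <edition_site> <hasT|hasN|hasM> <code> [<code> ...]
#' stage_rule <edition_site> <stage> T=<v> N=<v> M=<v> [B=<digit>] [age=<op><years>]
#' equiv <role> <category> = <member> [<member> ...]
#' axiom <rule_id> <rhs> <- <literal> [<literal> ...]
#' }
#'
#' In `stage_rule`, `<v>` is a code id, a comma-separated list of code ids
#' (expanded into one rule per alternative), or `any`, which stands for the
#' site's code-space concept for that category. In `axiom`, a literal is
#' `atomic:<id>`, `exists:<role>:<filler>`, or `num:age:<op>:<years>`.
#' @name rule_dsl
NULL

dsl_error <- function(file, line_no, msg) {
  stop(sprintf("%s:%d: %s", file, line_no, msg), call. = FALSE)
}

parse_num_cond <- function(tok) {
  m <- regmatches(tok, regexec("^(<=|>=|<|>)([0-9]+\\.?[0-9]*)$", tok))[[1]]
  if (length(m) != 3) return(NULL)
  list(op = m[2], value = as.numeric(m[3]))
}

#' Parse one rule-module document
#'
#' Parses the declarative text format described in [rule_dsl] into an
#' un-normalized module: declarations, hierarchy edges, equivalences, code
#' spaces, site/edition-site/stage-rule directives. Parsing is total and
#' order-independent; cross-references (to imported modules or to concepts
#' declared further down the file) are resolved later by [merge_imports()].
#'
#' @param text character scalar or vector of lines.
#' @param file a label used in error messages (and stored as provenance).
#' @return an object of class `tnm_module`.
#' @export
parse_module <- function(text, file = "<text>") {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  mod <- list(id = NA_character_, imports = character(),
              concepts = data.frame(id = character(), kind = character(),
                                    role = character(),
                                    stringsAsFactors = FALSE),
              edges = data.frame(child = character(), parent = character(),
                                 role = character(), stringsAsFactors = FALSE),
              behaviours_allowed = list(),
              equivalences = list(), code_spaces = list(),
              sites = list(), edition_sites = list(),
              stage_rules = list(), axioms = list(),
              file = file)
  declare <- function(id, kind, role, line_no) {
    if (id %in% mod$concepts$id) {
      dsl_error(file, line_no, paste0("duplicate concept id: ", id))
    }
    mod$concepts[nrow(mod$concepts) + 1L, ] <<- c(id, kind, role)
  }
  check_role <- function(role, line_no, allowed = TNM_ROLES) {
    if (!role %in% allowed) {
      dsl_error(file, line_no, paste0("unknown role: ", role))
    }
  }
  for (line_no in seq_along(text)) {
    line <- sub("#.*$", "", text[[line_no]])
    line <- trimws(line)
    if (!nzchar(line)) next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    dir <- tok[[1]]
    args <- tok[-1]
    need <- function(n) {
      if (length(args) < n) dsl_error(file, line_no, paste0(
        "directive '", dir, "' needs at least ", n, " arguments"))
    }
    switch(dir,
      module = {
        need(1)
        if (!is.na(mod$id)) dsl_error(file, line_no, "duplicate module directive")
        mod$id <- args[[1]]
      },
      import = {
        need(1)
        mod$imports <- c(mod$imports, args[[1]])
      },
      code = {
        need(2)
        check_role(args[[1]], line_no)
        id <- args[[2]]
        declare(id, "code", args[[1]], line_no)
        rest <- args[-(1:2)]
        while (length(rest)) {
          key <- rest[[1]]
          if (key == "parent") {
            ps <- character()
            rest <- rest[-1]
            while (length(rest) && !rest[[1]] %in% c("parent", "behaviours")) {
              ps <- c(ps, rest[[1]]); rest <- rest[-1]
            }
            if (!length(ps)) dsl_error(file, line_no, "parent needs a value")
            for (p in ps) {
              mod$edges[nrow(mod$edges) + 1L, ] <- c(id, p, args[[1]])
            }
          } else if (key == "behaviours") {
            if (length(rest) < 2) dsl_error(file, line_no, "behaviours needs a value")
            bs <- as.integer(strsplit(rest[[2]], ",", fixed = TRUE)[[1]])
            if (anyNA(bs)) dsl_error(file, line_no, "bad behaviours list")
            mod$behaviours_allowed[[id]] <- bs
            rest <- rest[-(1:2)]
          } else {
            dsl_error(file, line_no, paste0("unexpected token: ", key))
          }
        }
      },
      category = {
        need(2)
        check_role(args[[1]], line_no)
        declare(args[[2]], "category", args[[1]], line_no)
        if (length(args) >= 4 && args[[3]] == "parent") {
          mod$edges[nrow(mod$edges) + 1L, ] <- c(args[[2]], args[[4]], args[[1]])
        }
      },
      attach = {
        need(3)
        check_role(args[[1]], line_no)
        mod$edges[nrow(mod$edges) + 1L, ] <- c(args[[2]], args[[3]], args[[1]])
      },
      stage = {
        need(1)
        declare(args[[1]], "stage", NA_character_, line_no)
        if (length(args) >= 3 && args[[2]] == "parent") {
          mod$edges[nrow(mod$edges) + 1L, ] <- c(args[[1]], args[[3]], "stage")
        }
      },
      edition = {
        need(1)
        declare(args[[1]], "edition", "hasTNMEdition", line_no)
      },
      class = {
        need(1)
        declare(args[[1]], "auxiliary", NA_character_, line_no)
        if (length(args) >= 3 && args[[2]] == "parent") {
          mod$edges[nrow(mod$edges) + 1L, ] <- c(args[[1]], args[[3]], "class")
        }
      },
      site = {
        need(5)
        id <- args[[1]]
        declare(id, "site", NA_character_, line_no)
        kv <- args[-1]
        if (length(kv) %% 2L != 0L) dsl_error(file, line_no, "site needs key value pairs")
        keys <- kv[c(TRUE, FALSE)]
        vals <- kv[c(FALSE, TRUE)]
        bad <- setdiff(keys, c("topography", "morphology", "grade", "age"))
        if (length(bad)) dsl_error(file, line_no, paste0("unknown site key: ", bad[[1]]))
        site <- list(id = id, topography = NA, morphology = NA,
                     grade = NA, age = NULL)
        for (i in seq_along(keys)) {
          if (keys[[i]] == "age") {
            cond <- parse_num_cond(vals[[i]])
            if (is.null(cond)) dsl_error(file, line_no, "bad age condition")
            site$age <- cond
          } else site[[keys[[i]]]] <- vals[[i]]
        }
        if (is.na(site$topography) || is.na(site$morphology)) {
          dsl_error(file, line_no, "site needs topography and morphology")
        }
        mod$sites[[length(mod$sites) + 1L]] <- site
      },
      edition_site = {
        need(5)
        if (args[[2]] != "site" || args[[4]] != "edition") {
          dsl_error(file, line_no, "expected: edition_site <id> site <s> edition <e>")
        }
        declare(args[[1]], "edition_site", NA_character_, line_no)
        mod$edition_sites[[length(mod$edition_sites) + 1L]] <-
          list(id = args[[1]], site = args[[3]], edition = args[[5]])
      },
      code_space = {
        need(3)
        check_role(args[[2]], line_no, allowed = c("hasT", "hasN", "hasM"))
        mod$code_spaces[[length(mod$code_spaces) + 1L]] <-
          list(site = args[[1]], role = args[[2]], codes = args[-(1:2)])
      },
      stage_rule = {
        need(3)
        sr <- list(site = args[[1]], stage = args[[2]],
                   T = NULL, N = NULL, M = NULL,
                   behaviour = NULL, age = NULL, line = line_no)
        for (kvtok in args[-(1:2)]) {
          kv <- regmatches(kvtok, regexec("^([A-Za-z]+)=(.+)$", kvtok))[[1]]
          if (length(kv) != 3) dsl_error(file, line_no, paste0("bad token: ", kvtok))
          key <- kv[[2]]; val <- kv[[3]]
          if (key %in% c("T", "N", "M")) {
            sr[[key]] <- if (identical(val, "any")) list(kind = "any") else
              list(kind = "code",
                   values = strsplit(val, ",", fixed = TRUE)[[1]])
          } else if (key == "B") {
            sr$behaviour <- as.integer(val)
            if (is.na(sr$behaviour)) dsl_error(file, line_no, "bad behaviour digit")
          } else if (key == "age") {
            cond <- parse_num_cond(val)
            if (is.null(cond)) dsl_error(file, line_no, "bad age condition")
            sr$age <- cond
          } else dsl_error(file, line_no, paste0("unknown stage_rule key: ", key))
        }
        if (is.null(sr$T) || is.null(sr$N) || is.null(sr$M)) {
          dsl_error(file, line_no, "stage_rule needs T=, N= and M=")
        }
        mod$stage_rules[[length(mod$stage_rules) + 1L]] <- sr
      },
      equiv = {
        need(4)
        check_role(args[[1]], line_no)
        if (args[[3]] != "=") dsl_error(file, line_no, "expected '=' in equiv")
        members <- args[-(1:3)]
        mod$equivalences[[length(mod$equivalences) + 1L]] <-
          list(role = args[[1]], lhs = args[[2]], members = members)
      },
      axiom = {
        need(4)
        if (args[[3]] != "<-") dsl_error(file, line_no, "expected '<-' in axiom")
        lits <- lapply(args[-(1:3)], function(t) {
          parts <- strsplit(t, ":", fixed = TRUE)[[1]]
          if (parts[[1]] == "atomic" && length(parts) == 2) {
            lit_atomic(parts[[2]])
          } else if (parts[[1]] == "exists" && length(parts) == 3) {
            check_role(parts[[2]], line_no)
            lit_exists(parts[[2]], parts[[3]])
          } else if (parts[[1]] == "num" && length(parts) == 4 &&
                     parts[[2]] %in% TNM_NUM_ATTRS) {
            lit_num(parts[[2]], parts[[3]], as.numeric(parts[[4]]))
          } else dsl_error(file, line_no, paste0("bad literal: ", t))
        })
        mod$axioms[[length(mod$axioms) + 1L]] <-
          list(rule_id = args[[1]], rhs = args[[2]], lhs = lits, line = line_no)
      },
      dsl_error(file, line_no, paste0("unknown directive: ", dir))
    )
  }
  if (is.na(mod$id)) {
    if (length(text) == 0 || all(!nzchar(trimws(sub("#.*$", "", text))))) {
      mod$id <- "<empty>"
    } else {
      dsl_error(file, 1L, "missing module directive")
    }
  }
  structure(mod, class = "tnm_module")
}

#' @rdname parse_module
#' @param path path to a module file.
#' @export
parse_module_file <- function(path) {
  parse_module(readLines(path, warn = FALSE), file = basename(path))
}

#' Load every rule-module file in a directory
#'
#' @param dir directory containing `*.tnm` module files.
#' @return named list of `tnm_module`, keyed by module id.
#' @export
load_modules <- function(dir) {
  paths <- list.files(dir, pattern = "\\.tnm$", full.names = TRUE)
  mods <- lapply(paths, parse_module_file)
  names(mods) <- vapply(mods, function(m) m$id, character(1))
  mods
}

#' @export
print.tnm_module <- function(x, ...) {
  cat(sprintf("module %s (%d concepts, %d edges, %d stage rules; imports: %s)\n",
              x$id, nrow(x$concepts), nrow(x$edges), length(x$stage_rules),
              if (length(x$imports)) paste(x$imports, collapse = ", ") else "none"))
  invisible(x)
}
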
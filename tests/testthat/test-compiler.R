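test_that("stage-rule blocks parse into conjunction axioms", {
  kb <- tiny_kb()
  stage_rules <- Filter(function(r) r$origin == "stage_rule", kb$rules)
  expect_length(stage_rules, 1L)
  r <- stage_rules[[1]]
  keys <- vapply(r$lhs, tnmkb:::lit_key, character(1))
  expect_setequal(keys, c("A:TNMSiteEd7Toy", "E:hasT:T1", "E:hasN:N0",
                          "E:hasM:M0", "E:hasBehaviour:BehaviourCode3"))
  expect_identical(r$rhs, "TNMStageI")
})

test_that("parser rejects unknown roles and duplicate ids with line numbers", {
  expect_error(parse_module("module m\ncode hasFoo X1", "bad.tnm"),
               "bad\\.tnm:2: unknown role: hasFoo")
  expect_error(parse_module("module m\ncode hasT A\ncode hasT A", "dup.tnm"),
               "dup\\.tnm:3: duplicate concept id: A")
  empty <- parse_module("", "empty.tnm")
  expect_length(empty$stage_rules, 0L)
  expect_identical(nrow(empty$concepts), 0L)
})

test_that("union equivalences normalize to one GCI per member, one direction", {
  eq <- list(role = "hasMorphology", lhs = "Mesothelioma",
             members = paste0("M_905", 0:5))
  rules <- normalize_equivalence(eq)
  expect_length(rules, 6L)
  for (r in rules) {
    expect_length(r$lhs, 1L)
    expect_identical(r$lhs[[1]]$type, "exists")
    expect_identical(r$rhs, "Mesothelioma")
  }
  # no reverse inclusion anywhere
  expect_false(any(vapply(rules, function(r) {
    any(vapply(r$lhs, function(l) identical(l$concept, "Mesothelioma"),
               logical(1)))
  }, logical(1))))
  expect_length(normalize_equivalence(
    list(role = "hasT", lhs = "Solo", members = "T1")), 1L)
})

test_that("normalization count equals union arity", {
  set.seed(7)
  for (n in sample(1:20, 8L)) {
    eq <- list(role = "hasMorphology", lhs = "Cat",
               members = sprintf("M_%04d", sample.int(9999, n)))
    expect_length(normalize_equivalence(eq), n)
  }
})

test_that("code spaces compile to union edges plus one membership rule", {
  kb <- fixture_kb()
  cs <- kb$code_spaces[["TNMSiteEd7Breast.hasT"]]
  expect_length(cs$codes, 28L)
  u_edges <- kb$edges[kb$edges$parent == "TNMSiteEd7BreastCodeSpaceTUnion", ]
  expect_identical(nrow(u_edges), 28L)
  expect_true("CT1c" %in% cs$codes)
  expect_false("CT4e" %in% cs$codes)
  expect_false("CTis" %in% cs$codes)   # clinical in-situ outside the space
  comp <- compile_code_space(list(site = "TNMSiteEd7Breast", role = "hasM",
                                  codes = "CM0"))
  expect_identical(nrow(comp$edges), 1L)
  expect_identical(comp$rule$rhs, "TNMSiteEd7BreastCodeSpaceM")
})

test_that("import merge resolves the module tree and rejects bad graphs", {
  dir <- system.file("extdata", "kb", package = "tnmkb")
  mods <- load_modules(dir)
  kb <- merge_imports("encr_fixture_root", mods)
  expect_identical(kb$modules[[1]], "icdo_generic")
  expect_true("tnm_ed7" %in% kb$modules)

  self_loop <- parse_module("module loopy\nimport loopy", "loopy.tnm")
  expect_error(merge_imports(self_loop, list(loopy = self_loop)),
               "cyclic import")
  orphan <- parse_module("module orphan\nimport nowhere", "orphan.tnm")
  expect_error(merge_imports(orphan), "missing import")
  dup <- parse_module("module dup\nimport icdo_generic\ncode hasTopography C50",
                      "dup.tnm")
  expect_error(merge_imports(dup, mods), "redefinition clash")
})

test_that("swapping the edition module changes exactly the altered rule", {
  dir <- system.file("extdata", "kb", package = "tnmkb")
  mods <- load_modules(dir)
  kb7 <- merge_imports("tnm_ed7", mods)
  ed7_text <- readLines(file.path(dir, "tnm_ed7.tnm"))
  ed8_text <- sub("^module tnm_ed7$", "module tnm_ed8", ed7_text)
  # one altered stage rule: stage IA requires N1 instead of N0
  ed8_text <- sub("TNMStageIA T=T1 N=N0", "TNMStageIA T=T1 N=N1", ed8_text)
  mods$tnm_ed8 <- parse_module(ed8_text, "tnm_ed8.tnm")
  kb8 <- merge_imports("tnm_ed8", mods)
  k7 <- tnmkb:::rule_set_canonical(kb7$rules)
  k8 <- tnmkb:::rule_set_canonical(kb8$rules)
  expect_length(setdiff(k7, k8), 1L)
  expect_length(setdiff(k8, k7), 1L)
  expect_match(setdiff(k8, k7), "E:hasN:N1")
})

test_that("definition-clash detection matches an all-pairs brute force", {
  kb <- fixture_kb()
  expect_length(detect_definition_clashes(kb), 0L)

  text <- '
module clashy
code hasTopography C649
code hasMorphology M_8000
category hasMorphology Carcinoma
attach hasMorphology M_8000 Carcinoma
site SiteA topography C649 morphology Carcinoma
site SiteB topography C649 morphology Carcinoma
site SiteC topography C649 morphology Carcinoma
'
  kbc <- merge_imports(parse_module(text, "clashy"))
  got <- detect_definition_clashes(kbc)
  # brute force over all unordered pairs of definition rules
  defs <- Filter(function(r) isTRUE(r$definition), kbc$rules)
  want <- list()
  for (i in seq_along(defs)) for (j in seq_along(defs)) {
    if (i >= j) next
    ki <- paste(sort(vapply(defs[[i]]$lhs, tnmkb:::lit_key, character(1))),
                collapse = "&")
    kj <- paste(sort(vapply(defs[[j]]$lhs, tnmkb:::lit_key, character(1))),
                collapse = "&")
    if (identical(ki, kj) && defs[[i]]$rhs != defs[[j]]$rhs) {
      want[[length(want) + 1L]] <- sort(c(defs[[i]]$rule_id,
                                          defs[[j]]$rule_id))
    }
  }
  canon <- function(ps) sort(vapply(ps, paste, character(1), collapse = "|"))
  expect_identical(canon(got), canon(want))
  expect_length(got, 3L)
})
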
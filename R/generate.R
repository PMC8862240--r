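#' @title Synthetic record generation
#' @description
#' Generates labelled batches of synthetic registry records implementing
#' the three validation test scenarios, for every site that carries stage
#' rules: (i) all parameters consistent with the declared stage;
#' (ii) one or more parameters corrupted for the declared stage, drawn
#' half-and-half from outside the site's code space and from inside the
#' space but inconsistent with the stage; (iii) a declared stage group
#' outside the site's permissible set. Generation is fully seeded and
#' reproducible.
#' @name synthetic_records
NULL

# leaf codes of a site space satisfying a generic value, X codes excluded
space_leaves <- function(kb, space_codes, generic = NULL) {
  pool <- space_codes[!is_x_code(space_codes)]
  if (is.null(generic)) return(pool)
  pool[vapply(pool, function(cd) generic %in% ancestors(kb, cd), logical(1))]
}

sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

dot_topography <- function(id) {
  if (nchar(id) == 4L) paste0(substr(id, 1, 3), ".", substr(id, 4, 4)) else id
}

raw_code_value <- function(code) {
  # PT1a -> "1a", CTX -> "X", PTis -> "is"
  sub("^[CP][TNM]", "", code)
}

code_field <- function(code, category) {
  paste0(if (startsWith(code, "P")) "p" else "c", category)
}

sample_age_for <- function(cond) {
  if (is.null(cond)) return(sample(25:90, 1L))
  switch(cond$op,
    `<`  = sample(18:(ceiling(cond$value) - 1L), 1L),
    `<=` = sample(18:floor(cond$value), 1L),
    `>`  = sample((floor(cond$value) + 1L):95, 1L),
    `>=` = sample(ceiling(cond$value):95, 1L))
}

site_surface <- function(kb, esid) {
  info <- kb$es_info[[esid]]
  site_rule <- Filter(function(r) identical(r$origin, "site") &&
                        identical(r$rhs, info$site), kb$rules)[[1]]
  top <- site_rule$meta$topography
  desc <- descendants(kb, top)
  tops <- desc[grepl("^C[0-9]{3}$", desc)]
  if (!length(tops)) tops <- top
  morphs <- query_codes_in_category(kb, site_rule$meta$morphology)
  edition_num <- as.integer(sub("^TNMEd", "", info$edition))
  list(tops = sort(tops), morphs = morphs, edition = edition_num)
}

# raw record satisfying one uniformly sampled stage rule of the site
sample_valid_raw <- function(kb, esid, surface, rid) {
  idx <- kb$stage_index[[esid]]
  r <- kb$rules[[sample1(idx)]]
  slots <- r$meta$slots
  spaces <- site_space_codes(kb, esid)
  raw <- list(record_id = rid,
              tnm_edition = as.character(surface$edition),
              topography = dot_topography(sample1(surface$tops)))
  beh <- if (is.null(slots$behaviour)) 3L else slots$behaviour
  morphs <- Filter(function(m) {
    bs <- kb$behaviours_allowed[[m]]
    is.null(bs) || beh %in% bs
  }, surface$morphs)
  raw$morphology <- sub("^M_", "", sample1(morphs))
  raw$behaviour <- as.character(beh)
  for (category in c("T", "N", "M")) {
    sl <- slots[[category]]
    pool <- if (is.null(sl) || identical(sl$kind, "any")) {
      space_leaves(kb, spaces[[category]])
    } else space_leaves(kb, spaces[[category]], sl$value)
    code <- sample1(pool)
    raw[[code_field(code, category)]] <- raw_code_value(code)
  }
  raw$age <- as.character(sample_age_for(slots$age))
  if (stats::runif(1) < 0.3) raw$grade <- as.character(sample(1:3, 1L))
  raw$stage_group <- stage_label(r$rhs)
  list(raw = raw, rule = r)
}

# does the (possibly corrupted) record still satisfy some rule of its
# declared stage?
satisfies_declared <- function(kb, rec, esid) {
  idx <- kb$stage_index[[esid]]
  rules <- Filter(function(r) identical(r$rhs, rec$declared_stage),
                  kb$rules[idx])
  spaces <- site_space_codes(kb, esid)
  any(vapply(rules, function(r) {
    all(vapply(CORRECTION_FIELDS, function(f) {
      slot_satisfied(kb, rec, r, f, spaces)
    }, logical(1)))
  }, logical(1)))
}

corrupt_raw <- function(kb, esid, raw) {
  spaces <- site_space_codes(kb, esid)
  use_outside <- stats::runif(1) < 0.5
  categories <- sample(c("T", "N", "M"))
  if (use_outside) {
    category <- categories[[1]]
    field <- code_field(paste0("P", category), category)
    present <- Filter(function(f) !is.null(raw[[f]]),
                      paste0(c("p", "c"), category))
    if (length(present)) field <- present[[1]]
    raw[[field]] <- "9"   # syntactically valid, outside every fixture space
    return(list(raw = raw, fields = category))
  }
  # inside the space but inconsistent with the declared stage: search over
  # candidate generic values (and a behaviour flip) for one that breaks
  # every rule of the declared stage
  flip_candidates <- list()
  for (category in categories) {
    gens <- setdiff(sort(unique(generic_code(
      spaces[[category]][!is_x_code(spaces[[category]])]))), character(0))
    for (g in sample(gens)) {
      flip_candidates[[length(flip_candidates) + 1L]] <-
        list(field = category, generic = g)
    }
  }
  flip_candidates[[length(flip_candidates) + 1L]] <- list(field = "behaviour")
  for (cand in flip_candidates) {
    raw2 <- raw
    if (cand$field == "behaviour") {
      raw2$behaviour <- as.character(if (raw$behaviour == "2") 3L else 2L)
      fields <- "behaviour"
    } else {
      category <- cand$field
      leaves <- space_leaves(kb, spaces[[category]], cand$generic)
      if (!length(leaves)) next
      code <- sample1(leaves)
      for (f in paste0(c("p", "c"), category)) raw2[[f]] <- NULL
      raw2[[code_field(code, category)]] <- raw_code_value(code)
      fields <- category
    }
    rec2 <- normalize_record(raw2)
    if (!length(rec2$findings) && !satisfies_declared(kb, rec2, esid)) {
      return(list(raw = raw2, fields = fields))
    }
  }
  # no in-space corruption can break the stage (fully permissive rules):
  # fall back to an out-of-space code
  category <- categories[[1]]
  present <- Filter(function(f) !is.null(raw[[f]]),
                    paste0(c("p", "c"), category))
  field <- if (length(present)) present[[1]] else code_field(paste0("P", category), category)
  raw[[field]] <- "9"
  list(raw = raw, fields = category)
}

scenario_counts <- function(per_site, mix) {
  stopifnot(length(mix) == 3L, all(mix >= 0), sum(mix) > 0)
  mix <- mix / sum(mix)
  n <- pmax(1L, floor(per_site * mix))
  while (sum(n) > per_site) n[which.max(n)] <- n[which.max(n)] - 1L
  n[[1]] <- n[[1]] + (per_site - sum(n))
  stats::setNames(n, c("valid", "corrupted_parameter", "unknown_stage"))
}

#' Generate labelled synthetic records
#'
#' @param kb merged knowledge base.
#' @param per_site number of records per stage-bearing site (at least 3, so
#'   each scenario occurs at least once per site).
#' @param mix relative proportions of the three scenarios
#'   (valid, corrupted parameter, unknown stage group).
#' @param seed integer seed; identical seeds give identical output.
#' @return list of entries `list(raw, record, label)` where `raw` is the
#'   CSV-dialect field list, `record` the normalized `tnm_record`, and
#'   `label` a `list(scenario, corrupted_fields)` ground truth.
#' @export
generate_records <- function(kb, per_site = 3L,
                             mix = c(1, 1, 1) / 3, seed = 1L) {
  if (per_site < 3L) {
    stop("per_site must be at least 3 (one record per scenario)")
  }
  set.seed(seed)
  sites <- sort(names(kb$stage_index))
  out <- list()
  rid <- 0L
  for (esid in sites) {
    surface <- site_surface(kb, esid)
    counts <- scenario_counts(per_site, mix)
    permitted <- stage_label(query_stage_groups(kb, esid))
    all_stages <- stage_label(sort(
      kb$concepts$id[kb$concepts$kind == "stage"]))
    foreign <- setdiff(all_stages, permitted)
    plan <- rep(names(counts), counts)
    for (scenario in plan) {
      rid <- rid + 1L
      base <- sample_valid_raw(kb, esid, surface, sprintf("R%04d", rid))
      raw <- base$raw
      fields <- character()
      if (scenario == "corrupted_parameter") {
        cr <- corrupt_raw(kb, esid, raw)
        raw <- cr$raw
        fields <- cr$fields
      } else if (scenario == "unknown_stage") {
        raw$stage_group <- sample1(foreign)
        fields <- "stage_group"
      }
      out[[length(out) + 1L]] <- list(
        raw = raw, record = normalize_record(raw),
        label = list(scenario = scenario,
                     corrupted_fields = if (scenario == "valid") character()
                                        else fields))
    }
  }
  out
}
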
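---
title: "TNM staging as a saturation-based rule engine: model, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TNM staging as a saturation-based rule engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnmkb)
```

## The problem and the model

Cancer registries record solid tumours as summary case records: an ICD-O-3
topography code (site, e.g. `C50.1`), a morphology code and behaviour
digit (cell type and in-situ/malignant status, e.g. `8050/2`), a TNM
edition, clinical and/or pathological T, N and M category codes, and a
synthesized stage group (0, IA, …, IV). The central validation question is
whether the declared stage group is consistent with the other codes for
that site and edition.

`tnmkb` answers it with a knowledge base of *general concept inclusions*
(GCIs): axioms of the form

$$\ell_1 \sqcap \ell_2 \sqcap \dots \sqcap \ell_k \sqsubseteq C$$

where each literal $\ell_i$ is atomic (a named concept already derived),
existential ($\exists r.F$ over one of the closed roles
`hasTopography`, `hasMorphology`, `hasBehaviour`, `hasGrade`, `hasT`,
`hasN`, `hasM`, `hasTNMEdition`), or a numeric condition on the single
datatype attribute `age` (years), and $C$ is always atomic. The concept
vocabulary is arranged in per-role DAG hierarchies: 4-digit morphology
codes under their 3-digit family, family codes under morphology
categories (`Adenocarcinoma ⊑ Carcinoma`), clinical/pathological category
codes under their generic code (`PTis ⊑ Tis`), sub-stages under their
coarse stage (`IIIC ⊑ III`). Concepts bound to different roles are
disjoint by construction, and the lint `check_hierarchy_acyclic()`
verifies both acyclicity and that disjointness.

An existential $\exists r.F$ matches a record asserting $(r, d)$ whenever
$F$ lies in the reflexive-transitive ancestor closure of $d$. This single
matching rule unifies the two styles in which category membership can be
written — `∃hasMorphology.M_905 ⊑ Mesothelioma` with the codes as
hierarchy children, or per-member existential GCIs — because union
equivalences are normalized into one GCI per member *and* their members
are installed as hierarchy children of the category. Only the
code-to-category direction is kept; the reverse inclusion of an
equivalence is never emitted, which is what prevents two defined classes
that happen to share an expression from being inferred equivalent.
`detect_definition_clashes()` reports any pair of definitions whose
normalized left sides coincide anyway.

## Inference

Classification of a record is forward chaining to a least fixpoint
(`saturate()`): every rule whose left side matches fires once, adding its
right-hand concept together with that concept's hierarchy ancestors;
firing is monotone and idempotent, so the result is independent of rule
order and terminates inside the finite vocabulary. For the breast
test record the chain is site → edition site → code-space concepts →
stage group:

```{r}
kb <- build_paper_kb()
rec <- normalize_record(list(record_id = "ex", tnm_edition = "7",
  topography = "C50.1", morphology = "8050/2", pT = "is",
  cN = "0", cM = "0"))
res <- saturate(kb, fact_set(tnmkb:::record_assertions(kb, rec)))
res$trace
```

The *most specific* derived stage is reported. Because each firing also
adds stage ancestors, `IIIC` and `III` may both be derived; the minimal
element is unique whenever the rule set is well formed. If two
incomparable stages are ever minimal the engine refuses to choose and
emits a knowledge-base-inconsistency finding — incomparable stages always
indicate a rule-authoring error, not a property of the record.

A second execution mode (`direct`) computes the same answers without the
fixpoint loop, by indexed lookups: site rules are evaluated literal-wise,
edition sites through the site×edition index, code-space concepts by list
membership, stage rules through the per-site index. The two modes are
contract-equivalent and the test suite compares them report-for-report on
1000+ generated records; the direct mode exists because a production
validator wants predictable per-record cost, and keeping both honest
against each other is itself a useful cross-check.

## Validation semantics and tunable parameters

Checks V1–V6 are described in `?record_validator`. The design points that
were genuinely open, and how they were settled:

* **Pathological first.** When both clinical and pathological codes are
  present for a category, both must lie in the code space (V2), and stage
  inference uses the pathological code — registries treat pathological
  staging as confirmatory. No precedence is defined beyond that.
* **X codes.** `TX`/`NX` (and the legacy `MX`) encode "cannot be
  assessed". They are legal members of code spaces and so pass V2, but
  stage inference abstains whenever a selected category code is an X code:
  no stage rule should consume an unassessable value, even where a
  code-space-based "any" term would technically admit it. Such records
  end `unstaged` rather than `invalid`.
* **Coarse declared stages.** `lenient_stage = TRUE` accepts a declared
  `III` when `IIIC` is inferred (and lets `III` pass the permissible-set
  check when a sub-stage of it is permitted). The default is strict,
  because registry quality checks want the granularity the table defines.
* **No-stage combinations.** A record whose codes are all present,
  in-space and assessable but match no stage row gets a V5 error when a
  stage was declared: the combination itself is invalid for the site.
* **Block size.** `validate_batch()` ingests records in blocks (default
  100, arbitrary), fully retracting each block's facts before the next;
  reports are provably independent of the block size and this is
  property-tested over random sizes.
* **Corrections.** `propose_corrections()` assumes the declared stage is
  correct and solves for the offending parameters: stage rules of the
  declared stage are ranked by how few record fields violate them, and
  the expected value set of each violated field is collected from the
  minimally violated rules. Because every rule constrains each field
  independently, per-field expected sets are exact. A proposal is unique
  when one value remains; `apply_corrections()` writes unique proposals
  back (preferring the C/P branch the original value came from), and the
  suite checks that corrected records re-validate as `valid`.

## The fixture knowledge base and the synthetic generator

The packaged modules encode: the edition-7 breast stage table (stage 0
requires behaviour 2; invasive rows behaviour 3; "Any" cells expressed
through the site's code-space concept, never the global code universe),
the 28-code breast T space, N/M spaces transcribed from the table rows,
the kidney site rule, the carcinoma / adenocarcinoma / basal-cell /
mesothelioma morphology groupings, and one deliberately synthetic
age-conditioned site (`TNMSiteThyroidSynth`, threshold 45 years, loosely
modelled on papillary thyroid) whose only purpose is to exercise numeric
conditions end to end. The stage table exists in a second, independent
transcription — a plain CSV consulted by string lookup
(`brute_force_stage_oracle()`) — and the suite checks engine/oracle
agreement over the full breast T×N×M×behaviour product (2464
combinations, a few seconds of compute).

`generate_records()` emulates a registry test file: for every
stage-bearing site it samples a stage rule uniformly, draws satisfying
codes uniformly over the admissible (non-X) space values, picks clinical
or pathological variants at random, and then either leaves the record
consistent (scenario i), corrupts a parameter (scenario ii — half the
time to a syntactically valid code outside the space, half the time to an
in-space value verified to break every rule of the declared stage), or
declares a stage outside the site's permitted set (scenario iii). Labels
carry the corrupted fields, and label soundness is tested: scenario-i
records validate, scenario-ii/iii records always produce at least one
error finding, with iii flagged specifically by the permissible-stage
check.

What the generator does *not* emulate: missing and partial TNM data
distributions of real registries, morphology/topography combination
errors, multi-record consistency (duplicates, follow-ups), or free-text
noise beyond the surface dialects the normalizer handles. Passing tests
therefore demonstrate the engine's internal consistency and its agreement
with the transcribed table — not performance on messy production data.

## Numerical and procedural choices

* Determinism: all sampling flows through one seed; generated batches are
  byte-identical per seed. Sets are reported sorted; auxiliary concepts
  (`…CodeSpaceT`, `…Union`) have deterministic names so OWL exports are
  reproducible byte for byte.
* The ancestor closure is precomputed at merge time (hundreds of
  concepts), making literal matching O(1) per candidate; the exhaustive
  breast enumeration and the 1000-record mode-equivalence check each run
  in seconds on one CPU, and the whole suite in well under a minute.
* Degenerate inputs: empty documents parse to empty modules; an empty
  knowledge base exports a valid (empty) ontology; empty fact sets derive
  nothing; unknown concepts raise typed errors at the API boundary and
  V6 findings at the record boundary.
* The OWL functional-syntax writer emits `SubClassOf` with the complex
  expression on the subclass side, `ObjectSomeValuesFrom` for
  existentials and `DataSomeValuesFrom` with facet restrictions for age;
  the companion reader parses exactly this emission. Round-tripping the
  fixture rule set is part of the suite.

## Known limitations

Completeness is claimed only for the rule fragment the compiler emits
(conjunctions of atomic/existential/numeric literals over acyclic
hierarchies with atomic right-hand sides) — this is not a general OWL
reasoner, and inverse-role queries are answered from indexes rather than
by reasoning. Only the edition-7 breast rules ship as a real site;
the architecture supports further sites and editions by adding module
files (swapping the edition module is itself tested), but no edition-8
ruleset is provided. Grade participates in the vocabulary and record
format but no packaged site rule consumes it. The correction search
assumes the declared stage is the trustworthy field; the converse
assumption (codes correct, stage wrong) is exactly what validation mode
already computes.
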
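# tnmkb — TNM staging knowledge base and record validation for cancer registries

Population-based cancer registries must verify that the synthesized TNM
stage group recorded for each cancer case agrees with the individual T
(tumour extent), N (nodal involvement) and M (metastasis) category codes —
a check that depends on the anatomical site (ICD-O-3 topography), the
tumour morphology and behaviour, and the TNM edition in use. `tnmkb`
implements this check as an executable knowledge base plus inference
engine, with no external description-logic reasoner required.

The rule set is written as plain-text modules in a small declarative
format: per-role code hierarchies (topography, morphology, behaviour,
grade, T, N, M, edition), morphology categories, site definitions, per-site
and per-edition code spaces, and stage-group rules. Everything compiles to
*general concept inclusions* (GCIs) — axioms whose left side is a
conjunction of literals entailed by a single named concept:

```
∃hasTopography.C50 ⊓ ∃hasMorphology.Carcinoma ⊑ TNMSiteBreast
TNMSiteBreast ⊓ ∃hasTNMEdition.TNMEd7 ⊑ TNMSiteEd7Breast
TNMSiteEd7Breast ⊓ ∃hasBehaviour.BehaviourCode2
    ⊓ ∃hasT.Tis ⊓ ∃hasN.N0 ⊓ ∃hasM.M0 ⊑ TNMStage0
TNMSiteEd7BreastCodeSpaceT ⊓ ∃hasN.N3 ⊓ ∃hasM.M0
    ⊓ ∃hasBehaviour.BehaviourCode3 ⊑ TNMStageIIIC
```

Union equivalences (`Mesothelioma ≡ M_9050 ⊔ … ⊔ M_9055`) are remodelled
into one GCI per member — only that direction — so that two defined
classes sharing an expression can never collapse into an unintended
equivalence. Classification is forward chaining to a least fixpoint: every
rule whose left side is matched by a record's facts fires, adding its
right-hand concept and that concept's hierarchy ancestors, until nothing
new derives. Code spaces make "Any T" mean *any T of the site-specific
set*, so a T code outside the space blocks stage inference and is flagged
instead of silently accepted.

The package ships a fixture knowledge base for TNM edition 7 breast cancer
(full stage table, 28-code T space), a kidney site rule, morphology
groupings, and a synthetic age-conditioned thyroid-like site, plus:

* a batch validator with checks V1–V6 (site resolution, code-space
  membership, behaviour/stage consistency, permissible stage group,
  declared-vs-inferred stage, record format) in two contract-equivalent
  execution modes (`reasoner` = saturation, `direct` = indexed lookup);
* correction proposals for records whose declared stage is permissible
  (the stage is assumed correct, the offending parameters are solved for);
* a seeded generator of labelled synthetic record batches covering three
  test scenarios (valid / corrupted parameter / unknown stage group);
* OWL 2 functional-syntax export with a round-trip reader;
* a command-line front end (`inst/exec/tnmkb`).

## Worked example

Stage the classic breast test record (topography C50.1, morphology 8050/2,
edition 7, T=is, N=0, M=0):

```r
library(tnmkb)
kb <- build_paper_kb()
cmd_stage(tnm_edition = "7", topography = "C50.1", morphology = "8050/2",
          pT = "is", cN = "0", cM = "0", kb = kb)
#> site:         Breast (TNMSiteEd7Breast)
#> T code space: CT0 CT1 CT1a CT1b CT1c CT2 CT3 CT4 CT4a CT4b CT4c CT4d CTX
#>               PT0 PT1 PT1a PT1b PT1c PT1mi PT2 PT3 PT4 PT4a PT4b PT4c PT4d PTis PTX
#> N code space: CN0 CN1 CN2 CN3 CNX PN0 PN1 PN1mi PN2 PN3 PNX
#> M code space: CM0 CM1 PM0 PM1
#> stage groups: 0 IA IB IIA IIB IIIA IIIB IIIC IV
#> stage:        0
```

The record is subsumed site → edition site → code spaces → stage group 0.
A record declared stage 0 but coded T=1 with behaviour 3 fails validation,
and because its declared stage is permissible the engine solves for the
offending parameters:

```r
rec <- normalize_record(list(record_id = "ex2", tnm_edition = "7",
  topography = "C50.9", morphology = "8500", behaviour = "3",
  pT = "1", pN = "0", pM = "0", stage_group = "0"))
rep <- validate_record(kb, rec)
rep
#> record ex2: verdict invalid  site Breast  stage IA
#>   [V3/error] behaviour: behaviour 3 is inconsistent with stage 0 (expected 2)
#>   [V5/error] stage_group: declared stage 0 does not match inferred stage IA
props <- propose_corrections(kb, rec, rep)
format_corrections(kb, rec, rep, props, print = TRUE)
#> record ex2  site Breast  declared stage 0
#>   T:         PT1    >> Tis !
#>   N:         PN0    >> PN0
#>   M:         PM0    >> PM0
#>   behaviour: 3      >> 2 !
```

Both flagged corrections are unique (`Tis`, behaviour `2`); applying them
with `apply_corrections()` yields a record that validates as `valid`.

Batch use from a shell (CSV dialect documented in `?read_records_csv`):

```sh
inst/exec/tnmkb generate --out batch.csv --per-site 20 --seed 1
inst/exec/tnmkb validate batch.csv --out report.csv --mode direct
inst/exec/tnmkb query stages-of-site TNMSiteEd7Breast
inst/exec/tnmkb export-owl --out tnmkb.ofn
```

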
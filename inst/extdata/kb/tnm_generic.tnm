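# Edition-independent TNM vocabulary: generic T/N/M category codes with
# their clinical (C) and pathological (P) specialisations, the stage-group
# hierarchy, and the generic (edition-free) TNM sites. Clinical in-situ
# (CTis) and clinical micro-invasion (T1mi) specialisations exist in the
# vocabulary but individual site code spaces may exclude them.

module tnm_generic
import morphology_grouping

edition TNMEd7

# stage groups, sub-stages under their coarse stage
stage TNMStage0
stage TNMStageI
stage TNMStageIA parent TNMStageI
stage TNMStageIB parent TNMStageI
stage TNMStageII
stage TNMStageIIA parent TNMStageII
stage TNMStageIIB parent TNMStageII
stage TNMStageIII
stage TNMStageIIIA parent TNMStageIII
stage TNMStageIIIB parent TNMStageIII
stage TNMStageIIIC parent TNMStageIII
stage TNMStageIV
stage TNMStageIVA parent TNMStageIV
stage TNMStageIVC parent TNMStageIV

# T category
code hasT T0
code hasT CT0 parent T0
code hasT PT0 parent T0
code hasT T1
code hasT CT1 parent T1
code hasT PT1 parent T1
code hasT T1a parent T1
code hasT CT1a parent T1a
code hasT PT1a parent T1a
code hasT T1b parent T1
code hasT CT1b parent T1b
code hasT PT1b parent T1b
code hasT T1c parent T1
code hasT CT1c parent T1c
code hasT PT1c parent T1c
code hasT T1mi parent T1
code hasT PT1mi parent T1mi
code hasT T2
code hasT CT2 parent T2
code hasT PT2 parent T2
code hasT T3
code hasT CT3 parent T3
code hasT PT3 parent T3
code hasT T4
code hasT CT4 parent T4
code hasT PT4 parent T4
code hasT T4a parent T4
code hasT CT4a parent T4a
code hasT PT4a parent T4a
code hasT T4b parent T4
code hasT CT4b parent T4b
code hasT PT4b parent T4b
code hasT T4c parent T4
code hasT CT4c parent T4c
code hasT PT4c parent T4c
code hasT T4d parent T4
code hasT CT4d parent T4d
code hasT PT4d parent T4d
code hasT Tis
code hasT CTis parent Tis
code hasT PTis parent Tis
code hasT TX
code hasT CTX parent TX
code hasT PTX parent TX

# N category (micro-metastasis N1mi is deliberately NOT under N1: stage
# tables treat them as distinct rows; only the pathological form exists)
code hasN N0
code hasN CN0 parent N0
code hasN PN0 parent N0
code hasN N1
code hasN CN1 parent N1
code hasN PN1 parent N1
code hasN N1mi
code hasN PN1mi parent N1mi
code hasN N2
code hasN CN2 parent N2
code hasN PN2 parent N2
code hasN N3
code hasN CN3 parent N3
code hasN PN3 parent N3
code hasN NX
code hasN CNX parent NX
code hasN PNX parent NX

# M category
code hasM M0
code hasM CM0 parent M0
code hasM PM0 parent M0
code hasM M1
code hasM CM1 parent M1
code hasM PM1 parent M1
code hasM MX
code hasM CMX parent MX
code hasM PMX parent MX

# generic TNM sites: topography family + morphology category entail the
# site, one general class axiom per site (one direction only)
site TNMSiteBreast topography C50 morphology Carcinoma
site TNMSiteKidney topography C649 morphology Carcinoma
site TNMSiteThyroidSynth topography C739 morphology Carcinoma
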
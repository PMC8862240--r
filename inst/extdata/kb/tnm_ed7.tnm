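# TNM edition 7 plug-in module: edition-specific sites, their T/N/M code
# spaces, and the stage-group rules for breast.
#
# Transcription provenance:
#  - The breast T code space is the printed 28-code list (13 clinical +
#    15 pathological; no clinical Tis, no clinical T1mi).
#  - The breast N and M spaces are transcribed from the stage table rows:
#    N0, N1mi (pathological only), N1, N2, N3 plus NX; M0 and M1 (edition 7
#    dropped MX). X codes participate in the code-space check only.
#  - Stage rows follow the edition-7 breast stage-group table: 0 = Tis/N0/M0
#    (in-situ, behaviour 2); IA = T1/N0; IB = T0,T1/N1mi; IIA = T0,T1/N1 or
#    T2/N0; IIB = T2/N1 or T3/N0; IIIA = T0-T2/N2 or T3/N1,N2;
#    IIIB = T4/N0-N2; IIIC = any T in the breast space/N3; IV = any T, any
#    N, M1 (invasive stages behaviour 3). "Any" always means any code of
#    the site-specific space, expressed through the code-space concept.

module tnm_ed7
import tnm_generic

edition_site TNMSiteEd7Breast site TNMSiteBreast edition TNMEd7

code_space TNMSiteEd7Breast hasT CT0 CT1 CT1a CT1b CT1c CT2 CT3 CT4 CT4a CT4b CT4c CT4d CTX PT0 PT1 PT1a PT1b PT1c PT1mi PT2 PT3 PT4 PT4a PT4b PT4c PT4d PTX PTis
code_space TNMSiteEd7Breast hasN CN0 CN1 CN2 CN3 CNX PN0 PN1 PN1mi PN2 PN3 PNX
code_space TNMSiteEd7Breast hasM CM0 CM1 PM0 PM1

stage_rule TNMSiteEd7Breast TNMStage0 T=Tis N=N0 M=M0 B=2
stage_rule TNMSiteEd7Breast TNMStageIA T=T1 N=N0 M=M0 B=3
stage_rule TNMSiteEd7Breast TNMStageIB T=T0,T1 N=N1mi M=M0 B=3
stage_rule TNMSiteEd7Breast TNMStageIIA T=T0,T1 N=N1 M=M0 B=3
stage_rule TNMSiteEd7Breast TNMStageIIA T=T2 N=N0 M=M0 B=3
stage_rule TNMSiteEd7Breast TNMStageIIB T=T2 N=N1 M=M0 B=3
stage_rule TNMSiteEd7Breast TNMStageIIB T=T3 N=N0 M=M0 B=3
stage_rule TNMSiteEd7Breast TNMStageIIIA T=T0,T1,T2 N=N2 M=M0 B=3
stage_rule TNMSiteEd7Breast TNMStageIIIA T=T3 N=N1,N2 M=M0 B=3
stage_rule TNMSiteEd7Breast TNMStageIIIB T=T4 N=N0,N1,N2 M=M0 B=3
stage_rule TNMSiteEd7Breast TNMStageIIIC T=any N=N3 M=M0 B=3
stage_rule TNMSiteEd7Breast TNMStageIV T=any N=any M=M1 B=3
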
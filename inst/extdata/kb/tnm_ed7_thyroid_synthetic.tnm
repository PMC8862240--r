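# SYNTHETIC fixture module: an age-conditioned TNM site exercising the
# numeric (datatype) attribute in stage rules. Modelled loosely on the
# edition-7 papillary thyroid grouping with its age threshold of 45 years,
# but simplified; it is a constructed test fixture, not a transcription of
# a published stage table.

module tnm_ed7_thyroid_synthetic
import tnm_ed7

edition_site TNMSiteEd7ThyroidSynth site TNMSiteThyroidSynth edition TNMEd7

code_space TNMSiteEd7ThyroidSynth hasT CT1 CT2 CT3 CT4 CTX PT1 PT2 PT3 PT4 PTX
code_space TNMSiteEd7ThyroidSynth hasN CN0 CN1 CNX PN0 PN1 PNX
code_space TNMSiteEd7ThyroidSynth hasM CM0 CM1 PM0 PM1

# below the age threshold every non-metastatic tumour is stage I
stage_rule TNMSiteEd7ThyroidSynth TNMStageI T=any N=any M=M0 B=3 age=<45
stage_rule TNMSiteEd7ThyroidSynth TNMStageII T=any N=any M=M1 B=3 age=<45

# at or above the threshold the grouping depends on T, N and M
stage_rule TNMSiteEd7ThyroidSynth TNMStageI T=T1 N=N0 M=M0 B=3 age=>=45
stage_rule TNMSiteEd7ThyroidSynth TNMStageII T=T2 N=N0 M=M0 B=3 age=>=45
stage_rule TNMSiteEd7ThyroidSynth TNMStageIII T=T3 N=N0 M=M0 B=3 age=>=45
stage_rule TNMSiteEd7ThyroidSynth TNMStageIII T=T1,T2,T3 N=N1 M=M0 B=3 age=>=45
stage_rule TNMSiteEd7ThyroidSynth TNMStageIVA T=T4 N=any M=M0 B=3 age=>=45
stage_rule TNMSiteEd7ThyroidSynth TNMStageIVC T=any N=any M=M1 B=3 age=>=45
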
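# ICD-O-3 code hierarchies: topography, morphology, behaviour, grade.
# 4-digit morphology codes sit under their 3-digit family code; permissible
# behaviours per 4-digit code follow the ICD-O-3 morphology list.

module icdo_generic

# topography: breast (C50 family), kidney (C64.9), thyroid gland (C73.9)
code hasTopography C50
code hasTopography C500 parent C50
code hasTopography C501 parent C50
code hasTopography C502 parent C50
code hasTopography C503 parent C50
code hasTopography C504 parent C50
code hasTopography C505 parent C50
code hasTopography C506 parent C50
code hasTopography C508 parent C50
code hasTopography C509 parent C50
code hasTopography C649
code hasTopography C739

# behaviour digits (0 benign, 1 uncertain, 2 in situ, 3 malignant,
# 6 metastatic, 9 unknown)
code hasBehaviour BehaviourCode0
code hasBehaviour BehaviourCode1
code hasBehaviour BehaviourCode2
code hasBehaviour BehaviourCode3
code hasBehaviour BehaviourCode6
code hasBehaviour BehaviourCode9

# histologic grade / differentiation
code hasGrade GradeCode1
code hasGrade GradeCode2
code hasGrade GradeCode3
code hasGrade GradeCode4
code hasGrade GradeCode9

# morphology: carcinoma NOS / papillary family
code hasMorphology M_805
code hasMorphology M_8050 parent M_805 behaviours 2,3
code hasMorphology M_8051 parent M_805 behaviours 3
code hasMorphology M_8052 parent M_805 behaviours 2,3

# basal cell carcinoma family
code hasMorphology M_809
code hasMorphology M_8090 parent M_809 behaviours 3
code hasMorphology M_8091 parent M_809 behaviours 3
code hasMorphology M_8092 parent M_809 behaviours 3
code hasMorphology M_8093 parent M_809 behaviours 3
code hasMorphology M_8097 parent M_809 behaviours 3
code hasMorphology M_8098 parent M_809 behaviours 3

# adenocarcinoma families
code hasMorphology M_814
code hasMorphology M_8140 parent M_814 behaviours 2,3
code hasMorphology M_850
code hasMorphology M_8500 parent M_850 behaviours 2,3
code hasMorphology M_8503 parent M_850 behaviours 2,3

# mesothelioma family
code hasMorphology M_905
code hasMorphology M_9050 parent M_905 behaviours 0,3
code hasMorphology M_9051 parent M_905 behaviours 3
code hasMorphology M_9052 parent M_905 behaviours 0,3
code hasMorphology M_9053 parent M_905 behaviours 3
code hasMorphology M_9054 parent M_905 behaviours 0,3
code hasMorphology M_9055 parent M_905 behaviours 1
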
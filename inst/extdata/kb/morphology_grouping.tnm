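# Morphology categories: named groupings of ICD-O-3 morphology codes.
# Categories live in the hasMorphology hierarchy as parents of code
# concepts, so an existential over a category matches any descendant code.
# The mesothelioma grouping is written as a union equivalence; merge
# remodels it into one general class axiom per member (one direction only).

module morphology_grouping
import icdo_generic

category hasMorphology Carcinoma
category hasMorphology Adenocarcinoma parent Carcinoma
category hasMorphology BasalCellCarcinoma parent Carcinoma
category hasMorphology Mesothelioma

equiv hasMorphology Mesothelioma = M_9050 M_9051 M_9052 M_9053 M_9054 M_9055

attach hasMorphology M_805 Carcinoma
attach hasMorphology M_809 BasalCellCarcinoma
attach hasMorphology M_814 Adenocarcinoma
attach hasMorphology M_850 Adenocarcinoma
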
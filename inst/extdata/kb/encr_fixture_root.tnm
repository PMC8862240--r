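# Root module of the packaged fixture knowledge base. Swapping the edition
# module (e.g. a future edition-8 ruleset) only requires changing the
# import list here.

module encr_fixture_root
import tnm_ed7
import tnm_ed7_thyroid_synthetic
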
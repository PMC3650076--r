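component,n_accessions
annex1_in_contracting_parties,2625646
article15,693752
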
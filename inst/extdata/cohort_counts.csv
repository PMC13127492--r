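outcome,n_initiators,n_total
alcohol,4330,11868
nicotine,646,11868
cannabis,406,11868
any_substance,4706,11868
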
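population,group
Western Sahara,inland
Algeria (Reguibates),inland
Morocco,coastal
Algeria (Oran),coastal
Tunisia,coastal
Libya,coastal
Egypt,coastal
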
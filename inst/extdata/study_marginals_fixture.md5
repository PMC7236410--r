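94971453971532c9f4159dc52fb18276
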
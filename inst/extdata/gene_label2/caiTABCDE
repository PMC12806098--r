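caiTABCDE
caiT
caiA
caiB	K08298:405
caiC
caiD
caiE
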
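AATAAA
ATTAAA
TATAAA
AGTAAA
AATACA
CATAAA
AATATA
GATAAA
AATGAA
AATAAT
AAGAAA
ACTAAA
AATAGA
ATTACA
AACAAA
ATTATA
AACAAG
AATAAG
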
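>pcCYC1 precleaved CYC1 3' end (5' product of cleavage), 5' 6-FAM label
UUUAUAGUUAUGUUAGUAUUAAGAACGUUAUUUAUAUUUCAA
>CYC1 uncleaved CYC1 3' end with 3' extension, 5' 6-FAM and 3' Alexa647 labels
UUUAUAGUUAUGUUAGUAUUAAGAACGUUAUUUAUAUUUCAAAUUUUUCUUUUUUU
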
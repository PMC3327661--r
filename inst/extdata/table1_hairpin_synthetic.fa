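>hp-1451-synth
UCGCACAGGAGCAAGUUACCGCACAUGCGGCUGAACAGAUCUAGGCAAGACGCUCCGCA
>hp-1559-synth
UUCGAUGCUUGUAUGCUACUCCAUGCAAGCACUCCGGAGCAAUAACAGAGUACAGAUAC
>hp-2131-synth
AUGCAGAAGUGCACGGAAACAGCUAGGCAGGCCCCCUCCUGUUACUGUUCUUCUGAUG
>hp-2954-1-synth
CAUCCCCAUUCCACUCCUAGCAAUAUGCGGAGCCUAAUGGCUGCCACUGGAUUUCUUCG
>hp-2954-2-synth
GGUAUGAGGGUUUCCGUGGGCACCUGCGUGUAUCUGGUGCUGAGAGGGCUUGGGGAGAGGA
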
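>gga-miR-1451
UCGCACAGGAGCAAGUUACCGC
>gga-miR-1559
UUCGAUGCUUGUAUGCUACUCC
>gga-miR-2131
AUGCAGAAGUGCACGGAAACAGC
>gga-miR-2131*
CUGUUACUGUUCUUCUGAUG
>gga-miR-2954
CAUCCCCAUUCCACUCCUAGCA
>gga-miR-2954*
GCUGAGAGGGCUUGGGGAGAGGA
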
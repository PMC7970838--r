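>mt16S_forward herring-specific forward primer
CGCCCACCAATCACGAA
>mt16S_reverse herring-specific reverse primer
ACGTTTGTGCCAGTATCACGTT
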
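>synthetic_balanced example genome with uniform base composition (synthetic)
ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT
ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT
>synthetic_at_rich example genome with low GC content (synthetic)
AATTAATTAATTAATTAATTAATTAATTAATTAATTAATTACGTACGTACGTACGTACGT
AATTAATTAATTAATTAATTAATTAATTAATTAATTAATTACGTACGTACGTACGTACGT
>synthetic_gc_skewed example genome with excess C over G (synthetic)
ACCTACCTACCTACCTACCTACCTACCTACCTACCTACCTACCTACCTACCTACCTACCT
ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT
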
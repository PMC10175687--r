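# Synthetic MRSA teicoplanin MIC histogram (EUCAST-style two-column format).
# This is an editable stand-in snapshot, NOT surveillance data: most isolates
# sit at 0.5-1 mg/L as European MRSA surveillance reports. Replace with a
# current distribution before drawing any clinical conclusion from CFR.
mic	fraction
0.25	0.05
0.5	0.55
1	0.35
2	0.04
4	0.01
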
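>PUMA_BH3 mouse p53-upregulated modulator of apoptosis, residues 128-161
GEEEQWAREIGAQLRRMADDLNAQYERRRQEEQQ
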
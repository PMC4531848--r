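== Taxonomic assignment report ==
query: q1
database flavor: stringent (12 sequences)
query length: 1200 bp
composition: A=302 C=303 G=295 T=300 other=0
undetermined bases: 0.00%
first-hit match length: 100.0% of query (>=95% expected)
closest leaf: Genusaa_speciesaa~v~TT~SYN00001
closest patristic distance: 0.002000
closest leaf in proximal cluster: yes
proximal cluster (k=2): 2 members
closest type strain: Genusaa_speciesaa~v~TT~SYN00001
closest type strain in proximal cluster: yes
intra-species distance q75: 0.003216
genus inter-species distance q75: 0.042467
species suggestion: Genusaa speciesaa
genus suggestion: Genusaa
warnings: none
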
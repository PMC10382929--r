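# Inferred mitochondrial minichromosomes of the most recent common
# ancestor of sucking lice (Anoplura), 11 minichromosomes, transcribed
# from the published ancestral karyotype.  No sizes are available for an
# inferred ancestor.  Orientation of the T-nad1-Q run follows the extant
# species (see vignette).
rrnS-C
atp8-atp6-N
R-nad4L-P-cox3-A
E-cytb-S1-S2
nad2
M-L1-rrnL-V
K-nad4
I-cox1-L2
D-Y-cox2-nad6
~Q-~nad1-~T-G-nad3-W
H-nad5-F
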
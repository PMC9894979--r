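ligand	receptor	annotation
LGALS3	LAG3	exhaustion
CEACAM1	HAVCR2	exhaustion
NECTIN4	TIGIT	exhaustion
HLA-B	KLRD1	exhaustion
MYL9	CD69	costimulation
TNFSF10	TNFRSF11B	decoy
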
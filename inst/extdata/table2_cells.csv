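species,intervention,ln_mr,sd
Humans,KD,0.3436,0.2842
Humans,KD+,0.2311,0.1972
Humans,CR,,
Humans,CR+,0.5596,0.1532
Athymic mice,KD,-0.0186,0.3529
Athymic mice,KD+,0.1345,0.0305
Athymic mice,CR,0.3563,0.0376
Athymic mice,CR+,,
C57BL mice,KD,0.2261,0.0956
C57BL mice,KD+,0.576,0.0961
C57BL mice,CR,0.5415,0.3219
C57BL mice,CR+,,
SCID mice,KD,0.6325,0.5048
SCID mice,KD+,,
SCID mice,CR,0.3556,0.0501
SCID mice,CR+,,
Fisher rats,KD,0.0117,0.3228
Fisher rats,KD+,,
Fisher rats,CR,,
Fisher rats,CR+,,
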
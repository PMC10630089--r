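((((Opisthokonta,Apusozoa)OpisthokontaApusozoa,Breviata)Obazoa,Amoebozoa)Amorphea,(((Stramenopila,Alveolata)Halvaria,Rhizaria)SAR,Archaeplastida)Diaphoretickes,Discoba,Metamonada)LECA;
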
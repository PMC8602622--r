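amino_acid_metabolism_synthetic	synthetic example pathway	serum_m001	serum_m002	serum_m003	serum_m004	serum_m005
acylcarnitine_transport_synthetic	synthetic example pathway	serum_m010	serum_m011	serum_m012	serum_m013
nucleotide_metabolism_synthetic	synthetic example pathway	serum_m020	serum_m021	serum_m022	serum_m023	serum_m024	serum_m025
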
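# Isotopic masses (Da) and abundances for the elements of metal-thiolate protein
# chemistry (H, C, N, O, S, Cu, Zn). Values: IUPAC/CIAAW 2021 compilation
# (atomic masses from AME2020). Pinned here so simulated patterns are bit-stable.
element,isotope,mass,abundance
H,1,1.0078250319,0.999885
H,2,2.0141017781,0.000115
C,12,12.0000000000,0.9893
C,13,13.0033548352,0.0107
N,14,14.0030740052,0.99636
N,15,15.0001088989,0.00364
O,16,15.9949146221,0.99757
O,17,16.9991315000,0.00038
O,18,17.9991604000,0.00205
S,32,31.9720706900,0.9499
S,33,32.9714585000,0.0075
S,34,33.9678668300,0.0425
S,36,35.9670808800,0.0001
Cu,63,62.9295975000,0.6915
Cu,65,64.9277895000,0.3085
Zn,64,63.9291422000,0.4917
Zn,66,65.9260334000,0.2773
Zn,67,66.9271273000,0.0404
Zn,68,67.9248442000,0.1845
Zn,70,69.9253193000,0.0061
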
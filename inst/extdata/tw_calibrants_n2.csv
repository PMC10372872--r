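# Native-mode traveling-wave calibrant reference values in nitrogen, keyed by
# (protein, charge). Nominal DTCCS_N2 values compiled after the Bush laboratory
# native calibrant database (Bush et al., Anal. Chem. 2010, 82, 9557-9565);
# table version 2010-native-N2. Arrival times are measured per experiment and
# are NOT part of this table.
name,charge,mass,ccs_ref
ubiquitin,4,8565.8,1090
ubiquitin,5,8565.8,1137
ubiquitin,6,8565.8,1250
cytochrome_c,6,12358.3,1393
cytochrome_c,7,12358.3,1481
beta_lactoglobulin,7,18363.0,1956
beta_lactoglobulin,8,18363.0,2020
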
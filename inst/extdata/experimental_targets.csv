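species,metal,observable,target_dG,tolerance
H2PO4-,,hfe_ti,-111.06,0.05
HPO4-2,,hfe_ti,-315.69,0.05
PO4-3,,hfe_ti,-660.85,0.05
H2PO4-,Ca+2,binding_pmf,-1.92,0.30
HPO4-2,Ca+2,binding_pmf,-3.70,0.30
PO4-3,Ca+2,binding_pmf,-8.81,0.30
H2PO4-,Mg+2,binding_pmf,-1.73,0.30
HPO4-2,Mg+2,binding_pmf,-3.86,0.30
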
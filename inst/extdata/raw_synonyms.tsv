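term	peptide_length	saccharide_length	is_depositor_external_name
command			FALSE
surpass			FALSE
abc			FALSE
-ol			FALSE
-phenyl			FALSE
chloride)			FALSE
paracetamol (INN)			FALSE
paracetamol (Tylenol)			FALSE
TNF (TN)			FALSE
AstraZeneca			FALSE
what?ever			FALSE
somatostatin-28	28		FALSE
stachyose		4	FALSE
2,4-D, sodium salt			FALSE
acetone derivative			FALSE
solution of ethanol			FALSE
gene product			FALSE
EGFR inhibitor			FALSE
MFCD00012345			FALSE
XYZ-4421			TRUE
1abc			FALSE
RYYVLZVUVIJVGH-UHFFFAOYSA-N			FALSE
KF 17837			FALSE
Bisphenol A			FALSE
alpha-tocopherol			FALSE
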
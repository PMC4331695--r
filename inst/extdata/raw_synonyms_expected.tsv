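# Hand-derived expected curation outcomes for raw_synonyms.tsv.
# Filters apply in the printed bullet order; the first failure is the
# reason code. Variants are |-separated ('|' is a forbidden character in
# terms, so the separator is unambiguous).
term	status	reason	cleaned_term	variants
command	rejected	english_word	NA	
surpass	rejected	english_word	NA	
abc	rejected	too_short	NA	
-ol	rejected	too_short	NA	
-phenyl	rejected	hyphen_boundary	NA	
chloride)	rejected	unbalanced_brackets	NA	
paracetamol (INN)	accepted	NA	paracetamol	paracetamol
paracetamol (Tylenol)	rejected	unknown_qualifier	NA	
TNF (TN)	rejected	too_short	NA	
AstraZeneca	rejected	dubious_synonym	NA	
what?ever	rejected	forbidden_character	NA	
somatostatin-28	rejected	biopolymer	NA	
stachyose	rejected	biopolymer	NA	
2,4-D, sodium salt	rejected	comma_space	NA	
acetone derivative	rejected	context_qualifier	NA	
solution of ethanol	rejected	context_qualifier	NA	
gene product	rejected	dubious_word	NA	
EGFR inhibitor	rejected	dubious_word	NA	
MFCD00012345	rejected	catalogue_number	NA	
XYZ-4421	rejected	catalogue_number	NA	
1abc	rejected	pdb_code	NA	
RYYVLZVUVIJVGH-UHFFFAOYSA-N	rejected	inchi_key	NA	
KF 17837	accepted	NA	KF 17837	KF 17837|KF17837|KF-17837
Bisphenol A	accepted	NA	Bisphenol A	Bisphenol A|Bisphenol-A
alpha-tocopherol	accepted	NA	alpha-tocopherol	alpha-tocopherol|α-tocopherol
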
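gene_id	protein_name	function_label	mode	log2fc_RpV	log2fc_RpM	log2fc_RpVM
SPO3479	glycolate oxidase (glcE)	Carbon source - Glycolate	competition	-0.44
SPO3805	Methylthioacryloyl-CoA hydratase (dmdD)	Carbon source - DMSP	competition		-0.11
SPO2708	carnitine dehydratase	Carbon/nitrogen source - carnitine	competition	-0.16
SPO1586	N-methylglutamate dehydrogenase (mgdC)	Carbon/nitrogen source - methylamine	competition		-0.18
SPO3360	2-amino-3-ketobutyrate co-A ligase (kbl)	Carbon/nitrogen source - threonine	competition			-0.12
SPO0673	taurine--pyruvate aminotransferase (tpa)	Carbon/nitrogen source - taurine	competition		-0.2
SPO0397	protein-P-II uridylyltransferase (glnD)	Nitrogen acquisition	competition			-6.5
SPO3661	allophanate hydrolase family protein	Nitrogen acquisition	competition	-0.24	-0.24	-0.29
SPO0891	alkylphosphonate utilization protein (phnM)	Phosphate acquisition	competition		-0.11
SPO1727	polyphosphate kinase 2, putative	Phosphate storage	competition			-2.2
SPO1213	oligopeptide ABC transporter, ATP-binding	Transporter - peptide	competition		-0.12
SPO2815	peptide/nickel/opine ABC transporter, permease	Transporter	competition	-0.12
SPO2816	peptide/nickel/opine ABC transporter, permease	Transporter	competition	-0.14
SPO1814	TRAP dicarboxylate transporter (dctP)	Transporter - organic acid	competition	-0.21	-0.2	-0.18
SPO1816	TRAP dicarboxylate transporter (dctM)	Transporter - organic acid	competition		-0.17	-0.18
SPO2626	TRAP transporter (dctM)	Transporter - organic acid	competition	-0.13		-0.12
SPO2627	C4 dicarbodylateTRAP transporter (dctQ)	Transporter - organic acid	competition	-0.17		-0.65
SPO2630	C4-dicarboxylate TRAP regulatory protein	Transporter - organic acid	competition	-0.25
SPOA0238	TRAP dicarboxylate transporter (dctP)	Transporter - organic acid	competition	-0.18	-0.2	-0.18
SPOA0240	TRAP transporter (dctM)	Transporter - organic acid	competition	-0.14	-0.14	-0.14
SPOA0237	C4-dicarboxylate transport transcriptional regulatory protein (dctD-2)	Transporter - organic acid	competition	-0.27	-0.25	-0.22
SPO0521	glutamate/glutamine/aspartate/asparagine ABC transporter, permease	Transporter - N-rich amino acid	competition			0.22
SPO0715	phosphocarrier protein HPr	Transporter - sugar	competition		1.2
SPOA0249	TRAP dicarboxylate transporter (dctP)	Transporter - organic acid	competition			0.13
SPO1496	ABC transporter, permease	Transporter	competition		0.38
SPOA0367	ABC transporter, permease	Transporter	competition	0.12
SPO0018	argininosuccinate synthase (argG)	Arginine	crossfeeding	3.5	3
SPO0332	argininosuccinate lyase (argH)	Arginine	crossfeeding	2.8
SPO0422	2-isopropylmalate synthase (leuA)	Leucine	crossfeeding		0.6
SPO0210	3-isopropylmalate dehydrogenase (leuB)	Leucine	crossfeeding			2.4
SPO0215	3-isopropylmalate dehydratase (leuD-1)	Leucine	crossfeeding	1.1		0.77
SPO1351	O-succinylhomoserine sulfhydrylase (metZ)	Homocysteine	crossfeeding	3
SPO1734	homoserine dehydrogenase (hom)	Homoserine	crossfeeding		5
SPO1884	S-methyltransferase component of split metH	Methionine	crossfeeding			3.9
SPO1973	3-dehydroquinate dehydratase, type II (aroQ)	Aromatic amino acids	crossfeeding	3.9
SPO2150	anthranilate phosphoribosyltransferase (trpD)	Tryptophan	crossfeeding	3.6		2.3
SPO2151	indole-3-glycerol phosphate synthase (trpC)	Tryptophan	crossfeeding	4.4
SPO3768	glutamate synthase (gltB)	Glutamate	crossfeeding	0.9		0.75
SPO2634	sulfite reductase	Amino acid - sulfur assimilation	crossfeeding	4.8
SPO2635	phosophoadenylyl-sulfate reductase (cysH)	Amino acid - sulfur assimilation	crossfeeding		4.2
SPO0102	3-methyl-2-oxobutanoate hydroxymethyltransferase (panB)	Vitamin B5	crossfeeding	0.43	0.42	0.44
SPO3224	cobalamin biosynthetic protein (cobC)	Vitamin B12	crossfeeding			6.2
SPO3633	molybdopterin converting factor, subunit 2	Molybdopterin	crossfeeding	0.41		0.3
SPO3634	molybdopterin converting factor, subunit 1 (moaD)	Molybdopterin	crossfeeding			0.3
SPO0284	dihydroorotase, multifunctional complex	Pyrimidine	crossfeeding			2.2
SPO2654	orotate phosphoribosyltransferase (pyrE)	Pyrimidine	crossfeeding	4.9
SPO1318	adenylosuccinate synthetase (purA)	Purine	crossfeeding		3.6	5.2
SPO1870	phosphoribosylformylglycinamidine synthase II (purL)	Purine	crossfeeding			3.1
SPO2168	phosphoribosylglycinamide formyltransferase (purN)	Purine	crossfeeding	1.6
SPO2677	amidophosphoribosyltransferase (purF)	Purine	crossfeeding	1.2
SPO1240	type I secretion outer membrane protein (tolC)	Antimicrobial/Efflux	chemically_mediated	0.9		0.9
SPO1928	Tat (twin-arginine translocation) pathway signal sequence domain protein	Antimicrobial/Efflux	chemically_mediated		-0.13
SPO3091	type II secretion system protein F (gspF)	Antimicrobial/Efflux	chemically_mediated		-0.11	-0.13
SPO1757	capsular polysaccharide export protein (kpsS)	Efflux	chemically_mediated			-0.18
SPO2713	Protein translocase subunit SecA 2 (secA2)	Efflux	chemically_mediated		-0.42
SPO2251	gene transfer agent (orfg14)	Gene transfer	chemically_mediated	-0.84
SPO0071	competence protein F, putative	Gene transfer	chemically_mediated	-0.13		-0.2
SPOA0111	indolepyruvate oxidoreductase (iorA)	Signaling - auxin	chemically_mediated			-0.12
SPO2287	autoinducer synthesis protein	Signaling	chemically_mediated			0.12
SPO3073	cytochrome c oxidase, subunit III (ctaE)	Aerobic respiration	altered_environment	0.43	0.33
SPO3075	Protoheme IX farnesyltransferase (ctaB)	Aerobic respiration	altered_environment	0.87	0.68	0.86
SPO3076	cytochrome c oxidase, subunit II (ctaC)	Aerobic respiration	altered_environment		0.47	0.49
SPO1383	cytochrome c oxidase, aa3-type, subunit I (ctaD)	Aerobic respiration	altered_environment	0.43
SPOA0212	nitric oxide reductase F protein	Respiration	altered_environment			0.31
SPO2099	cytochrome c-554 (cycF)	Respiration	altered_environment	-0.15
SPO1898	cytochrome P450 family protein	Respiration	altered_environment	-0.14
SPOA0223	cytochrome cd1 nitrite reductase (nirF)	Respiration	altered_environment	-0.17
SPO0935	nitroreductase family protein	Respiration	altered_environment			-0.17
SPO2340	superoxide dismutase, Fe (sodB)	Reactive oxygen species	altered_environment	1.7		2.1
SPO_Sp16SA	16S rRNA	Cell cycle/growth	altered_environment			0.11
SPO_Sp16SB	16S rRNA	Cell cycle/growth	altered_environment			0.13
SPO_Sp16SC	16S rRNA	Cell cycle/growth	altered_environment			0.14
SPO0503	ribosomal protein L30 (rpmD)	Cell cycle/growth	altered_environment			0.34
SPO1443	ATP-dependent RNA helicase RhlE (rhlE)	Cell cycle/growth	altered_environment	0.44	0.36	0.42
SPO3256	ribosomal protein L31 (rpmE)	Cell cycle/growth	altered_environment		3.9
SPO0691	GTP-binding protein Era (era)	Cell cycle/growth	altered_environment	0.78	0.84
SPO2819	NAD(P)+ transhydrogenase, beta (pntB)	Energy	altered_environment	0.39	0.36
SPO2820	NAD(P) transhydrogenase, alpha (pntA)	Energy	altered_environment			0.36
SPO0095	nicotinate phosphoribosyltransferase (pncB)	Energy	altered_environment	0.11
SPO1519	carbon monoxide dehydrogenase, large subunit (coxL-1)	Energy - carbon monoxide	altered_environment	-0.17		-0.23
SPO3901	carbon monoxide dehydrogenase G protein, putative	Energy - carbon monoxide	altered_environment			-0.31
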
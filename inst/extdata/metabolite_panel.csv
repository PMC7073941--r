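metabolite_id,name,abbreviation,met_class,method,is_kind,pathway_position
Ala,Alanine,Ala,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:pyruvate_family
Arg,Arginine,Arg,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:glutamate_family
Asn,Asparagine,Asn,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:aspartate_family
Asp,Aspartic acid,Asp,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:aspartate_family
Cys,Cysteine,Cys,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:serine_family
Gln,Glutamine,Gln,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:glutamate_family
Glu,Glutamic acid,Glu,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:glutamate_family
Gly,Glycine,Gly,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:serine_family
His,Histidine,His,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:histidine
Ile,Isoleucine,Ile,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:branched_chain
Leu,Leucine,Leu,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:branched_chain
Lys,Lysine,Lys,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:aspartate_family
Met,Methionine,Met,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:aspartate_family
Phe,Phenylalanine,Phe,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:aromatic
Pro,Proline,Pro,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:glutamate_family
Ser,Serine,Ser,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:serine_family
Thr,Threonine,Thr,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:aspartate_family
Trp,Tryptophan,Trp,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:aromatic
Tyr,Tyrosine,Tyr,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:aromatic
Val,Valine,Val,amino_acid,LC_amino_acid,labeled_amino_acid_mix,amino_acids:branched_chain
AMP,Adenosine monophosphate,AMP,nucleoside_phosphate,capIC,labeled_extract,nucleotides:adenylate
ADP,Adenosine diphosphate,ADP,nucleoside_phosphate,capIC,labeled_extract,nucleotides:adenylate
ATP,Adenosine triphosphate,ATP,nucleoside_phosphate,capIC,labeled_extract,nucleotides:adenylate
GMP,Guanosine monophosphate,GMP,nucleoside_phosphate,capIC,labeled_extract,nucleotides:guanylate
GDP,Guanosine diphosphate,GDP,nucleoside_phosphate,capIC,labeled_extract,nucleotides:guanylate
GTP,Guanosine triphosphate,GTP,nucleoside_phosphate,capIC,labeled_extract,nucleotides:guanylate
CMP,Cytidine monophosphate,CMP,nucleoside_phosphate,capIC,labeled_extract,nucleotides:cytidylate
CDP,Cytidine diphosphate,CDP,nucleoside_phosphate,capIC,labeled_extract,nucleotides:cytidylate
CTP,Cytidine triphosphate,CTP,nucleoside_phosphate,capIC,labeled_extract,nucleotides:cytidylate
UMP,Uridine monophosphate,UMP,nucleoside_phosphate,capIC,labeled_extract,nucleotides:uridylate
UDP,Uridine diphosphate,UDP,nucleoside_phosphate,capIC,labeled_extract,nucleotides:uridylate
UTP,Uridine triphosphate,UTP,nucleoside_phosphate,capIC,labeled_extract,nucleotides:uridylate
dAMP,Deoxyadenosine monophosphate,dAMP,deoxynucleoside_phosphate,capIC,labeled_extract,deoxynucleotides:adenylate
dADP,Deoxyadenosine diphosphate,dADP,deoxynucleoside_phosphate,capIC,labeled_extract,deoxynucleotides:adenylate
dATP,Deoxyadenosine triphosphate,dATP,deoxynucleoside_phosphate,capIC,labeled_extract,deoxynucleotides:adenylate
dGMP,Deoxyguanosine monophosphate,dGMP,deoxynucleoside_phosphate,capIC,labeled_extract,deoxynucleotides:guanylate
dGDP,Deoxyguanosine diphosphate,dGDP,deoxynucleoside_phosphate,capIC,labeled_extract,deoxynucleotides:guanylate
dGTP,Deoxyguanosine triphosphate,dGTP,deoxynucleoside_phosphate,capIC,labeled_extract,deoxynucleotides:guanylate
dCMP,Deoxycytidine monophosphate,dCMP,deoxynucleoside_phosphate,capIC,labeled_extract,deoxynucleotides:cytidylate
dCDP,Deoxycytidine diphosphate,dCDP,deoxynucleoside_phosphate,capIC,labeled_extract,deoxynucleotides:cytidylate
dCTP,Deoxycytidine triphosphate,dCTP,deoxynucleoside_phosphate,capIC,labeled_extract,deoxynucleotides:cytidylate
dTMP,Deoxythymidine monophosphate,dTMP,deoxynucleoside_phosphate,capIC,labeled_extract,deoxynucleotides:thymidylate
dTDP,Deoxythymidine diphosphate,dTDP,deoxynucleoside_phosphate,capIC,labeled_extract,deoxynucleotides:thymidylate
dTTP,Deoxythymidine triphosphate,dTTP,deoxynucleoside_phosphate,capIC,labeled_extract,deoxynucleotides:thymidylate
G6P,Glucose 6-phosphate,G6P,glycolysis,capIC,labeled_extract,glycolysis:1
F6P,Fructose 6-phosphate,F6P,glycolysis,capIC,labeled_extract,glycolysis:2
FBP,Fructose 1.6-bisphosphate,FBP,glycolysis,capIC,labeled_extract,glycolysis:3
DHAP,Dihydroxyacetone phosphate,DHAP,glycolysis,capIC,labeled_extract,glycolysis:4
GA3P,Glyceraldehyde 3-phosphate,GA3P,glycolysis,capIC,labeled_extract,glycolysis:5
PG3,3-Phosphoglyceric acid,3PG,glycolysis,capIC,labeled_extract,glycolysis:6
PEP,Phosphoenolpyruvic acid,PEP,glycolysis,capIC,labeled_extract,glycolysis:7
PYR,Pyruvic acid,Pyr,glycolysis,LC_organic_acid,matched_isotopologue,glycolysis:8
PG6,6-Phosphogluconic acid,6PG,PPP,capIC,labeled_extract,ppp:1
RU5P,Ribulose 5-phosphate,RL5P,PPP,capIC,labeled_extract,ppp:2
R5P,Ribose 5-phosphate,R5P,PPP,capIC,labeled_extract,ppp:3
S7P,Sedoheptulose 7-phosphate,S7P,PPP,capIC,labeled_extract,ppp:4
E4P,Erythrose 4-phosphate,E4P,PPP,capIC,labeled_extract,ppp:5
CIT,Citric acid,Cit,TCA,capIC,labeled_extract,tca:1
AKG,Alpha-ketoglutaric acid,aKG,TCA,capIC,labeled_extract,tca:2
SUC,Succinic acid,Suc,TCA,capIC,labeled_extract,tca:3
FUM,Fumaric acid,Fum,TCA,capIC,labeled_extract,tca:4
MAL,Malic acid,Mal,TCA,capIC,labeled_extract,tca:5
OAA,Oxaloacetic acid,OAA,TCA,capIC,labeled_extract,tca:6
LAC,Lactic acid,Lac,organic_acid_other,LC_organic_acid,matched_isotopologue,overflow:lactate
ACE,Acetic acid,Ace,organic_acid_other,LC_organic_acid,labeled_extract,overflow:acetate
GLX,Glyoxylic acid,Glx,organic_acid_other,LC_organic_acid,labeled_extract,anaplerosis:glyoxylate
UDPG,UDP-glucose,UDP-glc,organic_acid_other,capIC,labeled_extract,sugar_nucleotides:udp_glucose
UDPGAL,UDP-galactose,UDP-gal,organic_acid_other,capIC,labeled_extract,sugar_nucleotides:udp_galactose
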
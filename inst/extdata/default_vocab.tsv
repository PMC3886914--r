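word	category	weight
protease	Digestive enzymes	1
proteinase	Digestive enzymes	1
peptidase	Digestive enzymes	1
cathepsin	Digestive enzymes	1
trypsin	Digestive enzymes	1
chymotrypsin	Digestive enzymes	1
pepsin	Digestive enzymes	1
carboxypeptidase	Digestive enzymes	1
aminopeptidase	Digestive enzymes	1
amylase	Digestive enzymes	1
maltase	Digestive enzymes	1
glucosidase	Digestive enzymes	1
galactosidase	Digestive enzymes	1
lipase	Digestive enzymes	1
phospholipase	Digestive enzymes	1
nuclease	Digestive enzymes	1
chitinase	Digestive enzymes	1
aspartyl protease	Digestive enzymes	1
serpin	Protease inhibitors	1
cystatin	Protease inhibitors	1
protease inhibitor	Protease inhibitors	2
proteinase inhibitor	Protease inhibitors	2
kunitz	Protease inhibitors	1
kazal	Protease inhibitors	1
transporter	Transporters/storage	1
symporter	Transporters/storage	1
antiporter	Transporters/storage	1
channel	Transporters/storage	1
aquaporin	Transporters/storage	1
ferritin	Transporters/storage	1
vitellogenin	Transporters/storage	1
hexamerin	Transporters/storage	1
atpase	Transporters/storage	1
permease	Transporters/storage	1
collagen	Extracellular matrix/cell adhesion	1
laminin	Extracellular matrix/cell adhesion	1
integrin	Extracellular matrix/cell adhesion	1
cadherin	Extracellular matrix/cell adhesion	1
fibronectin	Extracellular matrix/cell adhesion	1
cuticle	Extracellular matrix/cell adhesion	1
cuticular	Extracellular matrix/cell adhesion	1
adhesion	Extracellular matrix/cell adhesion	1
mucin	Mucins	1
lysozyme	Immunity	1
defensin	Immunity	1
lectin	Immunity	1
galectin	Immunity	1
peptidoglycan	Immunity	1
toll	Immunity	1
relish	Immunity	1
immune	Immunity	1
antimicrobial	Immunity	1
prophenoloxidase	Immunity	1
lipocalin	Lipocalins	1
nitrophorin	Lipocalins	1
biliprotein	Lipocalins	1
secreted	Other secreted	1
antigen	Other secreted	1
salivary	Other secreted	1
odorant	Odorant binding proteins	1
takeout	Odorant binding proteins	1
chemosensory	Odorant binding proteins	1
juvenile hormone binding	Odorant binding proteins	1
peroxidase	Oxidant metabolism/detoxification	1
catalase	Oxidant metabolism/detoxification	1
superoxide dismutase	Oxidant metabolism/detoxification	1
glutathione	Oxidant metabolism/detoxification	1
thioredoxin	Oxidant metabolism/detoxification	1
cytochrome p450	Oxidant metabolism/detoxification	1
detoxification	Oxidant metabolism/detoxification	1
sulfotransferase	Oxidant metabolism/detoxification	1
peritrophin	Peritrophins	1
peritrophic	Peritrophins	1
chitin binding	Peritrophins	1
actin	Cytoskeletal	1
tubulin	Cytoskeletal	1
myosin	Cytoskeletal	1
dynein	Cytoskeletal	1
kinesin	Cytoskeletal	1
spectrin	Cytoskeletal	1
tropomyosin	Cytoskeletal	1
filamin	Cytoskeletal	1
cytoskeleton	Cytoskeletal	1
ribosomal	Protein synthesis machinery	1
ribosome	Protein synthesis machinery	1
elongation factor	Protein synthesis machinery	1
initiation factor	Protein synthesis machinery	1
trna synthetase	Protein synthesis machinery	1
aminoacyl	Protein synthesis machinery	1
mitochondrial	Metabolism, energy	1
oxidase	Metabolism, energy	1
dehydrogenase	Metabolism, energy	1
atp synthase	Metabolism, energy	1
nadh	Metabolism, energy	1
citrate synthase	Metabolism, energy	1
glycolytic	Metabolism, energy	1
enolase	Metabolism, energy	1
aldolase	Metabolism, energy	1
chaperone	Protein modification machinery	1
chaperonin	Protein modification machinery	1
heat shock	Protein modification machinery	1
disulfide isomerase	Protein modification machinery	1
peptidylprolyl	Protein modification machinery	1
glycosyltransferase	Protein modification machinery	1
prolyl hydroxylase	Protein modification machinery	1
proteasome	Proteasome machinery	1
ubiquitin	Proteasome machinery	1
histone	Nuclear regulation	1
chromatin	Nuclear regulation	1
nucleosome	Nuclear regulation	1
rna polymerase	Transcription machinery	1
spliceosome	Transcription machinery	1
splicing	Transcription machinery	1
snrnp	Transcription machinery	1
ribonucleoprotein	Transcription machinery	1
gtpase	Signal transduction	1
kinase	Signal transduction	1
phosphatase	Signal transduction	1
calmodulin	Signal transduction	1
receptor	Signal transduction	1
rab	Signal transduction	1
ras	Signal transduction	1
transcription factor	Transcription factor	1
homeobox	Transcription factor	1
zinc finger	Transcription factor	1
forkhead	Transcription factor	1
aminotransferase	Metabolism, amino acid	1
tyrosine hydroxylase	Metabolism, amino acid	1
tryptophan oxygenase	Metabolism, amino acid	1
kynurenine	Metabolism, amino acid	1
arginase	Metabolism, amino acid	1
glycogen	Metabolism, carbohydrate	1
trehalose	Metabolism, carbohydrate	1
trehalase	Metabolism, carbohydrate	1
hexokinase	Metabolism, carbohydrate	1
fatty acid	Metabolism, lipid	1
acyl	Metabolism, lipid	1
lipid	Metabolism, lipid	1
sterol	Metabolism, lipid	1
apolipoprotein	Metabolism, lipid	1
desaturase	Metabolism, lipid	1
elongase	Metabolism, lipid	1
coenzyme	Metabolism, intermediate	1
pantetheinase	Metabolism, intermediate	1
biotin	Metabolism, intermediate	1
folate	Metabolism, intermediate	1
nucleotide	Metabolism, nucleotide	1
purine	Metabolism, nucleotide	1
pyrimidine	Metabolism, nucleotide	1
adenylate	Metabolism, nucleotide	1
signal recognition	Protein export machinery	1
translocon	Protein export machinery	1
sec61	Protein export machinery	1
coatomer	Protein export machinery	1
clathrin	Protein export machinery	1
snare	Protein export machinery	1
exportin	Nuclear export	1
nucleoporin	Nuclear export	1
transposase	Transposable element	1
transposon	Transposable element	1
retrotransposon	Transposable element	1
reverse transcriptase	Transposable element	1
gag	Transposable element	1
pol polyprotein	Transposable element	1
virus	Viral	1
viral	Viral	1
capsid	Viral	1
virion	Viral	1
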
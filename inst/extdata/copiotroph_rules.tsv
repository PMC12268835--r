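rank	name	group
class	Alphaproteobacteria	copiotroph
class	Gammaproteobacteria	copiotroph
phylum	Bacteroidetes	copiotroph
phylum	Actinobacteria	copiotroph
phylum	Firmicutes	copiotroph
phylum	Acidobacteria	oligotroph
phylum	Planctomycetes	oligotroph
phylum	Verrucomicrobia	oligotroph
phylum	Chloroflexi	oligotroph
phylum	Gemmatimonadetes	oligotroph
order	Rhizobiales	copiotroph
family	Chitinophagaceae	copiotroph
genus	Bacillus	copiotroph
genus	Pseudomonas	copiotroph
genus	Bradyrhizobium	oligotroph
genus	Mycobacterium	oligotroph
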
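#SENT
#PHRASE	cathepsin D (CTSD)
1000	C0007634	Cathepsin D	[Amino Acid, Peptide, or Protein]
861	C1413915	CTSD gene	[Gene or Genome]
694	C0010762	Cathepsins	[Enzyme]
500	C0033684	Proteins	[Amino Acid, Peptide, or Protein]
#PHRASE	apolipoprotein E (ApoE)
1000	C0003595	Apolipoprotein E	[Amino Acid, Peptide, or Protein]
901	C1412481	APOE gene	[Gene or Genome]
827	C0003593	Apolipoproteins	[Amino Acid, Peptide, or Protein]
756	C0002716	Amyloid Proteins	[Amino Acid, Peptide, or Protein]
466	C0023820	Lipoproteins	[Amino Acid, Peptide, or Protein]
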
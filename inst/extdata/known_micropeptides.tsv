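name	aa_sequence	start	end	strand	note
Humanin				+	16S rRNA resident micropeptide
SHLP1				+	16S rRNA resident micropeptide
SHLP2				+	16S rRNA resident micropeptide
SHLP3				+	16S rRNA resident micropeptide
SHLP4				+	16S rRNA resident micropeptide
SHLP5				+	16S rRNA resident micropeptide
SHLP6				+	16S rRNA resident micropeptide
MOTS-c				+	12S rRNA resident micropeptide
gau				+	antisense within cox1
SHMOOSE				+	tRNA-Ser resident, overlaps nd5; not part of the 9-entry exclusion list used for the 227 count
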
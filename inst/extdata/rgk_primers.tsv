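# Cloning primers for zebrafish (dr_) and fruit-fly (dm_) RGK open reading
# frames. Forward primers were designed to carry an MluI site (ACGCGT) and
# reverse primers a NotI site (GCGGCCGC) for directional cloning.
name	direction	sequence
dr_Gem	forward	GATCACGCGTACCATGACCCTGCTGGCGAGCGTGC
dr_Gem	reverse	GATCGATCGCGGCCGCTTACAGACTCATCAGGTCATGAC
dr_Rad	forward	GATCACGCGTACCATGACTTTGAACAAAGGAGACAAG
dr_Rad	reverse	GATCGATCGCGGCCGCTTATAGCACTGAAAGGTCGTGGC
dr_Rem1	forward	GATCACGCGTACCATGACACTCAACACACAGAAGG
dr_Rem1	reverse	GATCGATCGCGGCCGCTCACAGCACAGCGAGGTCATGG
dr_Rem2	forward	GATCACGCGTACCATGTCGGACCAGGGTTATGGC
dr_Rem2	reverse	GATCGATCGCGGCCGCTCACATTAAAGCGCTGAGGTCG
dm_RGK1	forward	GATCACGCGTACCATGGCGCCCTTCTACAAGCGC
dm_RGK1	reverse	GATCGATCGCGGCCGCTTAGAGTACATGCAGATTCTCGC
dm_RGK2	forward	GATCACGCGTACCATGGCCCAGCAACAGCGCAGC
dm_RGK2	reverse	GATCGATCGCGGCCGCTTATAGCACATGCAGATTCTCG
dm_RGK3	forward	GATCACGCGTACCATGGTGGACGACATCTCACCG
dm_RGK3	reverse	GATCGATCGCGGCCGCTTAGAGCACCTGCAGATTCTCGC
dm_RGK2t	forward	GATCACGCGTACCATGGCCCAGCAACAGCGCAGC
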
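accession	position	amino_acid	contrast	ratio	regulated_type	p_value	description
A0A2K1WUE2	493	S	CdN/CK	1.28	Up	0.0064	eukaryotic translation initiation factor isoform (eIF)
A0A2K1XQU0	1237	S	CdN/CK	1.669	Up	0.0414	eukaryotic translation initiation factor 4G-like (eIF)
B9GP88	987	T	CdN/CK	1.704	Up	0.018	eukaryotic translation initiation factor 4G isoform X1 (eIF)
B9GP88	988	S	CdN/CK	1.899	Up	0.0271	eukaryotic translation initiation factor 4G isoform X1 (eIF)
A0A2K1XBQ3	26	S	CdN/CK	1.458	Up	0.0485	ABC transporter G family member (ABC transporter protein)
A0A2K2ACX1	110	S	CdN/CK	1.241	Up	0.00616	ABC transporter G family member (ABC transporter protein)
A0A2K1XB30	251	S	CdN/CK	1.671	Up	0.028	zinc finger family protein (ZFP)
A0A2K1XB30	382	S	CdN/CK	1.867	Up	0.0199	zinc finger family protein (ZFP)
A0A2K2ATR0	296	S	CdN/CK	1.991	Up	0.00726	zinc-finger homeodomain protein 9-like (ZFP)
B9HN74	557	S	CdN/CK	1.421	Up	0.0354	heat shock protein 70 (HSP70)
B9HV59	10	S	CdN/CK	1.345	Up	0.0299	heat shock protein 70 (HSP70)
B9HV59	12	S	CdN/CK	3.554	Up	0.00632	heat shock protein 70 (HSP70)
B9HV59	14	T	CdN/CK	1.493	Up	0.0000634	heat shock protein 70 (HSP70)
U7E2Z8	604	S	CdN/CK	2.388	Up	0.0185	heat shock-related family protein (HSP70)
W8PVS7	250	T	CdN/CK	2.7	Up	0.0191	Peroxidase (POD)
A0A2K2C6G4	246	T	CdN/CK	1.816	Up	0.0231	splicing factor 3B subunit 1-like (SF3B1)
A0A2K2C6G4	185	T	CdN/CK	2.175	Up	0.0149	splicing factor 3B subunit 1-like (SF3B1)
A0A2K2C6G4	207	T	CdN/CK	2.355	Up	0.0341	splicing factor 3B subunit 1-like (SF3B1)
A0A2K2C6G4	209	T	CdN/CK	2.086	Up	0.0351	splicing factor 3B subunit 1-like (SF3B1)
A0A2K2C6G4	353	T	CdN/CK	1.529	Up	0.0387	splicing factor 3B subunit 1-like (SF3B1)
A0A2K2C6G4	244	T	CdN/CK	1.92	Up	0.0127	splicing factor 3B subunit 1-like (SF3B1)
A0A2K2C6G4	219	T	CdN/CK	1.954	Up	0.0089	splicing factor 3B subunit 1-like (SF3B1)
A0A2K2C6G4	125	T	CdN/CK	1.484	Up	0.0462	splicing factor 3B subunit 1-like (SF3B1)
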
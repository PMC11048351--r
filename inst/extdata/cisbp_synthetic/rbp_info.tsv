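Motif_ID	RBP_Name	RBP_Species
M001_syn	NONO	Mus_musculus
M002_syn	HNRNPA2B1	Homo_sapiens
M003_syn	FUS	Mus_musculus
M004_syn	DECOY_01	Mus_musculus
M005_syn	DECOY_02	Mus_musculus
M006_syn	DECOY_03	Mus_musculus
M007_syn	DECOY_04	Mus_musculus
M008_syn	DECOY_05	Mus_musculus
M009_syn	DECOY_06	Mus_musculus
M010_syn	DECOY_07	Mus_musculus
M011_syn	DECOY_08	Mus_musculus
M012_syn	DECOY_09	Mus_musculus
M013_syn	DECOY_10	Mus_musculus
M014_syn	DECOY_11	Mus_musculus
M015_syn	DECOY_12	Mus_musculus
M016_syn	DECOY_13	Mus_musculus
M017_syn	DECOY_14	Mus_musculus
M018_syn	DECOY_15	Mus_musculus
M019_syn	DECOY_16	Mus_musculus
M020_syn	DECOY_17	Mus_musculus
M021_syn	DECOY_18	Mus_musculus
M022_syn	DECOY_19	Mus_musculus
M023_syn	DECOY_20	Mus_musculus
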
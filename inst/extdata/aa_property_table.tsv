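# Amino-acid property scales used for CDR3 middle-region scoring.
# Provenance (per column):
#   kf1..kf10  : Kidera et al. (1985) J Protein Chem 4:23-55, the ten
#                orthogonal factors; kf4 tracks hydrophobicity on an
#                inverted scale. Verified against the Peptides R package.
#   mjenergy   : Miyazawa & Jernigan (1996) J Mol Biol 256:623-644,
#                diagonal contact energies e_ii (RT units).
#   strength   : derived here as -(e_ii + mean(e_jj))/2, the mean pairwise
#                interaction affinity under the additive approximation
#                e_ij ~ (e_ii+e_jj)/2; larger = stronger predicted contact.
#   core,rim,surface : SYNTHETIC stand-ins. The published protein-protein
#                cross-docking interface propensities were not obtainable
#                in this build environment; these columns are monotone
#                constructs (core = rescaled Kyte-Doolittle burial
#                propensity; rim = bulky-but-not-buried; surface = small/
#                polar residues predicted to keep accessibility unchanged).
#                Do not interpret their absolute values.
#   alpha,beta,turn : Chou & Fasman (1978) conformational propensities.
#   disorder   : TOP-IDP scale, Campen et al. (2008).
#   volume     : Zamyatnin (1972) residue volumes, A^3. The five bulkiest
#                residues are W, Y, F, R, K.
#   polarity   : Grantham (1974).
#   charge     : net side-chain charge at pH 7 (H = +0.1).
#   hydropathy : Kyte & Doolittle (1982).
aa	kf1	kf2	kf3	kf4	kf5	kf6	kf7	kf8	kf9	kf10	strength	mjenergy	core	rim	surface	alpha	beta	turn	disorder	volume	polarity	charge	hydropathy
A	-1.56	-1.67	-0.97	-0.27	-0.93	-0.78	-0.2	-0.08	0.21	-0.48	3.0592	-2.72	0.7	0.051	0.565	1.42	0.83	0.66	0.06	88.6	8.1	0	1.8
R	0.22	1.27	1.37	1.87	-1.7	0.46	0.92	-0.39	0.23	0.93	2.4742	-1.55	0	0.6756	0.6622	0.98	0.93	0.95	0.18	173.4	10.5	1	-4.5
N	1.14	-0.07	-0.12	0.81	0.18	0.37	-0.09	1.23	1.1	-1.73	2.5392	-1.68	0.1111	0.2862	0.7834	0.67	0.89	1.56	0.007	114.1	11.6	0	-3.5
D	0.58	-0.22	-1.58	0.81	-0.92	0.15	-1.52	0.47	0.76	0.7	2.4992	-1.6	0.1111	0.2703	0.7924	1.01	0.54	1.46	0.192	111.1	13	-1	-3.5
C	0.12	-0.89	0.45	-1.05	-0.71	2.41	1.52	-0.69	1.13	1.1	4.4192	-5.44	0.7778	0.0641	0.4668	0.7	1.19	1.19	0.02	108.5	5.5	0	2.5
Q	-0.47	0.24	0.07	1.1	1.1	0.59	0.84	-0.71	-0.03	-2.33	2.4692	-1.54	0.1111	0.4436	0.6949	1.11	1.1	0.98	0.318	143.8	10.5	0	-3.5
E	-1.45	0.19	-1.61	1.17	-1.31	0.4	0.04	0.38	-0.35	-0.12	2.4542	-1.51	0.1111	0.415	0.711	1.51	0.37	0.74	0.736	138.4	12.3	-1	-3.5
G	1.46	-1.96	-0.23	-0.16	0.1	-0.11	1.32	2.36	-1.66	0.46	2.8193	-2.24	0.4556	0	0.7722	0.57	0.75	1.56	0.166	60.1	9	0	-0.4
H	-0.41	0.52	-0.28	0.28	1.61	1.01	-1.85	0.47	1.13	1.63	3.2242	-3.05	0.1444	0.475	0.6502	1	0.87	0.95	0.303	153.2	10.4	0.1	-3.2
I	-0.73	-0.16	1.79	-0.77	-0.54	0.03	-0.83	0.51	0.66	-1.78	4.9692	-6.54	1	0	0.1822	1.08	1.6	0.47	-0.486	166.7	5.2	0	4.5
L	-1.04	0	-0.24	-1.1	-0.55	-2.05	0.96	-0.76	0.45	0.93	5.3842	-7.37	0.9222	0.0494	0.2211	1.21	1.3	0.59	-0.326	166.7	4.9	0	3.8
K	-0.34	0.82	-0.23	1.7	1.54	-1.62	1.15	-0.08	-0.48	0.6	1.7592	-0.12	0.0667	0.6039	0.6432	1.16	0.74	1.01	0.586	168.6	11.3	1	-3.9
M	-1.4	0.18	-0.42	-0.73	2	1.52	0.26	0.11	-1.27	0.27	4.4292	-5.46	0.7111	0.1771	0.3379	1.45	1.05	0.6	-0.397	162.9	5.7	0	1.9
F	-0.21	0.98	-0.36	-1.43	0.22	-0.81	0.67	1.1	1.71	-0.44	5.3292	-7.26	0.8111	0.1462	0.2074	1.13	1.38	0.6	-0.697	189.9	5.2	0	2.8
P	2.06	-0.33	-1.15	-0.75	0.88	-0.45	0.3	-2.3	0.74	-0.28	2.5743	-1.75	0.3222	0.2126	0.6821	0.57	0.55	1.52	0.987	112.7	8	0	-1.6
S	0.81	-1.08	0.16	0.42	-0.21	-0.43	-1.89	-1.15	-0.97	-0.23	2.5343	-1.67	0.4111	0.1015	0.7083	0.77	0.75	1.43	0.341	89	9.2	0	-0.8
T	0.26	-0.7	1.21	0.63	-0.1	0.21	0.24	-1.15	-0.56	0.19	2.5592	-1.72	0.4222	0.1929	0.6219	0.83	1.19	0.96	0.059	116.1	8.6	0	-0.7
W	0.3	2.1	-0.72	-1.57	-1.16	0.57	-0.48	-0.4	-2.3	-0.6	4.2292	-5.06	0.4	0.6	0.3	1.08	1.37	0.96	-0.884	227.8	5.4	0	-0.9
Y	1.38	1.48	0.8	-0.56	0	-0.68	-0.31	1.03	-0.05	0.53	3.7843	-4.17	0.3556	0.513	0.4242	0.69	1.47	1.14	-0.51	193.6	6.2	0	-1.3
V	-0.74	-0.71	2.04	-0.4	0.5	-0.81	-1.07	0.06	-0.46	0.65	4.4592	-5.52	0.9667	0.0159	0.2784	1.06	1.7	0.5	-0.121	140	5.9	0	4.2
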
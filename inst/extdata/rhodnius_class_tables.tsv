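table	class	n_contigs	n_reads	reads_per_contig	pct_reads
1	Digestive enzymes	25	12861	514.4	7.7
1	Transporters/storage	16	7532	470.8	4.5
1	Extracellular matrix/cell adhesion	12	4489	374.1	2.7
1	Mucins	8	8277	1034.6	5.0
1	Immunity	6	11306	1884.3	6.8
1	Lipocalins	6	4357	726.2	2.6
1	Other secreted	6	2175	362.5	1.3
1	Odorant binding proteins	4	557	139.3	0.3
1	Oxidant metabolism/detoxification	4	1683	420.8	1.0
1	Peritrophins	2	74	37.0	0.0
1	Cytoskeletal	13	21773	1674.8	13.1
1	Protein synthesis machinery	19	12286	646.6	7.4
1	Metabolism, energy	23	11184	486.3	6.7
1	Protein modification machinery	10	11092	1109.2	6.7
1	Proteasome machinery	15	9637	642.5	5.8
1	Unknown, conserved	44	5249	119.3	3.2
1	Nuclear regulation	4	2708	677.0	1.6
1	Transcription machinery	17	2260	132.9	1.4
1	Signal transduction	27	1902	70.4	1.1
1	Transcription factor	10	1858	185.8	1.1
1	Metabolism, intermediate	5	1387	277.4	0.8
1	Protein export machinery	11	1274	115.8	0.8
1	Metabolism, carbohydrate	5	541	108.2	0.3
1	Metabolism, lipid	6	462	77.0	0.3
1	Metabolism, amino acid	4	129	32.3	0.1
1	Metabolism, nucleotide	1	95	95.0	0.1
1	Nuclear export	1	17	17.0	0.0
1	Unknown	193	23028	119.3	13.8
1	Transposable element	12	6425	535.4	3.9
2	Digestive enzymes	6	965	160.8	8.6
2	Protease inhibitors	1	266	266.0	2.4
2	Transporters/storage	4	223	55.8	2.0
2	Other secreted	1	104	104.0	0.9
2	Mucins	1	47	47.0	0.4
2	Oxidant metabolism/detoxification	1	32	32.0	0.3
2	Signal transduction	13	859	66.1	7.7
2	Transcription factor	3	722	240.7	6.5
2	Unknown, conserved	11	493	44.8	4.4
2	Cytoskeletal	3	466	155.3	4.2
2	Metabolism, amino acid	2	262	131.0	2.3
2	Protein export machinery	5	202	40.4	1.8
2	Transcription machinery	4	197	49.3	1.8
2	Metabolism, carbohydrate	2	90	45.0	0.8
2	Protein modification machinery	2	77	38.5	0.7
2	Metabolism, energy	1	56	56.0	0.5
2	Proteasome machinery	2	48	24.0	0.4
2	Unknown	68	5638	82.9	50.5
2	Transposable element	4	236	59.0	2.1
2	Viral	1	174	174.0	1.6
3	Other secreted	1	132	132.0	0.4
3	Transporters/storage	8	428	53.5	1.3
3	Digestive enzymes	22	8549	388.6	26.9
3	Mucins	2	3609	1804.5	11.4
3	Odorant binding proteins	4	1020	255.0	3.2
3	Immunity	2	325	162.5	1.0
3	Oxidant metabolism/detoxification	2	137	68.5	0.4
3	Nuclear regulation	2	148	74.0	0.5
3	Transcription factor	2	61	30.5	0.2
3	Transcription machinery	3	389	129.7	1.2
3	Protein synthesis machinery	5	129	25.8	0.4
3	Protein export machinery	2	72	36.0	0.2
3	Protein modification machinery	3	310	103.3	1.0
3	Proteasome machinery	1	64	64.0	0.2
3	Metabolism, carbohydrate	2	222	111.0	0.7
3	Metabolism, amino acid	2	45	22.5	0.1
3	Metabolism, lipid	2	266	133.0	0.8
3	Metabolism, intermediate	1	178	178.0	0.6
3	Signal transduction	7	191	27.3	0.6
3	Extracellular matrix/cell adhesion	6	4501	750.2	14.2
3	Cytoskeletal	5	187	37.4	0.6
3	Metabolism, energy	6	5158	859.7	16.2
3	Unknown, conserved	14	1109	79.2	3.5
3	Unknown	66	4527	68.6	14.2
3	Transposable element	1	29	29.0	0.1
4	Transporters/storage	7	1292	184.6	3.6
4	Oxidant metabolism/detoxification	3	902	300.7	2.5
4	Other secreted	2	296	148.0	0.8
4	Digestive enzymes	3	244	81.3	0.7
4	Odorant binding proteins	3	193	64.3	0.5
4	Peritrophins	1	18	18.0	0.1
4	Cytoskeletal	17	4562	268.4	12.8
4	Transcription machinery	7	3803	543.3	10.7
4	Unknown, conserved	21	3351	159.6	9.4
4	Protein synthesis machinery	5	2130	426.0	6.0
4	Metabolism, amino acid	3	1656	552.0	4.7
4	Extracellular matrix/cell adhesion	8	1367	170.9	3.8
4	Metabolism, lipid	3	824	274.7	2.3
4	Metabolism, energy	6	704	117.3	2.0
4	Protein modification machinery	2	656	328.0	1.8
4	Signal transduction	6	554	92.3	1.6
4	Nuclear regulation	5	534	106.8	1.5
4	Transcription factor	1	462	462.0	1.3
4	Protein export machinery	5	457	91.4	1.3
4	Metabolism, carbohydrate	1	423	423.0	1.2
4	Proteasome machinery	2	214	107.0	0.6
4	Unknown	69	8609	124.8	24.2
4	Transposable element	4	2355	588.8	6.6
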
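id1	id2	chrom	length_cm
IND02	IND05	chr1	11.375
IND02	IND05	chr1	12.625
IND03	IND01	chr2	8.625
IND06	IND05	chr2	8.875
IND05	IND02	chr2	11.125
IND04	IND06	chr3	8.375
IND03	IND06	chr3	9.375
IND02	IND03	chr3	10.375
IND06	IND03	chr3	14.625
IND06	IND01	chr4	9.875
IND03	IND02	chr5	9.125
IND04	IND03	chr5	9.125
IND05	IND01	chr5	11.125
IND04	IND02	chr5	15.125
IND01	IND06	chr6	12.375
IND02	IND03	chr7	8.125
IND03	IND01	chr7	8.625
IND02	IND01	chr7	12.125
IND05	IND03	chr7	18.375
IND03	IND02	chr8	8.125
IND06	IND03	chr8	16.125
IND03	IND01	chr9	9.375
IND01	IND05	chr11	9.375
IND03	IND04	chr11	9.875
IND04	IND06	chr11	13.625
IND04	IND06	chr11	17.125
IND04	IND06	chr11	18.875
IND04	IND06	chr12	8.125
IND05	IND04	chr12	10.125
IND05	IND01	chr12	12.375
IND05	IND06	chr14	9.125
IND04	IND06	chr14	9.375
IND02	IND01	chr15	11.125
IND05	IND01	chr17	8.125
IND05	IND02	chr17	9.125
IND05	IND03	chr17	12.875
IND04	IND03	chr18	9.125
IND05	IND06	chr20	8.125
IND04	IND03	chr20	10.625
IND02	IND04	chr20	12.875
IND04	IND05	chr21	8.375
IND01	IND05	chr21	16.375
IND04	IND01	chr22	18.625
IND09	IND10	chr1	8.375
IND11	IND08	chr1	9.875
IND08	IND09	chr2	9.625
IND11	IND07	chr4	10.375
IND12	IND11	chr5	14.625
IND08	IND07	chr6	13.375
IND12	IND09	chr7	8.375
IND08	IND07	chr7	10.875
IND11	IND09	chr7	16.125
IND12	IND10	chr7	19.375
IND08	IND07	chr8	8.125
IND07	IND11	chr8	8.875
IND11	IND12	chr8	11.375
IND07	IND11	chr9	14.875
IND11	IND10	chr10	10.125
IND07	IND08	chr14	8.375
IND07	IND10	chr15	8.125
IND11	IND12	chr15	8.375
IND10	IND09	chr16	8.375
IND12	IND11	chr17	8.875
IND07	IND12	chr17	9.125
IND08	IND12	chr18	8.625
IND12	IND09	chr18	9.125
IND12	IND10	chr18	10.375
IND07	IND11	chr19	8.125
IND08	IND07	chr19	8.625
IND12	IND07	chr19	11.875
IND08	IND10	chr19	13.625
IND12	IND07	chr21	15.625
IND02	IND08	chr1	8.375
IND04	IND12	chr1	8.625
IND05	IND12	chr1	9.875
IND05	IND08	chr1	10.375
IND02	IND10	chr1	11.125
IND06	IND12	chr1	13.875
IND02	IND09	chr1	14.375
IND02	IND08	chr1	16.125
IND02	IND11	chr1	17.125
IND01	IND08	chr2	8.375
IND06	IND09	chr2	8.375
IND02	IND07	chr2	8.625
IND02	IND10	chr2	8.875
IND02	IND10	chr2	8.875
IND03	IND11	chr2	9.375
IND02	IND10	chr2	9.625
IND01	IND11	chr2	10.625
IND01	IND08	chr2	12.125
IND03	IND07	chr3	14.125
IND06	IND11	chr3	16.375
IND05	IND11	chr4	10.375
IND02	IND11	chr4	18.875
IND01	IND12	chr5	8.125
IND06	IND07	chr5	9.875
IND03	IND08	chr5	11.125
IND05	IND09	chr5	11.625
IND03	IND09	chr5	12.375
IND04	IND10	chr5	14.875
IND01	IND11	chr6	11.375
IND01	IND11	chr6	17.375
IND03	IND11	chr6	18.375
IND05	IND09	chr7	9.375
IND06	IND11	chr7	10.625
IND02	IND11	chr7	12.625
IND06	IND09	chr7	14.625
IND06	IND12	chr8	10.125
IND05	IND09	chr8	13.375
IND06	IND10	chr8	17.625
IND04	IND12	chr9	8.375
IND03	IND09	chr9	8.625
IND06	IND10	chr9	10.125
IND04	IND08	chr10	9.375
IND04	IND09	chr10	10.125
IND04	IND08	chr10	10.375
IND05	IND11	chr10	10.375
IND05	IND10	chr10	11.375
IND02	IND11	chr10	11.875
IND01	IND12	chr11	8.125
IND02	IND10	chr11	10.625
IND05	IND09	chr11	14.875
IND02	IND11	chr12	8.125
IND01	IND12	chr12	8.875
IND04	IND12	chr12	10.125
IND06	IND10	chr12	12.375
IND01	IND10	chr12	12.625
IND06	IND12	chr14	8.625
IND03	IND10	chr14	11.125
IND06	IND10	chr14	13.625
IND03	IND07	chr16	8.375
IND02	IND08	chr16	8.625
IND05	IND07	chr16	9.375
IND05	IND09	chr16	11.875
IND06	IND10	chr16	12.875
IND04	IND10	chr16	17.875
IND04	IND08	chr17	8.375
IND04	IND10	chr17	10.625
IND04	IND12	chr19	8.625
IND05	IND07	chr19	9.375
IND05	IND12	chr19	9.875
IND04	IND07	chr19	13.875
IND04	IND12	chr20	9.125
IND03	IND09	chr20	10.375
IND06	IND07	chr20	14.125
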
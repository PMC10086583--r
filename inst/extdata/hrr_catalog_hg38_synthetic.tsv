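symbol	chrom	start	end
RPA2	chr1	28200000	28300000
RAD54L	chr1	46200000	46300000
UBE2T	chr1	202300000	202400000
EXO1	chr1	241800000	241900000
GEN1	chr2	17900000	18000000
FANCL	chr2	58200000	58300000
ZRANB3	chr2	85300000	85400000
BARD1	chr2	214700000	214800000
FANCD2	chr3	10000000	10100000
ATRIP	chr3	48400000	48500000
TOPBP1	chr3	133600000	133700000
ATR	chr3	142500000	142600000
HELQ	chr4	83300000	83400000
RAD1	chr5	34900000	35000000
RAD17	chr5	69100000	69200000
RAD50	chr5	132600000	132700000
MDC1	chr6	30700000	30800000
FANCE	chr6	35400000	35500000
RPA3	chr7	7600000	7700000
HUS1	chr7	47900000	48000000
XRCC2	chr7	152600000	152700000
TEX15	chr8	30500000	30600000
WRN	chr8	31200000	31300000
SPIDR	chr8	47300000	47400000
NBN	chr8	89900000	90000000
RAD54B	chr8	94400000	94500000
RECQL4	chr8	144500000	144600000
FANCG	chr9	35000000	35100000
RMI1	chr9	83600000	83700000
FANCC	chr9	95100000	95200000
SWI5	chr9	127900000	128000000
PTEN	chr10	87900000	88000000
FANCF	chr11	22600000	22700000
MUS81	chr11	65600000	65700000
RAD9A	chr11	67600000	67700000
MRE11	chr11	94400000	94500000
ATM	chr11	108200000	108300000
CHEK1	chr11	125500000	125600000
RAD52	chr12	1000000	1100000
RAD51AP1	chr12	4500000	4600000
BRCA2	chr13	32300000	32400000
FANCM	chr14	45100000	45200000
RAD51B	chr14	67800000	67900000
XRCC3	chr14	103500000	103600000
RAD51	chr15	40700000	40800000
TP53BP1	chr15	43300000	43400000
FANCI	chr15	89200000	89300000
BLM	chr15	90700000	90800000
EME2	chr16	1800000	1900000
SLX4	chr16	3600000	3700000
RMI2	chr16	11300000	11400000
ERCC4	chr16	13900000	14000000
PALB2	chr16	23600000	23700000
SLX1A	chr16	29400000	29500000
FANCA	chr16	89700000	89800000
RPA1	chr17	1700000	1800000
TOP3A	chr17	18200000	18300000
RAD51D	chr17	35100000	35200000
BRCA1	chr17	43000000	43100000
EME1	chr17	50200000	50300000
RAD51C	chr17	58700000	58800000
BRIP1	chr17	61600000	61700000
RECQL5	chr17	75600000	75700000
RBBP8	chr18	22900000	23000000
SWSAP1	chr19	6700000	6800000
POLD1	chr19	50400000	50500000
BCL2L1	chr20	31700000	31800000
CHEK2	chr22	28700000	28800000
DMC1	chr22	38500000	38600000
FANCB	chrX	14800000	14900000
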
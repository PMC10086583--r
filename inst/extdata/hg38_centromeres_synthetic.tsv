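chrom	start	end
chr1	121700000	125100000
chr2	91800000	96000000
chr3	87800000	94000000
chr4	48200000	51800000
chr5	46100000	50100000
chr6	58500000	62600000
chr7	58100000	62400000
chr8	43200000	47200000
chr9	42200000	45500000
chr10	38000000	41600000
chr11	51000000	55800000
chr12	34700000	37200000
chr13	16000000	18900000
chr14	16000000	18200000
chr15	17000000	20500000
chr16	36300000	38300000
chr17	22700000	27400000
chr18	15400000	21500000
chr19	24400000	28100000
chr20	25700000	30400000
chr21	10900000	13000000
chr22	13700000	17400000
chrX	58100000	63800000
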
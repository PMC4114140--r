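# Per-cell counts of region probes passing the +/-0.3 log2-ratio threshold,
# single S- and G0/G1-phase cells of three carrier cell lines.
# nocall: no-call flags as tallied by the published summary row (part B);
# printed_flag: every per-cell no-call superscript printed in part A
# (two flagged dup7p cells are counted as underestimation in part B).
cell_id	phase	cell_line	region	k	n	nocall	printed_flag
S_1_1	S	1	dup7p	25	40	FALSE	FALSE
S_1_2	S	1	dup7p	11	40	FALSE	FALSE
S_1_3	S	1	dup7p	13	40	FALSE	FALSE
S_1_4	S	1	dup7p	18	40	FALSE	FALSE
S_1_5	S	1	dup7p	8	40	FALSE	TRUE
S_1_6	S	1	dup7p	9	40	FALSE	TRUE
S_1_7	S	1	dup7p	18	40	FALSE	FALSE
S_1_8	S	1	dup7p	13	40	FALSE	FALSE
S_1_9	S	1	dup7p	10	40	TRUE	TRUE
S_1_10	S	1	dup7p	27	40	FALSE	FALSE
G0/G1_1_1	G0G1	1	dup7p	23	40	FALSE	FALSE
G0/G1_1_2	G0G1	1	dup7p	20	40	FALSE	FALSE
G0/G1_1_3	G0G1	1	dup7p	18	40	FALSE	FALSE
G0/G1_1_4	G0G1	1	dup7p	28	40	FALSE	FALSE
G0/G1_1_5	G0G1	1	dup7p	24	40	FALSE	FALSE
G0/G1_1_6	G0G1	1	dup7p	20	40	FALSE	FALSE
G0/G1_1_7	G0G1	1	dup7p	25	40	FALSE	FALSE
S_2_1	S	2	dup9p	26	42	FALSE	FALSE
S_2_2	S	2	dup9p	21	42	FALSE	FALSE
S_2_3	S	2	dup9p	19	42	FALSE	FALSE
S_2_4	S	2	dup9p	29	42	FALSE	FALSE
S_2_5	S	2	dup9p	22	42	FALSE	FALSE
S_2_6	S	2	dup9p	25	42	FALSE	FALSE
S_2_7	S	2	dup9p	28	42	FALSE	FALSE
S_2_8	S	2	dup9p	27	42	FALSE	FALSE
S_2_9	S	2	dup9p	18	42	FALSE	FALSE
S_2_10	S	2	dup9p	31	42	FALSE	FALSE
G0/G1_2_1	G0G1	2	dup9p	16	42	FALSE	FALSE
G0/G1_2_2	G0G1	2	dup9p	19	42	FALSE	FALSE
G0/G1_2_3	G0G1	2	dup9p	25	42	FALSE	FALSE
G0/G1_2_4	G0G1	2	dup9p	36	42	FALSE	FALSE
G0/G1_2_5	G0G1	2	dup9p	31	42	FALSE	FALSE
G0/G1_2_6	G0G1	2	dup9p	23	42	FALSE	FALSE
G0/G1_2_7	G0G1	2	dup9p	22	42	FALSE	FALSE
G0/G1_2_8	G0G1	2	dup9p	31	42	FALSE	FALSE
S_2_1	S	2	del18p	3	28	TRUE	TRUE
S_2_2	S	2	del18p	13	28	FALSE	FALSE
S_2_3	S	2	del18p	21	28	FALSE	FALSE
S_2_4	S	2	del18p	20	28	FALSE	FALSE
S_2_5	S	2	del18p	25	28	FALSE	FALSE
S_2_6	S	2	del18p	18	28	FALSE	FALSE
S_2_7	S	2	del18p	21	28	FALSE	FALSE
S_2_8	S	2	del18p	22	28	FALSE	FALSE
S_2_9	S	2	del18p	24	28	FALSE	FALSE
S_2_10	S	2	del18p	22	28	FALSE	FALSE
G0/G1_2_1	G0G1	2	del18p	13	28	FALSE	FALSE
G0/G1_2_2	G0G1	2	del18p	17	28	FALSE	FALSE
G0/G1_2_3	G0G1	2	del18p	19	28	FALSE	FALSE
G0/G1_2_4	G0G1	2	del18p	23	28	FALSE	FALSE
G0/G1_2_5	G0G1	2	del18p	17	28	FALSE	FALSE
G0/G1_2_6	G0G1	2	del18p	20	28	FALSE	FALSE
G0/G1_2_7	G0G1	2	del18p	20	28	FALSE	FALSE
G0/G1_2_8	G0G1	2	del18p	19	28	FALSE	FALSE
S_3_1	S	3	dup18p	7	30	FALSE	FALSE
S_3_2	S	3	dup18p	14	30	FALSE	FALSE
S_3_3	S	3	dup18p	4	30	TRUE	TRUE
S_3_4	S	3	dup18p	16	30	FALSE	FALSE
S_3_5	S	3	dup18p	11	30	FALSE	FALSE
S_3_6	S	3	dup18p	13	30	FALSE	FALSE
G0/G1_3_1	G0G1	3	dup18p	2	30	TRUE	TRUE
G0/G1_3_2	G0G1	3	dup18p	17	30	FALSE	FALSE
G0/G1_3_3	G0G1	3	dup18p	15	30	FALSE	FALSE
G0/G1_3_4	G0G1	3	dup18p	19	30	FALSE	FALSE
G0/G1_3_5	G0G1	3	dup18p	17	30	FALSE	FALSE
G0/G1_3_6	G0G1	3	dup18p	17	30	FALSE	FALSE
G0/G1_3_7	G0G1	3	dup18p	23	30	FALSE	FALSE
S_3_1	S	3	del20p	7	8	FALSE	FALSE
S_3_2	S	3	del20p	7	8	FALSE	FALSE
S_3_3	S	3	del20p	6	8	FALSE	FALSE
S_3_4	S	3	del20p	7	8	FALSE	FALSE
S_3_5	S	3	del20p	6	8	FALSE	FALSE
S_3_6	S	3	del20p	8	8	FALSE	FALSE
G0/G1_3_1	G0G1	3	del20p	7	8	FALSE	FALSE
G0/G1_3_2	G0G1	3	del20p	6	8	FALSE	FALSE
G0/G1_3_3	G0G1	3	del20p	7	8	FALSE	FALSE
G0/G1_3_4	G0G1	3	del20p	5	8	FALSE	FALSE
G0/G1_3_5	G0G1	3	del20p	6	8	FALSE	FALSE
G0/G1_3_6	G0G1	3	del20p	7	8	FALSE	FALSE
G0/G1_3_7	G0G1	3	del20p	4	8	FALSE	FALSE
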
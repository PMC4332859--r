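grid	n	d	size
lexicode_published	4	3	7
lexicode_published	5	3	25
lexicode_published	5	4	7
lexicode_published	6	3	61
lexicode_published	6	4	15
lexicode_published	6	5	5
lexicode_published	7	3	211
lexicode_published	7	4	41
lexicode_published	7	5	11
lexicode_published	7	6	4
lexicode_published	8	3	531
lexicode_published	8	4	103
lexicode_published	8	5	24
lexicode_published	8	6	8
lexicode_published	8	7	3
lexicode_published	9	3	1936
lexicode_published	9	4	301
lexicode_published	9	5	62
lexicode_published	9	6	18
lexicode_published	9	7	6
lexicode_published	9	8	3
lexicode_published	10	3	7198
lexicode_published	10	4	971
lexicode_published	10	5	164
lexicode_published	10	6	40
lexicode_published	10	7	13
lexicode_published	10	8	5
lexicode_published	10	9	3
ga_range_gc	4	3	10
ga_range_gc	5	3	25
ga_range_gc	5	4	8
ga_range_gc	6	3	49
ga_range_gc	6	4	15
ga_range_gc	6	5	6
ga_range_gc	7	3	133
ga_range_gc	7	4	34
ga_range_gc	7	5	11
ga_range_gc	7	6	5
ga_range_gc	8	3	296
ga_range_gc	8	4	73
ga_range_gc	8	5	23
ga_range_gc	8	6	9
ga_range_gc	8	7	4
ga_range_gc	9	3	876
ga_range_gc	9	4	180
ga_range_gc	9	5	45
ga_range_gc	9	6	15
ga_range_gc	9	7	7
ga_range_gc	9	8	4
ga_range_gc	10	3	1863
ga_range_gc	10	4	399
ga_range_gc	10	5	91
ga_range_gc	10	6	28
ga_range_gc	10	7	12
ga_range_gc	10	8	6
ga_range_gc	10	9	3
ga_fixed_gc	4	3	10
ga_fixed_gc	5	3	18
ga_fixed_gc	5	4	7
ga_fixed_gc	6	3	49
ga_fixed_gc	6	4	15
ga_fixed_gc	6	5	6
ga_fixed_gc	7	3	109
ga_fixed_gc	7	4	28
ga_fixed_gc	7	5	10
ga_fixed_gc	7	6	4
ga_fixed_gc	8	3	296
ga_fixed_gc	8	4	73
ga_fixed_gc	8	5	23
ga_fixed_gc	8	6	9
ga_fixed_gc	8	7	4
ga_fixed_gc	9	3	724
ga_fixed_gc	9	4	168
ga_fixed_gc	9	5	41
ga_fixed_gc	9	6	14
ga_fixed_gc	9	7	6
ga_fixed_gc	9	8	3
ga_fixed_gc	10	3	1651
ga_fixed_gc	10	4	373
ga_fixed_gc	10	5	86
ga_fixed_gc	10	6	26
ga_fixed_gc	10	7	10
ga_fixed_gc	10	8	5
ga_fixed_gc	10	9	3
ga_cross_comp	4	3	9
ga_cross_comp	5	3	14
ga_cross_comp	5	4	7
ga_cross_comp	6	3	45
ga_cross_comp	6	4	15
ga_cross_comp	6	5	6
ga_cross_comp	7	3	103
ga_cross_comp	7	4	26
ga_cross_comp	7	5	10
ga_cross_comp	7	6	4
ga_cross_comp	8	3	274
ga_cross_comp	8	4	73
ga_cross_comp	8	5	23
ga_cross_comp	8	6	9
ga_cross_comp	8	7	4
ga_cross_comp	9	3	688
ga_cross_comp	9	4	168
ga_cross_comp	9	5	41
ga_cross_comp	9	6	14
ga_cross_comp	9	7	6
ga_cross_comp	9	8	4
ga_cross_comp	10	3	1579
ga_cross_comp	10	4	371
ga_cross_comp	10	5	86
ga_cross_comp	10	6	26
ga_cross_comp	10	7	10
ga_cross_comp	10	8	5
ga_cross_comp	10	9	3
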
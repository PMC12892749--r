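# Per-metric TP/FP/TN/FN patient counts for the published MRI-negative
# cohort (n = 15). These counts were not printed; they are uniquely
# recovered ("derived-from-printed-values") from the published
# sensitivity/specificity/accuracy values and Wilson 95% CI bounds.
metric	tp	fp	tn	fn
si	6	1	4	4
dc	5	1	5	4
dcout	5	1	5	4
dcin	4	1	4	6
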
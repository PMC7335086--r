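data_type,bulk
expression_matrix,expression.csv
annotation_file,NA
min_slope_deg,10
min_samples,20
min_line_length,30
variant_gene_pct,3
seed,1
output_dir,results
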
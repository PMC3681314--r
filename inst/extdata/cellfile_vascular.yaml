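# Unidirectional transport along a vascular cell file with the default
# permeabilities (basal PIN 20 um/s over background 1 um/s -> p = 19, q = 1).
# Run:  rootflux cellfile --config cellfile_vascular.yaml --out run_cellfile
p: 19
q: 1
n_cells: 60
cell_length: 16
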
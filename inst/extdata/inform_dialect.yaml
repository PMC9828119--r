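# Example dialect file for read_dialect(): maps an inForm-style per-cell
# export onto the canonical cell schema. Any field omitted here falls back to
# the canonical dialect's value.
name: inform-like
delim: "\t"
columns:
  cell_id: "Cell ID"
  core_id: "Sample Name"
  x_um: "Cell X Position"
  y_um: "Cell Y Position"
  compartment: "Tissue Category"
  ck: "CK"
  cd8: "CD8"
  cd68: "CD68"
  foxp3: "FOXP3"
  pd1: "PD-1"
  pdl1: "PD-L1"
true_values: ["1", "true", "TRUE", "+", "pos"]
false_values: ["0", "false", "FALSE", "-", "neg"]
compartment_aliases:
  Tumor: tumor
  Tumour: tumor
  tumor: tumor
  Stroma: stroma
  stroma: stroma
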
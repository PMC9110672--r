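# Template gate chain for isolating live single CD4 T helper cells from a
# mass cytometry panel:
#   Ir-DNA+ / Pt- live singlets -> bead exclusion on 140Ce -> CD45+ ->
#   CD3+ CD19- -> CD4+ CD8-
# Thresholds below are PLACEHOLDERS in asinh units: positivity cutoffs are
# instrument- and panel-specific and must be set by the analyst (e.g. from
# histograms), exactly as one would in a manual gating tool.
steps:
  - name: live_singlets
    x_marker: Ir191_DNA
    y_marker: Pt195_cisplatin
    x_range: [2.0, .inf]      # DNA-intercalator positive
    y_range: [-.inf, 1.5]     # cisplatin (dead-cell stain) negative
  - name: bead_exclusion
    x_marker: Ce140_beads
    y_marker: Ir191_DNA
    x_range: [-.inf, 1.0]     # exclude high 140Ce normalization beads
    y_range: [-.inf, .inf]
  - name: leukocytes
    x_marker: CD45
    y_marker: Ir191_DNA
    x_range: [2.0, .inf]
    y_range: [-.inf, .inf]
  - name: t_cells
    x_marker: CD3
    y_marker: CD19
    x_range: [2.0, .inf]
    y_range: [-.inf, 1.0]
  - name: cd4_helper
    x_marker: CD4
    y_marker: CD8
    x_range: [2.0, .inf]
    y_range: [-.inf, 1.0]
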
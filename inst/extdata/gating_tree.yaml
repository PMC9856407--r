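# Default hierarchical gating tree for standard cell types.
#
# CD45 is gated first so any leukocyte is classified independently of its
# Epcam status. Each internal node tests one marker's positivity flag; leaves
# carry the assigned cell type. Cells matching no terminal combination fall
# through to "unclassified".
marker: CD45
positive:
  marker: CD3
  positive:
    marker: CD8
    positive:
      marker: CD4
      positive: {cell_type: unclassified}
      negative: {cell_type: cd8_t_cell}
    negative:
      marker: CD4
      positive:
        marker: Foxp3
        positive: {cell_type: regulatory_t_cell}
        negative: {cell_type: unclassified}
      negative: {cell_type: unclassified}
  negative:
    marker: F4_80
    positive: {cell_type: macrophage}
    negative:
      marker: CD11c
      positive: {cell_type: dendritic_cell}
      negative:
        marker: CD11b
        positive:
          marker: Ly6G
          positive:
            marker: Arg1
            positive: {cell_type: neutrophil}
            negative:
              marker: MPO
              positive: {cell_type: n1_neutrophil}
              negative: {cell_type: neutrophil}
          negative: {cell_type: unclassified}
        negative: {cell_type: unclassified}
negative:
  marker: Epcam
  positive:
    marker: PyMT
    positive:
      marker: Ki67
      positive:
        marker: Sox9
        positive: {cell_type: unclassified}
        negative: {cell_type: proliferating_tumor}
      negative:
        marker: Sox9
        positive: {cell_type: cancer_stem_cell}
        negative: {cell_type: nonproliferating_tumor}
    negative: {cell_type: unclassified}
  negative:
    marker: CD31
    positive:
      marker: aSMA
      positive: {cell_type: unclassified}
      negative: {cell_type: endothelial_cell}
    negative:
      marker: aSMA
      positive:
        marker: NG2
        positive: {cell_type: pericyte}
        negative: {cell_type: fibroblast}
      negative: {cell_type: unclassified}
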
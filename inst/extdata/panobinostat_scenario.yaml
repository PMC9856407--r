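# Default panobinostat-response scenario for the synthetic generator.
#
# Planted quantities that mirror published measurements of the local
# panobinostat response are the 13.3% proximal cytotoxic-neutrophil fraction,
# the 42% calreticulin-high and 9% CC3+ fractions among cancer stem cells,
# the 40% ICAM-1 positivity of border-zone dendritic cells, and border
# compositions chosen so cancer stem cells outnumber ICAM-1+ dendritic cells
# 13.2-fold (0.2112 / (0.40 * 0.04) = 13.2). All remaining fractions and
# every spatial density/dispersion figure are modeling assumptions: no
# placement statistics were ever published for this system.
seed: 1
density_per_mm2: 11000

zone_composition:
  immediate:
    proliferating_tumor: 0.10
    nonproliferating_tumor: 0.45
    cancer_stem_cell: 0.005
    cd8_t_cell: 0.01
    regulatory_t_cell: 0.005
    dendritic_cell: 0.02
    n1_neutrophil: 0.12
    neutrophil: 0.08
    macrophage: 0.08
    endothelial_cell: 0.05
    fibroblast: 0.07
    pericyte: 0.01
  proximal:
    proliferating_tumor: 0.12
    nonproliferating_tumor: 0.40
    cancer_stem_cell: 0.01
    cd8_t_cell: 0.02
    regulatory_t_cell: 0.01
    dendritic_cell: 0.025
    n1_neutrophil: 0.133          # planted: 13.3% of proximal cells
    neutrophil: 0.06
    macrophage: 0.07
    endothelial_cell: 0.05
    fibroblast: 0.08
    pericyte: 0.022
  border:
    proliferating_tumor: 0.14
    nonproliferating_tumor: 0.29
    cancer_stem_cell: 0.2112      # 13.2 x (0.40 x 0.04): CSC vs ICAM1+ DC
    cd8_t_cell: 0.01
    regulatory_t_cell: 0.005
    dendritic_cell: 0.04
    n1_neutrophil: 0.05
    neutrophil: 0.04
    macrophage: 0.06
    endothelial_cell: 0.05
    fibroblast: 0.09
    pericyte: 0.0138
  distal:
    proliferating_tumor: 0.18
    nonproliferating_tumor: 0.55
    cancer_stem_cell: 0.01
    cd8_t_cell: 0.015
    regulatory_t_cell: 0.01
    dendritic_cell: 0.015
    n1_neutrophil: 0.005
    neutrophil: 0.02
    macrophage: 0.05
    endothelial_cell: 0.05
    fibroblast: 0.08
    pericyte: 0.015
  remote:
    proliferating_tumor: 0.32
    nonproliferating_tumor: 0.40
    cancer_stem_cell: 0.005
    cd8_t_cell: 0.01
    regulatory_t_cell: 0.005
    dendritic_cell: 0.013
    n1_neutrophil: 0.002
    neutrophil: 0.015
    macrophage: 0.05
    endothelial_cell: 0.06
    fibroblast: 0.10
    pericyte: 0.02
  control:                         # matched intratumoral background region
    proliferating_tumor: 0.32
    nonproliferating_tumor: 0.40
    cancer_stem_cell: 0.005
    cd8_t_cell: 0.01
    regulatory_t_cell: 0.005
    dendritic_cell: 0.013
    n1_neutrophil: 0.002
    neutrophil: 0.015
    macrophage: 0.05
    endothelial_cell: 0.06
    fibroblast: 0.10
    pericyte: 0.02

expression:
  # Beta shapes for the positive and negative intensity populations on [0,1];
  # both clear the 0.35 gating threshold with error < 1e-3 per marker.
  positive_params: [12, 4]
  negative_params: [1.5, 20]
  # Lineage signature: markers drawn positive with probability 1 for the
  # type; all unlisted lineage markers are negative.
  signatures:
    proliferating_tumor: [Epcam, PyMT, Ki67]
    nonproliferating_tumor: [Epcam, PyMT]
    cancer_stem_cell: [Epcam, PyMT, Sox9]
    cd8_t_cell: [CD45, CD3, CD8]
    regulatory_t_cell: [CD45, CD3, CD4, Foxp3]
    dendritic_cell: [CD45, CD11c]
    n1_neutrophil: [CD45, CD11b, Ly6G, MPO]
    neutrophil: [CD45, CD11b, Ly6G]
    macrophage: [CD45, F4_80, CD11b]
    endothelial_cell: [CD31]
    fibroblast: [aSMA]
    pericyte: [aSMA, NG2]
  # Candidate-biomarker positive fractions, optionally zone-specific
  # ({base: ..., <zone>: ...}). Zone-dependence encodes the drug gradient:
  # death/adhesion markers proximal, galectin-3 distal, PD-L1 remote.
  marker_rates:
    proliferating_tumor:
      CC3: 0.02
      ICAM1: 0.02
      CALR: 0.10
      Gal3: 0.002
      NRP1: 0.02
      PDL1: 0.003
    nonproliferating_tumor:
      CC3:   {base: 0.02, immediate: 0.50, proximal: 0.30}
      ICAM1: {base: 0.05, immediate: 0.40, proximal: 0.40}
      CALR: 0.10
      Gal3:  {base: 0.02, immediate: 0.10, proximal: 0.10, border: 0.30, distal: 0.85, remote: 0.002}
      NRP1:  {base: 0.05, immediate: 0.40, proximal: 0.40}
      PDL1:  {base: 0.003, remote: 0.08}
    cancer_stem_cell:
      CALR: 0.42                   # planted: 42% calreticulin-high CSCs
      CC3: 0.09                    # planted: 9% CC3+ CSCs
      ICAM1: 0.30
      Gal3: {base: 0.05, border: 0.60}
      NRP1: 0.10
      PDL1: 0.003
    cd8_t_cell:
      CALR: {base: 0.05, immediate: 0.30, proximal: 0.30}
      Gal3: 0.005
      CC3: 0.02
      ICAM1: 0.05
      NRP1: 0.02
      PDL1: 0.003
    regulatory_t_cell:
      CALR: 0.05
      Gal3: 0.005
      CC3: 0.02
      ICAM1: 0.05
      NRP1: 0.30
      PDL1: 0.003
    dendritic_cell:
      ICAM1: 0.40                  # planted: 40% ICAM-1+ DCs (border zone)
      Gal3: {base: 0.01, border: 0.30}
      CALR: {base: 0.05, immediate: 0.30, proximal: 0.30}
      NRP1: 0.10
      CC3: 0.02
      PDL1: 0.01
    n1_neutrophil:
      ICAM1: 0.60
      NRP1: 0.60
      CALR: {base: 0.10, immediate: 0.50, proximal: 0.50}
      Gal3: {base: 0.02, immediate: 0.70, proximal: 0.70}
      CC3: 0.15
      PDL1: 0.003
    neutrophil:
      Arg1: 0.50
      ICAM1: 0.20
      NRP1: 0.10
      CALR: {base: 0.05, immediate: 0.30, proximal: 0.30}
      Gal3: {base: 0.01, immediate: 0.50, proximal: 0.50}
      CC3: 0.10
      PDL1: 0.003
    macrophage:
      CALR: {base: 0.10, immediate: 0.50, proximal: 0.50}
      Gal3: {base: 0.01, immediate: 0.50, proximal: 0.50}
      ICAM1: 0.20
      NRP1: 0.10
      CC3: 0.05
      PDL1: 0.01
    endothelial_cell:
      ICAM1: 0.50
      Gal3: 0.005
      CC3: 0.02
      CALR: 0.05
      NRP1: 0.05
      PDL1: 0.003
    fibroblast:
      Gal3: {base: 0.01, border: 0.60}
      CALR: 0.05
      CC3: 0.02
      ICAM1: 0.05
      NRP1: 0.05
      PDL1: 0.003
    pericyte:
      Gal3: 0.005
      CALR: 0.05
      CC3: 0.02
      ICAM1: 0.05
      NRP1: 0.05
      PDL1: 0.003
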
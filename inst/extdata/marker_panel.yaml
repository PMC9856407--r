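# Default marker panel: lineage markers used by the gating hierarchy plus
# the seven candidate biomarkers of immunogenic cell death / checkpoint
# blockade. Thresholds are on the 0-1 mean-intensity scale; in a real run
# they would be calibrated on positive-control tissue per marker.
markers:
  Epcam:  {threshold: 0.35}
  CD45:   {threshold: 0.35}
  PyMT:   {threshold: 0.35}
  Ki67:   {threshold: 0.35}
  Sox9:   {threshold: 0.35}
  CD3:    {threshold: 0.35}
  CD8:    {threshold: 0.35}
  CD4:    {threshold: 0.35}
  Foxp3:  {threshold: 0.35}
  F4_80:  {threshold: 0.35}
  CD11c:  {threshold: 0.35}
  CD11b:  {threshold: 0.35}
  Ly6G:   {threshold: 0.35}
  Arg1:   {threshold: 0.35}
  CD31:   {threshold: 0.35}
  aSMA:   {threshold: 0.35}
  NG2:    {threshold: 0.35}
  MPO:    {threshold: 0.35, candidate: yes}
  CC3:    {threshold: 0.35, candidate: yes}
  ICAM1:  {threshold: 0.35, candidate: yes}
  CALR:   {threshold: 0.35, candidate: yes}
  Gal3:   {threshold: 0.35, candidate: yes}
  NRP1:   {threshold: 0.35, candidate: yes}
  PDL1:   {threshold: 0.35, candidate: yes}
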
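# A-priori 10-node networks on the AAL-116 parcellation, named by AAL
# region label (resolved against aal116_labels.tsv). The choice of
# lateralized parcels filling each network to exactly 10 nodes is a
# documented, user-overridable mapping: pass your own YAML to
# load_networks() to change it. Note the subgenual anterior cingulate has
# no dedicated AAL-116 parcel; the medial orbitofrontal parcels stand in
# for the medial frontal / subgenual contribution to the DMN.
DMN:
  - Frontal_Med_Orb_L
  - Frontal_Med_Orb_R
  - Cingulum_Post_L
  - Cingulum_Post_R
  - ParaHippocampal_L
  - ParaHippocampal_R
  - Precuneus_L
  - Precuneus_R
  - Parietal_Inf_L
  - Parietal_Inf_R
CEN:
  - Frontal_Mid_L
  - Frontal_Mid_R
  - Frontal_Inf_Tri_L
  - Frontal_Inf_Tri_R
  - Frontal_Sup_Medial_L
  - Frontal_Sup_Medial_R
  - Parietal_Sup_L
  - Parietal_Sup_R
  - Parietal_Inf_L
  - Parietal_Inf_R
SAL:
  - Insula_L
  - Insula_R
  - Cingulum_Ant_L
  - Cingulum_Ant_R
  - Amygdala_L
  - Amygdala_R
  - Temporal_Pole_Sup_L
  - Temporal_Pole_Sup_R
  - Temporal_Pole_Mid_L
  - Temporal_Pole_Mid_R
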
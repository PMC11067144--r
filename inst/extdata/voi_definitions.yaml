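# Composite VOI membership (Desikan-Killiany parcel names).
# `thickness` composites are surface-area-weighted means per hemisphere,
# `volume` composites are per-hemisphere sums; both are then averaged
# across hemispheres. Edit freely; regions must exist in the parsed table.
temporal_meta:
  measure: thickness
  members: [entorhinal, parahippocampal, fusiform, inferiortemporal,
            middletemporal]
lateral_temporal:
  measure: thickness
  members: [superiortemporal, middletemporal, inferiortemporal, bankssts,
            transversetemporal]
lateral_parietal:
  measure: thickness
  members: [inferiorparietal, superiorparietal, supramarginal]
medial_parietal:
  measure: thickness
  members: [precuneus, posteriorcingulate, isthmuscingulate]
frontal:
  measure: thickness
  members: [caudalmiddlefrontal, lateralorbitofrontal, medialorbitofrontal,
            paracentral, parsopercularis, parsorbitalis, parstriangularis,
            precentral, rostralmiddlefrontal, superiorfrontal, frontalpole]
hippocampus:
  measure: volume
  members: [Hippocampus]
amygdala:
  measure: volume
  members: [Amygdala]
entorhinal_volume:
  measure: volume
  members: [entorhinal]
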
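{
  "_comment": "Per-channel pore definitions (author residue numbering of the reference structures): axis-defining residues, selectivity-filter and activation-gate residues, gate window, filter-to-gate region used for water-exposed surface area, neighbour residue range for S6 contact masks, S6 helix span and the span used for 3D-1D score profiles. version 1.0",
  "trpv1": {
    "organism": "rat",
    "axis_residues": [642, 643, 644, 645, 671, 675, 676, 679, 680, 683, 686],
    "filter_residue": 643,
    "gate_residues_pi": [679],
    "gate_residues_alpha": [678, 682],
    "gate_region_residues": [678, 682],
    "esa_region_residues": [643, 682],
    "neighbor_contact_residues": [654, 692],
    "s6_range": [665, 690],
    "helix_map_range": [670, 682],
    "score_range": [670, 687]
  },
  "trpv3": {
    "organism": "mouse",
    "axis_residues": [637, 638, 639, 640, 666, 670, 671, 674, 675, 678, 681],
    "filter_residue": 638,
    "gate_residues_pi": [674],
    "gate_residues_alpha": [673, 677],
    "gate_region_residues": [673, 677],
    "esa_region_residues": [638, 677],
    "neighbor_contact_residues": [649, 687],
    "s6_range": [660, 685],
    "helix_map_range": [665, 677],
    "score_range": [665, 682]
  },
  "trpv6": {
    "organism": "human",
    "axis_residues": [539, 540, 541, 542, 567, 571, 572, 575, 576, 579, 582],
    "filter_residue": 542,
    "gate_residues_pi": [575],
    "gate_residues_alpha": [574, 578],
    "gate_region_residues": [574, 578],
    "esa_region_residues": [540, 578],
    "neighbor_contact_residues": [550, 588],
    "s6_range": [561, 586],
    "helix_map_range": [566, 578],
    "score_range": [566, 583]
  }
}
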
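# Default 384-well screening-plate layout: library siRNAs in columns 1-22,
# transfection controls in column 23, DMSO vehicle column 24.
controls:
  vehicle_ctrl:      {columns: [24]}
  nontargeting_ctrl: {wells: [A23, B23, C23, D23, E23, F23, G23, H23]}
  death_ctrl:        {wells: [I23, J23, K23, L23]}
  pathway_ctrl:      {wells: [M23, N23, O23, P23]}
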
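# Default hierarchical gating panel for the standard 10-phenotype scheme.
# Thresholds are stand-in absolute MFI cutoffs sitting between the low and
# high modes of the synthetic generator's bimodal intensity model; real
# exports need per-experiment cutoffs (the original gates were interactive).
name: root
children:
  - name: T_cells
    when: [{channel: CD3, op: ">", cutoff: 40}]
    children:
      - name: CD8_T
        when: [{channel: CD8, op: ">", cutoff: 40}]
        children:
          - name: resource
            when: [{channel: TCF1, op: ">", cutoff: 40},
                   {channel: PD1, op: ">", cutoff: 40}]
            label: CD8_TCF1+PD1+
          - name: effector
            when: [{channel: TCF1, op: "<=", cutoff: 40},
                   {channel: PD1, op: ">", cutoff: 40}]
            label: CD8_TCF1-PD1+
          - name: cd8_other
            label: CD8_other
      - name: CD4_T
        when: [{channel: CD8, op: "<=", cutoff: 40}]
        label: CD4_T
  - name: DCs
    when: [{channel: CD11c, op: ">", cutoff: 40},
           {channel: MHCII, op: ">", cutoff: 40}]
    children:
      - name: DC1
        when: [{channel: CD103, op: ">", cutoff: 40}]
        label: DC1
      - name: DC2
        when: [{channel: SIRPa, op: ">", cutoff: 40}]
        label: DC2
  - name: CD206_Mf
    when: [{channel: CD11c, op: "<=", cutoff: 40},
           {channel: CD206, op: ">", cutoff: 40}]
    label: CD206_Mf
  - name: SIRPa_Mfs
    when: [{channel: CD11c, op: "<=", cutoff: 40},
           {channel: CD206, op: "<=", cutoff: 40},
           {channel: SIRPa, op: ">", cutoff: 40}]
    children:
      - name: activated_Mf
        when: [{channel: MHCII, op: ">", cutoff: 40}]
        label: MHCII+_Mf
      - name: nonactivated_Mf
        when: [{channel: MHCII, op: "<=", cutoff: 40}]
        label: MHCII-_Mf
  - name: ungated
    label: other
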
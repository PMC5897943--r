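name: reduced PD-L1 regulation network
outputs:
- PDL1
- CCL2
- CCL3
- CCL4
- CCL5
- CCL7
- CCL11
- CCL20
- CX3CL1
- CXCL14
- TGFB1
- IDO1
- IL6
- VEGFA
- TDO2
- PGE2
- IL10
- LGALS9
- FASLG
- CD47
- CTLA4
- PDCD1LG2
- GM3
- GD2
species:
- name: EGFR
  synthesis: 0.2
  degradation: 0.2
  init: 1.0
- name: IFNG
  synthesis: 0.2
  degradation: 0.2
  init: 1.0
- name: PIK3CA
  synthesis: 0.2
  degradation: 0.2
  init: 1.0
- name: STK11
  synthesis: 0.2
  degradation: 0.2
  init: 1.0
- name: KEAP1
  synthesis: 0.2
  degradation: 0.2
  init: 1.0
- name: CDKN2A
  synthesis: 0.2
  degradation: 0.2
  init: 1.0
- name: TP53
  synthesis: 0.3
  degradation: 0.05
  init: 1.0
- name: RAS
  synthesis: 0.02
  degradation: 0.5
  init: 1.0
- name: RAF
  synthesis: 0.02
  degradation: 0.5
  init: 1.0
- name: MEK
  synthesis: 0.02
  degradation: 0.5
  init: 1.0
- name: ERK
  synthesis: 0.02
  degradation: 0.5
  init: 1.0
- name: AP1
  synthesis: 0.02
  degradation: 0.5
  init: 1.0
- name: AKT
  synthesis: 0.02
  degradation: 0.5
  init: 1.0
- name: MTOR
  synthesis: 0.02
  degradation: 0.5
  init: 1.0
- name: STAT3
  synthesis: 0.02
  degradation: 0.5
  init: 1.0
- name: IFNGR1
  synthesis: 0.02
  degradation: 0.5
  init: 1.0
- name: STAT1
  synthesis: 0.02
  degradation: 0.5
  init: 1.0
- name: IRF1
  synthesis: 0.02
  degradation: 0.5
  init: 1.0
- name: AMPK
  synthesis: 0.02
  degradation: 0.5
  init: 1.0
- name: PDL1
  synthesis: 0.01
  degradation: 0.2
  init: 1.0
- name: CCL2
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: CCL3
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: CCL4
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: CCL5
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: CCL7
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: CCL11
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: CCL20
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: CX3CL1
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: CXCL14
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: TGFB1
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: IDO1
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: IL6
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: VEGFA
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: TDO2
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: PGE2
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: IL10
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: LGALS9
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: FASLG
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: CD47
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: CTLA4
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: PDCD1LG2
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: GM3
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
- name: GD2
  synthesis: 0.02
  degradation: 0.25
  init: 0.1
reactions:
- id: ras_activation
  kind: michaelis_menten
  substrate: EGFR
  product: RAS
  Vmax: 3.0
  Km: 5.0
- id: raf_activation
  kind: michaelis_menten
  substrate: RAS
  product: RAF
  Vmax: 3.0
  Km: 5.0
- id: mek_activation
  kind: michaelis_menten
  substrate: RAF
  product: MEK
  Vmax: 3.0
  Km: 5.0
- id: erk_activation
  kind: michaelis_menten
  substrate: MEK
  product: ERK
  Vmax: 3.0
  Km: 5.0
- id: ap1_activation
  kind: michaelis_menten
  substrate: ERK
  product: AP1
  Vmax: 3.0
  Km: 5.0
- id: akt_activation
  kind: michaelis_menten
  substrate: PIK3CA
  product: AKT
  Vmax: 3.0
  Km: 5.0
- id: mtor_akt
  kind: michaelis_menten
  substrate: AKT
  product: MTOR
  Vmax: 1.5
  Km: 5.0
- id: mtor_ampk
  kind: michaelis_menten
  substrate: AMPK
  product: MTOR
  Vmax: 2.0
  Km: 5.0
- id: stat3_activation
  kind: michaelis_menten
  substrate: MTOR
  product: STAT3
  Vmax: 3.0
  Km: 5.0
  modifiers:
  - species: KEAP1
    role: activator
    Ka: 0.5
- id: ifngr1_activation
  kind: michaelis_menten
  substrate: IFNG
  product: IFNGR1
  Vmax: 3.0
  Km: 5.0
- id: stat1_activation
  kind: michaelis_menten
  substrate: IFNGR1
  product: STAT1
  Vmax: 3.0
  Km: 5.0
- id: irf1_activation
  kind: michaelis_menten
  substrate: STAT1
  product: IRF1
  Vmax: 3.0
  Km: 5.0
- id: ampk_activation
  kind: michaelis_menten
  substrate: STK11
  product: AMPK
  Vmax: 3.0
  Km: 5.0
  modifiers:
  - species: CDKN2A
    role: activator
    Ka: 0.5
- id: tp53_turnover
  kind: mass_action
  substrates:
  - TP53
  k: 0.8
  modifiers:
  - species: CDKN2A
    role: activator
    Ka: 0.5
- id: pdl1_tx_ap1
  kind: michaelis_menten
  substrate: AP1
  product: PDL1
  Vmax: 0.6
  Km: 5.0
  modifiers:
  - species: TP53
    role: inhibitor
    Ka: 0.5
- id: pdl1_tx_stat3
  kind: michaelis_menten
  substrate: STAT3
  product: PDL1
  Vmax: 0.5
  Km: 5.0
  modifiers:
  - species: TP53
    role: inhibitor
    Ka: 0.5
- id: pdl1_tx_stat1
  kind: michaelis_menten
  substrate: STAT1
  product: PDL1
  Vmax: 0.25
  Km: 5.0
  modifiers:
  - species: TP53
    role: inhibitor
    Ka: 0.5
- id: pdl1_tx_irf1
  kind: michaelis_menten
  substrate: IRF1
  product: PDL1
  Vmax: 0.25
  Km: 5.0
  modifiers:
  - species: TP53
    role: inhibitor
    Ka: 0.5
- id: tx_ccl2
  kind: michaelis_menten
  substrate: STAT1
  product: CCL2
  Vmax: 0.8
  Km: 4.0
- id: tx_ccl3
  kind: michaelis_menten
  substrate: AP1
  product: CCL3
  Vmax: 1.0
  Km: 5.0
- id: tx_ccl4
  kind: michaelis_menten
  substrate: STAT1
  product: CCL4
  Vmax: 1.2
  Km: 6.0
- id: tx_ccl5
  kind: michaelis_menten
  substrate: IRF1
  product: CCL5
  Vmax: 0.9
  Km: 4.0
- id: tx_ccl7
  kind: michaelis_menten
  substrate: AP1
  product: CCL7
  Vmax: 1.1
  Km: 5.0
- id: tx_ccl11
  kind: michaelis_menten
  substrate: STAT3
  product: CCL11
  Vmax: 0.8
  Km: 6.0
- id: tx_ccl20
  kind: michaelis_menten
  substrate: STAT3
  product: CCL20
  Vmax: 1.0
  Km: 4.0
- id: tx_cx3cl1
  kind: michaelis_menten
  substrate: AP1
  product: CX3CL1
  Vmax: 1.2
  Km: 5.0
- id: tx_cxcl14
  kind: michaelis_menten
  substrate: STAT1
  product: CXCL14
  Vmax: 0.9
  Km: 6.0
- id: tx_tgfb1
  kind: michaelis_menten
  substrate: AP1
  product: TGFB1
  Vmax: 1.1
  Km: 4.0
- id: tx_ido1
  kind: michaelis_menten
  substrate: IRF1
  product: IDO1
  Vmax: 0.8
  Km: 5.0
- id: tx_il6
  kind: michaelis_menten
  substrate: STAT3
  product: IL6
  Vmax: 1.0
  Km: 6.0
- id: tx_vegfa
  kind: michaelis_menten
  substrate: AP1
  product: VEGFA
  Vmax: 1.2
  Km: 4.0
- id: tx_tdo2
  kind: michaelis_menten
  substrate: IRF1
  product: TDO2
  Vmax: 0.9
  Km: 5.0
- id: tx_pge2
  kind: michaelis_menten
  substrate: AP1
  product: PGE2
  Vmax: 1.1
  Km: 6.0
- id: tx_il10
  kind: michaelis_menten
  substrate: STAT3
  product: IL10
  Vmax: 0.8
  Km: 4.0
- id: tx_lgals9
  kind: michaelis_menten
  substrate: STAT1
  product: LGALS9
  Vmax: 1.0
  Km: 5.0
- id: tx_faslg
  kind: michaelis_menten
  substrate: STAT1
  product: FASLG
  Vmax: 1.2
  Km: 6.0
- id: tx_cd47
  kind: michaelis_menten
  substrate: STAT3
  product: CD47
  Vmax: 0.9
  Km: 4.0
- id: tx_ctla4
  kind: michaelis_menten
  substrate: AP1
  product: CTLA4
  Vmax: 1.1
  Km: 5.0
- id: tx_pdcd1lg2
  kind: michaelis_menten
  substrate: IRF1
  product: PDCD1LG2
  Vmax: 0.8
  Km: 6.0
- id: tx_gm3
  kind: michaelis_menten
  substrate: AP1
  product: GM3
  Vmax: 1.0
  Km: 4.0
- id: tx_gd2
  kind: michaelis_menten
  substrate: AP1
  product: GD2
  Vmax: 1.2
  Km: 5.0
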
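canonical:
- Cortex
- NAcMed
- NAcLat
- NAcCore
- DStr
- VP
- PO
- Septum
- BNST
- EAM
- EP
- GPe
- PVH
- LHb
- MHb
- CeA
- LH
- ZI
- DR
- LDT
- PBN
- DCN
merged:
- Cortex
- NAc
- DStr
- VP
- PO
- Septum
- BNST
- EAM
- EP
- GPe
- PVH
- LHb
- MHb
- CeA
- LH
- ZI
- DR
- LDT
- PBN
- DCN
atlas_map:
  Cortex:
  - PL
  - ILA
  - ORB
  - GU
  - AI
  - MOs
  - MOp
  NAc: ACB
  DStr: STRd
  VP: PALv
  PO:
  - MPO
  - LPO
  Septum:
  - LSX
  - MS
  BNST: BST
  EAM:
  - MEA
  - AAA
  - NLOT
  - COA
  - MA
  - BMA
  - EPv
  - NDB
  EP: GPi
  GPe: GPe
  PVH: PVH
  LHb: LH
  MHb: MH
  CeA: CEA
  LH: LHA
  ZI: ZI
  DR:
  - DR
  - PAG
  LDT: LDT
  PBN: PB
  DCN: CBN
genotypes:
- DAT-Cre
- GAD2-Cre
- vGluT2-Cre
anesthesias:
- isoflurane
- KX
treatments:
- saline
- fluoxetine
- cocaine
- methamphetamine
- amphetamine
- nicotine
- morphine
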
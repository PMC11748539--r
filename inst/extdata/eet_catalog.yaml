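# Default catalog of extracellular electron transfer (EET) ortholog labels,
# named porin-cytochrome complex (pcc) definitions, hybrid slot assignments,
# flagellar-assembly gene set, and electron-shuttle gene groups.
#
# Label matching is case-insensitive; punctuation except "/" is stripped, so
# "TherJR_2595" and "therjr2595" resolve to the same label.
#
# mtoD and pioC are periplasmic carriers, not part of the membrane-bound
# porin complex; they are declared (so inventories can record them) but are
# barred from every complex definition and every hybrid slot.

labels:
  # Shewanella oneidensis Mtr pathway
  - {name: mtrA, roles: [PERIPLASMIC_ANCHOR]}
  - {name: mtrB, roles: [PORIN]}
  - {name: mtrC, roles: [OMC]}
  - {name: mtrD, roles: [PERIPLASMIC_ANCHOR]}
  - {name: mtrE, roles: [PORIN]}
  - {name: mtrF, roles: [OMC]}
  - {name: dmsA, roles: [PERIPLASMIC_ANCHOR]}
  - {name: dmsE, roles: [PERIPLASMIC_ANCHOR]}
  - {name: dmsF, roles: [PORIN]}
  # Rhodopseudomonas palustris TIE-1 Pio system (pioC excluded from complexes)
  - {name: pioA, roles: [PERIPLASMIC_ANCHOR]}
  - {name: pioB, roles: [PORIN]}
  - {name: pioC, roles: [ACCESSORY]}
  # Sideroxydans lithotrophicus ES-1 Mto system (mtoD excluded from complexes)
  - {name: mtoA, roles: [PERIPLASMIC_ANCHOR]}
  - {name: mtoB, roles: [PORIN]}
  - {name: mtoD, roles: [ACCESSORY]}
  # Single-protein membrane/cell-wall spanning complexes
  - {name: cyc2, roles: [PORIN, OMC]}
  - {name: cwcA, roles: [PORIN, OMC]}
  # Thermincola potens JR system
  - {name: therJR_2595, roles: [OMC]}
  - {name: therJR_0333, roles: [PERIPLASMIC_ANCHOR]}
  - {name: therJR_1122, roles: [PERIPLASMIC_ANCHOR]}
  # Geobacter sulfurreducens systems
  - {name: omabcB, roles: [PORIN]}
  - {name: omabcC, roles: [PERIPLASMIC_ANCHOR]}
  - {name: extB, roles: [OMC]}
  - {name: extC, roles: [PERIPLASMIC_ANCHOR]}
  - {name: extD, roles: [PORIN]}
  - {name: extE, roles: [OMC]}
  - {name: extF, roles: [PERIPLASMIC_ANCHOR]}
  - {name: extG, roles: [PORIN]}
  # Standalone outer-surface cytochromes
  - {name: omcA, roles: [OMC]}
  - {name: omcS, roles: [OMC]}
  - {name: omcZ, roles: [OMC]}
  # Enterococcus faecalis Gram-positive system members
  - {name: dmkA, roles: [ACCESSORY]}
  - {name: ndh3, roles: [ACCESSORY]}
  - {name: eetB, roles: [ACCESSORY]}
  # Inner-membrane / periplasmic conduits
  - {name: macA, roles: [IM_P_CONDUIT]}
  - {name: cbcL, roles: [IM_P_CONDUIT]}
  - {name: imcH, roles: [IM_P_CONDUIT]}
  - {name: menB, roles: [IM_P_CONDUIT]}
  - {name: menE, roles: [IM_P_CONDUIT]}
  - {name: fccA/3, roles: [IM_P_CONDUIT], synonyms: [fccA, fcc3]}
  - {name: cymA, roles: [IM_P_CONDUIT]}
  - {name: imdcA, roles: [IM_P_CONDUIT]}
  - {name: pdcA, roles: [IM_P_CONDUIT]}
  - {name: imoA, roles: [IM_P_CONDUIT]}
  # Flavin synthesis and export
  - {name: ribBA, roles: [SHUTTLE_SYNTH_FLAVIN]}
  - {name: ribBX, roles: [SHUTTLE_SYNTH_FLAVIN]}
  - {name: ribD, roles: [SHUTTLE_SYNTH_FLAVIN]}
  - {name: ribE1, roles: [SHUTTLE_SYNTH_FLAVIN]}
  - {name: ribE2, roles: [SHUTTLE_SYNTH_FLAVIN]}
  - {name: bfe, roles: [SHUTTLE_EXPORT]}
  - {name: yeeO, roles: [SHUTTLE_EXPORT]}
  # Phenazine synthesis, regulation and export pump
  - {name: phzD, roles: [SHUTTLE_SYNTH_PHENAZINE]}
  - {name: phzE, roles: [SHUTTLE_SYNTH_PHENAZINE]}
  - {name: phzF, roles: [SHUTTLE_SYNTH_PHENAZINE]}
  - {name: phzG, roles: [SHUTTLE_SYNTH_PHENAZINE]}
  - {name: ipdG, roles: [SHUTTLE_SYNTH_PHENAZINE]}
  - {name: mexG, roles: [SHUTTLE_EXPORT]}
  - {name: mexH, roles: [SHUTTLE_EXPORT]}
  - {name: mexI, roles: [SHUTTLE_EXPORT]}
  - {name: opmD, roles: [SHUTTLE_EXPORT]}

complexes:
  - name: MtrCAB
    origin: Shewanella oneidensis MR-1
    required: [mtrA, mtrB, mtrC]
    slots: {mtrB: PORIN, mtrA: PERIPLASMIC_ANCHOR, mtrC: OMC}
  - name: MtrDEF
    origin: Shewanella oneidensis MR-1
    required: [mtrD, mtrE, mtrF]
    slots: {mtrE: PORIN, mtrD: PERIPLASMIC_ANCHOR, mtrF: OMC}
  - name: DmsAEF
    origin: Shewanella oneidensis MR-1
    required: [dmsA, dmsE, dmsF]
    slots: {dmsF: PORIN, dmsA: PERIPLASMIC_ANCHOR, dmsE: PERIPLASMIC_ANCHOR}
  - name: PioAB
    origin: Rhodopseudomonas palustris TIE-1
    required: [pioA, pioB]
    slots: {pioB: PORIN, pioA: PERIPLASMIC_ANCHOR}
  - name: MtoAB
    origin: Sideroxydans lithotrophicus ES-1
    required: [mtoA, mtoB]
    slots: {mtoB: PORIN, mtoA: PERIPLASMIC_ANCHOR}
  - name: Cyc2
    origin: Sideroxydans lithotrophicus ES-1
    required: [cyc2]
    complete_alone: true
    slots: {cyc2: PORIN}
  - name: CwcA
    origin: Thermincola potens JR
    required: [cwcA]
    complete_alone: true
    slots: {cwcA: PORIN}
  - name: TherJR
    origin: Thermincola potens JR
    required: [therJR_2595, therJR_0333, therJR_1122]
    slots: {therJR_0333: PERIPLASMIC_ANCHOR, therJR_1122: PERIPLASMIC_ANCHOR,
            therJR_2595: OMC}
  - name: OmabcB
    origin: Geobacter sulfurreducens
    required: [omabcB, omabcC]
    slots: {omabcB: PORIN, omabcC: PERIPLASMIC_ANCHOR}
  - name: ExtEFG
    origin: Geobacter sulfurreducens
    required: [extE, extF, extG]
    slots: {extG: PORIN, extF: PERIPLASMIC_ANCHOR, extE: OMC}
  - name: ExtBCD
    origin: Geobacter sulfurreducens
    required: [extB, extC, extD]
    slots: {extD: PORIN, extC: PERIPLASMIC_ANCHOR, extB: OMC}
  - name: EetB-system
    origin: Enterococcus faecalis
    required: [dmkA, ndh3, eetB]
    slots: {dmkA: ACCESSORY, ndh3: ACCESSORY, eetB: ACCESSORY}

# Which labels may fill each structural slot when assembling cross-pathway
# hybrid complexes. A functional hybrid needs one label per slot.
hybrid_slots:
  porin: [mtrB, mtrE, pioB, mtoB, dmsF, extD, extG, omabcB]
  anchor: [mtrA, mtrD, pioA, mtoA, dmsA, dmsE, extC, extF,
           therJR_0333, therJR_1122]
  omc: [mtrC, mtrF, omcA, omcS, omcZ, therJR_2595, extB, extE]

# Flagellar-assembly genes; motility is called when an inventory carries more
# than 30 of these 55. The membership is a placeholder stand-in for the KEGG
# flagellar assembly module and is fully user-replaceable; all motility logic
# depends only on set cardinality and membership.
flagellar_set: [flgA, flgB, flgC, flgD, flgE, flgF, flgG, flgH, flgI, flgJ,
                flgK, flgL, flgM, flgN, flhA, flhB, flhC, flhD, flhE, flhF,
                flhG, fliA, fliC, fliD, fliE, fliF, fliG, fliH, fliI, fliJ,
                fliK, fliL, fliM, fliN, fliO, fliP, fliQ, fliR, fliS, fliT,
                fliU, fliV, fliW, fliY, fliZ, motA, motB, motX, motY, flaG,
                flrA, flrB, flrC, fleQ, fleN]

shuttle_rules:
  flavin_synthesis: [ribBA, ribBX, ribD, ribE1, ribE2]
  flavin_export: [bfe, yeeO]
  phenazine_synthesis: [phzD, phzE, phzF, phzG]
  phenazine_regulation: [ipdG]
  pump: [mexG, mexH, mexI, opmD]

excluded: [mtoD, pioC]
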
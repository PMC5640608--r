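# Default reaction inventory: central carbon metabolism, Wood-Ljungdahl
# pathway, carrier-exchange enzymes, lactate cycling, urea cycle and
# amino-acid degradation of an acetogen, expressed as carrier ledgers
# per unit flux. Conventions:
#   - fd_rd_pairs counts reduced ferredoxin in electron PAIRS (2 Fd_rd = 1).
#   - electrons: signed electrons donated by non-carrier species to the
#     carrier pool (negative = accepted from it); must equal
#     2 * (fd_rd_pairs + nadh + nadph).
#   - atp: substrate-level phosphorylation; ATP -> AMP + PPi counts as 2.
#   - protons: translocated outward per unit flux; the Rnf entry references
#     the configurable rnf_protons_per_pair of the energy config.
reactions:
  # fructose -> 2 pyruvate (glyceraldehyde-3-P dehydrogenase reduces NAD)
  glycolysis:
    ledger: {atp: 2, nadh: 2}
    electrons: 4
  # pyruvate -> acetyl-CoA + CO2, pyruvate:ferredoxin oxidoreductase
  pfor:
    ledger: {fd_rd_pairs: 1, co2: 1}
    electrons: 2
  # acetyl-CoA -> acetyl-phosphate -> acetate (phosphotransacetylase + acetate kinase)
  acetate_kinase:
    ledger: {atp: 1}
    electrons: 0
  # NADH-dependent pyruvate (Si)-reductase LdhA: pyruvate + NADH -> (R)-lactate
  ldha:
    ledger: {nadh: -1}
    electrons: -2
  # (R)-lactate dehydrogenase / electron-transfer flavoprotein confurcation:
  # (R)-lactate + 2 Fd_rd + 2 NAD -> pyruvate + 2 NADH
  lactate_dehydrogenase_etf:
    ledger: {fd_rd_pairs: -1, nadh: 2}
    electrons: 2
  # Rnf complex: 2 Fd_rd -> NADH, translocating protons (pure carrier
  # interconversion; electrons = gross electrons moved)
  rnf:
    ledger: {fd_rd_pairs: -1, nadh: 1, protons: rnf_protons_per_pair}
    electrons: 2
    reversible: true
    interconversion: true
  # Nfn transhydrogenase: NADH + 2 Fd_rd -> 2 NADPH (four electrons moved)
  nfn:
    ledger: {fd_rd_pairs: -1, nadh: -1, nadph: 2}
    electrons: 4
    reversible: true
    interconversion: true
  # bifurcating hydrogenase Hym: 2 H2 -> NADPH + 2 Fd_rd
  hym:
    ledger: {fd_rd_pairs: 1, nadph: 1}
    electrons: 4
  # --- Wood-Ljungdahl methyl branch ---
  # formate dehydrogenase: CO2 + 2 Fd_rd -> formate
  formate_dehydrogenase:
    ledger: {fd_rd_pairs: -1, co2: -1}
    electrons: -2
  # formyl-THF synthetase: formate + THF + ATP -> formyl-THF
  formyl_thf_synthetase:
    ledger: {atp: -1}
    electrons: 0
  # methenyl-THF reductase (NADPH-dependent): methenyl-THF -> methylene-THF
  methenyl_thf_reductase:
    ledger: {nadph: -1}
    electrons: -2
  # methylene-THF reductase, NADH donor model
  methylene_thf_reductase_nadh:
    ledger: {nadh: -1}
    electrons: -2
  # methylene-THF reductase, bifurcating model: oxidizes two NADH and
  # reduces two Fd_ox as it reduces methylene-THF to methyl-THF
  methylene_thf_reductase_bifurcating:
    ledger: {nadh: -2, fd_rd_pairs: 1}
    electrons: -2
  # --- Wood-Ljungdahl carbonyl branch ---
  # CO dehydrogenase subunit (AcsA) of acetyl-CoA synthase: CO2 + 2 Fd_rd -> CO
  codh_acsa:
    ledger: {fd_rd_pairs: -1, co2: -1}
    electrons: -2
  # --- urea cycle ---
  # carbamyl-phosphate synthase (glutamine + CO2 + 2 ATP)
  carbamyl_phosphate_synthase:
    ledger: {atp: -2, co2: -1}
    electrons: 0
  # ornithine carbamyltransferase: ornithine + carbamyl-P -> citrulline
  ornithine_carbamyltransferase:
    ledger: {}
    electrons: 0
  # argininosuccinate synthetase (ATP -> AMP + PPi, 2 ATP equivalents)
  argininosuccinate_synthetase:
    ledger: {atp: -2}
    electrons: 0
  # argininosuccinate lyase: argininosuccinate -> arginine + fumarate
  argininosuccinate_lyase:
    ledger: {}
    electrons: 0
  # arginase: arginine -> ornithine + urea
  arginase:
    ledger: {}
    electrons: 0
  # glutamine synthetase: glutamate + NH3 + ATP -> glutamine
  glutamine_synthetase:
    ledger: {atp: -1, nh3: -1}
    electrons: 0
  # --- amino-acid degradation ---
  # ornithine -> glutamate + NH3; both oxidation steps (oxidative deamination,
  # glutamate-5-semialdehyde oxidation) assigned to ferredoxin-linked
  # oxidoreductases (4 electrons = 2 Fd pairs)
  ornithine_to_glutamate:
    ledger: {fd_rd_pairs: 2, nh3: 1}
    electrons: 4
  # glutamate -> acetyl-CoA + pyruvate + NH3 via the redox-neutral
  # mesaconate / citramalyl-CoA route
  glutamate_to_acetyl_coa_pyruvate:
    ledger: {nh3: 1}
    electrons: 0
  # fumarate -> (S)-malate (fumarase) -> pyruvate + CO2 (NADP-linked malic enzyme)
  fumarate_to_pyruvate:
    ledger: {nadph: 1, co2: 1}
    electrons: 2
  # aspartase: aspartate -> fumarate + NH3
  aspartase:
    ledger: {nh3: 1}
    electrons: 0
  # arginine deiminase route: arginine -> citrulline + NH3; citrulline + Pi ->
  # ornithine + carbamyl-phosphate; carbamate kinase recovers ATP, releasing
  # NH3 + CO2
  arginine_deiminase_path:
    ledger: {atp: 1, nh3: 2, co2: 1}
    electrons: 0
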
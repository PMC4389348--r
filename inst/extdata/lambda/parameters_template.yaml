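# Free-energy parameters of the phage-lambda switch model.
#
# This file is schema-complete but VALUE-EMPTY: every delta_g is null and must
# be transcribed from the experimental literature before quantitative use
# (each entry carries a provenance slot naming the customary source). The
# loader refuses a pathway report on placeholder values unless
# allow_placeholder is set, in which case nulls are taken as 0 kcal/mol.
#
# Sources customarily used for these values:
#   - Santillan & Mackey (2004), Biophys J 86:1282-1292 (collected parameter set,
#     including lysogenic/lytic fixed-point concentrations)
#   - Darling, Holt & Ackers (2000), J Mol Biol 302:625-638 (CI binding/cooperativity)
#   - Reinitz & Vaisnys (1990), J Theor Biol 145:295-318 (Cro, RNAP)
energy_units: kcal/mol
intrinsic:
  - {site: O_R1, species: CI2, delta_g: null, provenance: "transcribe: Darling et al. (2000)"}
  - {site: O_R2, species: CI2, delta_g: null, provenance: "transcribe: Darling et al. (2000)"}
  - {site: O_R3, species: CI2, delta_g: null, provenance: "transcribe: Darling et al. (2000)"}
  - {site: O_L1, species: CI2, delta_g: null, provenance: "transcribe: Santillan & Mackey (2004)"}
  - {site: O_L2, species: CI2, delta_g: null, provenance: "transcribe: Santillan & Mackey (2004)"}
  - {site: O_L3, species: CI2, delta_g: null, provenance: "transcribe: Santillan & Mackey (2004)"}
  - {site: O_R1, species: Cro2, delta_g: null, provenance: "transcribe: Reinitz & Vaisnys (1990)"}
  - {site: O_R2, species: Cro2, delta_g: null, provenance: "transcribe: Reinitz & Vaisnys (1990)"}
  - {site: O_R3, species: Cro2, delta_g: null, provenance: "transcribe: Reinitz & Vaisnys (1990)"}
  - {site: O_L1, species: Cro2, delta_g: null, provenance: "transcribe: Santillan & Mackey (2004)"}
  - {site: O_L2, species: Cro2, delta_g: null, provenance: "transcribe: Santillan & Mackey (2004)"}
  - {site: O_L3, species: Cro2, delta_g: null, provenance: "transcribe: Santillan & Mackey (2004)"}
  - {site: P_R,  species: RNAP, delta_g: null, provenance: "transcribe: Santillan & Mackey (2004)"}
  - {site: P_RM, species: RNAP, delta_g: null, provenance: "transcribe: Santillan & Mackey (2004)"}
  - {site: P_L,  species: RNAP, delta_g: null, provenance: "transcribe: Santillan & Mackey (2004)"}
pair_cooperativities:
  - {site_a: O_R1, species_a: CI2, site_b: O_R2, species_b: CI2, delta_g: null,
     provenance: "transcribe: Darling et al. (2000)"}
  - {site_a: O_R2, species_a: CI2, site_b: O_R3, species_b: CI2, delta_g: null,
     provenance: "transcribe: Darling et al. (2000)"}
  - {site_a: O_L1, species_a: CI2, site_b: O_L2, species_b: CI2, delta_g: null,
     provenance: "transcribe: Santillan & Mackey (2004)"}
  - {site_a: O_L2, species_a: CI2, site_b: O_L3, species_b: CI2, delta_g: null,
     provenance: "transcribe: Santillan & Mackey (2004)"}
  - {site_a: O_R1, species_a: Cro2, site_b: O_R2, species_b: Cro2, delta_g: null,
     provenance: "transcribe: Reinitz & Vaisnys (1990)"}
  - {site_a: O_R2, species_a: Cro2, site_b: O_R3, species_b: Cro2, delta_g: null,
     provenance: "transcribe: Reinitz & Vaisnys (1990)"}
  - {site_a: O_L1, species_a: Cro2, site_b: O_L2, species_b: Cro2, delta_g: null,
     provenance: "transcribe: Santillan & Mackey (2004)"}
  - {site_a: O_L2, species_a: Cro2, site_b: O_L3, species_b: Cro2, delta_g: null,
     provenance: "transcribe: Santillan & Mackey (2004)"}
looping:
  # CI octamer bridging the two operators via DNA looping; add further terms
  # (e.g. octamer + O_R3/O_L3 tetramer) following whichever published
  # decomposition is transcribed.
  - assignments:
      - {site: O_R1, configuration: CI2}
      - {site: O_R2, configuration: CI2}
      - {site: O_L1, configuration: CI2}
      - {site: O_L2, configuration: CI2}
    delta_g: null
    provenance: "transcribe: Santillan & Mackey (2004); octamer looping free energy"
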
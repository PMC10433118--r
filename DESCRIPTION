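Package: aquarisk
Title: Heavy-Metal Water-Quality Indices and Ingestion-Pathway Health Risk Assessment
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Deterministic assessment of heavy-metal contamination in drinking
    water from site-by-metal concentration tables. Computes the metal pollution
    index (geometric mean of concentrations, MPI) and the heavy-metal
    evaluation index (sum of concentration to maximum-allowable-concentration
    ratios, HEI), and the USEPA-style ingestion exposure chain: chronic daily
    intake (CDI), hazard quotients (HQ) and hazard index (HI) against oral
    reference doses, and incremental lifetime cancer risk (ILCR) from cancer
    slope factors, for configurable adult and child cohorts. Ships a versioned,
    overridable registry of regulatory limits (WHO, FEPA, FAO, USEPA),
    toxicological constants and exposure profiles, a bundled seven-site river
    survey, a lognormal synthetic-table generator for property testing, and a
    command-line pipeline producing report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
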
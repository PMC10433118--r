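---
title: "Heavy-metal water-quality indices and ingestion-pathway risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy-metal water-quality indices and ingestion-pathway risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquarisk)
```

## The problem

Rivers passing through fast-growing towns accumulate heavy metals from
urban runoff, garages, scrap and battery recycling, dumpsites and treated
and untreated effluent. A screening assessment asks two questions of a
small site-by-metal concentration table: how contaminated is the water as
a whole, and what does drinking it mean for human health? `aquarisk`
answers both deterministically, with every constant exposed in a versioned
registry. The bundled dataset, `sosiani_survey()`, is a seven-station
survey of Zn, Cu and Pb (mg/L) along the Sosiani River in Eldoret, Kenya.

## The model

**Indices.** For a site with concentrations $C_i$ (mg/L):

$$\mathrm{MPI} = \Big(\prod_{i=1}^{n} C_i\Big)^{1/n}, \qquad
  \mathrm{HEI} = \sum_{i=1}^{n} \frac{C_i}{\mathrm{MAC}_i}.$$

The MPI is a geometric mean — a unitless aggregate on the scale of the
concentrations, undefined at zero (a non-positive input is a domain error,
not a silent zero). The HEI references each metal to an authority's
maximum allowable concentration; WHO is the default because it is the set
under which the bundled survey's published HEI values are internally
consistent across all seven stations. The MPI is generalised to $n$ metals
although the classical form is written for three; it reduces exactly to
the cube-root product on the bundled data.

**Exposure chain.** For the drinking-water ingestion pathway:

$$\mathrm{CDI} = \frac{C_i \cdot \mathrm{IR} \cdot \mathrm{EF} \cdot
  \mathrm{ED}}{\mathrm{BW} \cdot \mathrm{AT}}, \qquad
  \mathrm{HQ} = \frac{\mathrm{CDI}}{\mathrm{RfD}}, \qquad
  \mathrm{HI} = \sum \mathrm{HQ}, \qquad
  \mathrm{ILCR} = \mathrm{CDI} \cdot \mathrm{CSF}.$$

HI ≥ 1 flags significant non-cancer risk. ILCR is banded negligible
(< 10⁻⁶), low (10⁻⁶–10⁻⁴) and high (> 10⁻⁴), and is only defined for
metals classified carcinogenic (Cd, Cr, Pb, As); requesting it for a
non-carcinogen errors rather than returning zero, because a missing slope
factor is not evidence of no risk.

## Parameters and their defaults

| parameter | adult | child | units |
|---|---|---|---|
| ingestion rate IR | 1.5 | 0.7 | L/day |
| exposure frequency EF | 350 | 350 | days/year |
| exposure duration ED | 70 | 15 | years |
| body weight BW | 70 | 15 | kg |
| AT, non-cancer | 30 × 365 | 6 × 365 | days |
| AT, cancer | 70 × 365 | 15 × 365 | days |

Both averaging times are stored explicitly and never derived from ED. This
is a deliberate modelling decision: the profiles combine ED = 70 y with a
30-y non-cancer averaging time for adults, so deriving AT = ED × 365 —
the more common convention — would silently change every hazard quotient.
The stored-AT convention is what the bundled survey's published doses were
computed under, and the package locks it in so that its outputs remain
reproducible against them. The ratio of child to adult non-cancer CDI at
equal concentration is the fixed profile constant 7/3 ≈ 2.333, and for the
cancer endpoint 98/45 ≈ 2.178; both are asserted exactly in the tests.

Toxicological constants: RfD (mg/kg/day) Zn 0.3, Cu 0.04, Pb 0.0035; CSF
for Pb 0.0085 per (mg/kg/day). The RfD values are documented in the
registry as derived from the bundled survey's own CDI/HQ ratios — three
independent ratios per metal agree to four significant figures — and they
coincide with the standard USEPA IRIS oral values. All constants live in
`inst/extdata/reference_data.yaml`; any run can substitute a modified copy
(`--reference` on the command line, or `load_reference_config()`), so new
metals and authorities need no code change. A metal missing from a limit
set raises an error rather than defaulting — explicit failure is the safer
behaviour in a regulatory computation.

## Classification bands

Only one MPI band is stated in the scheme the survey used: 0.3–1 is
"pure water". The default table therefore encodes three bands — below
pure-water (< 0.3), pure water [0.3, 1), polluted (≥ 1) — closed on the
left, open on the right. Note that the bundled survey's mean MPI of 0.2323
falls *below* the stated pure-water band even though the original
assessment labelled it pure; the package follows the stated boundaries,
not the label. For HEI only the top rule is encoded: strictly greater
than 10 is "very highly polluted". Both band tables are arguments
(`classify_mpi(x, bands = ...)`), since fuller schemes exist in the
literature but were not part of the scheme being reproduced.

## The summary row

The per-site tables carry a `Mean` row. For the risk chain every quantity
is linear in concentration, so the value at the mean concentrations equals
the mean of per-site values, and the two conventions coincide on any
complete grid — a property the tests assert. The geometric-mean MPI is not
linear, and there the convention matters: the package evaluates the index
*at the per-metal mean concentrations* (0.2323 on the bundled survey)
rather than averaging per-site indices (0.227), because index-of-means is
the convention the published summary row used. `summarize_indices()`
exposes both via `mean_method`.

## A reconciled transcription error

The bundled survey's transcribed S7 Pb cell reads 0.12 mg/L, but five
independent published figures for that station — MPI 0.1978, HEI 11.17,
adult HQ 1.507, adult ILCR 1.921 × 10⁻⁵, and the column mean
0.105714 = 0.74/7 — all require 0.11 mg/L; none is consistent with 0.12.
`sosiani_survey(correct_s7_pb = TRUE)` (the default) returns the
reconciled value and emits a message; `FALSE` returns the literal cells.
The linear HEI also provides a structural diagnostic: on a complete grid
the mean-row HEI must equal the mean of per-site HEIs, and the identity
breaks only under the literal cells.

Two further quirks of the published tables are handled without any flag:
the per-site HI cells were summed from *rounded* HQ cells (tests compare
full-precision values within 1.5 units of the last printed digit, which
absorbs this and the table's occasional truncation), and the child mean
CDI for Cu was printed with transposed digits (0.03360 where the chain
gives 0.03260 = 0.815 × 0.04).

Excess cancer cases per million are reported both as the exact real value
and as its ceiling. Ceiling is the conservative integer convention (it
never understates the expectation: 18.46 → 19 adults); reporting the
exact value alongside avoids committing to a rounding rule, since no
single rule reproduces both published integer counts (40.21 would give 41,
not the published 40).

## The synthetic generator

`generate_samples()` emulates the structure of a survey table: a small
number of sites, strictly positive concentrations varying site-to-site
around a metal-specific mean, and a reported uncertainty per cell. Each
cell is drawn independently from a lognormal law parameterised so the
*arithmetic* mean equals the requested mean and the coefficient of
variation equals the requested CV ($\sigma^2 = \log(1 + \mathrm{cv}^2)$,
$\mu = \log m - \sigma^2/2$). Lognormality guarantees the positivity the
analysis assumes; `cv = 0` degenerates to every site at the mean.
Uncertainties are a fixed fraction of each draw and are carried through
I/O but never propagated into indices or risks — the chain is a
point-estimate computation, and the survey's ± values come with no stated
error model. What the generator does *not* emulate: spatial or temporal
autocorrelation between sites, detection-limit censoring, or correlated
metals. Tests that pass on generated tables therefore validate the
algebra and the contracts, not the field realism of any particular river.

Tests recover the requested mean and CV within 2% at 10⁴ sites under a
fixed seed (the standard error of the mean at cv = 0.5 is 0.5%, so 2% is
a four-sigma band); routine property tests use 10–30 sites, which keeps
the whole suite in a few seconds.

## Numerical choices

* MPI is computed in the log domain (`exp(mean(log(c)))`) and checked
  against a direct product oracle to 12 significant digits.
* ILCR is clamped to the probability domain [0, 1].
* Report tables round to 4 significant figures by default (`--precision`),
  matching the precision of the published tables; full precision is kept
  internally.
* Band lookups are closed-left/open-right except the HEI top rule, which
  is strictly "greater than 10".

## Limitations

Ingestion is the only pathway modelled — no dermal or inhalation exposure,
no multi-pathway aggregation, and no Monte Carlo uncertainty propagation;
all outputs are point estimates. The classification tables encode only the
bands the reproduced scheme states. HPI and other index families (degree
of contamination, PLI) are out of scope.
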
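---
title: "Micro-costing genomic sequencing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-costing genomic sequencing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcost)
```

## The costing model

`seqcost` implements a bottom-up (micro-costing) model of genomic
sequencing from the health provider's perspective. The unit of analysis is
the **patient**, not the sample: where a design sequences matched tumour
and germline DNA, every item cost already covers both samples and is never
doubled downstream. Each project is a list of resource line items, each
assigned to one of seven workflow steps (sampling, DNA extraction, library
preparation, sequencing, analysis, data storage, clinician reporting) and
one of five cost types (labour, consumables, testing, equipment, other).
An item carries either a direct per-patient cost in AUD or a quantity and
unit price (staff hours at an hourly wage are the typical quantity form);
`component_cost()` resolves either form.

Aggregation is plain summation, but two conventions matter:

- **Step shares** are percentages of the **operating** total, excluding
  capital equipment. This is how workflow-step proportions are usually
  tabulated, because capital sits outside an operating budget.
- **Sensitivity results** are relative changes of the
  **capital-inclusive** total, since a decision-maker's bottom line
  includes the instrument charge. Only this pairing of denominators makes
  the shares and the sensitivity percentages mutually consistent on the
  packaged fixtures.

When library preparation and sequencing are bought as one outsourced
service their split is unrecoverable, so a project flag
(`merge_lib_seq`) reports them as a single combined row keyed
`library_prep_and_sequencing`; cross-project summaries always combine the
two steps so merged and unmerged projects are comparable. Steps a project
never performs (e.g. clinician reporting in a pre-clinical study) are
flagged absent and render as `n/a`, distinct from a true zero cost such as
a tumour biopsy already taken in routine diagnostic care.

## Capital equipment

A sequencer bought for `K` with useful life `n` years at interest rate `r`
is converted to an equivalent annual cost `K / A(r, n)` with the annuity
factor `A(r, n) = (1 − (1 + r)^{-n}) / r` (limit `n` as `r → 0`), divided
by annual patient throughput, and increased by maintenance. Defaults are
`n = 5`, `r = 0.03` and a maintenance ratio of 0.5: in the source cost
tables the maintenance row is exactly half the machine row in every
project, so that ratio is the package default but remains configurable.
The fixtures carry the published per-patient machine and maintenance
charges directly (the underlying acquisition prices and throughputs were
never published); the full annuitization path is exercised by
`equipment_spec()` inputs and the synthetic generator. An equipment spec
with `annual_patients = 0` is rejected rather than producing an infinite
charge.

## Storage and currency

Data storage is priced per GB-month in USD on three cloud tiers —
coldline 0.007, nearline 0.010 (the base case), regional 0.025 — over a
default 60 months, then converted to AUD:
`gb × price × months / usd_per_aud`. The exchange rate is always an
explicit input with default 0.6929 USD per AUD (the 2018 market rate); the
package treats it strictly as USD-per-AUD because that is the only
reading consistent with the published AUD→USD conversions. The fixtures
carry their published per-patient storage costs verbatim, because those
printed values are not exactly recoverable from the tier price and any
stated rate; the storage formula is used for synthetic and what-if
projects, and for tier scenarios the engine scales the storage component
multiplicatively (price ratio), which is exact because storage cost is
linear in the price.

## One-way sensitivity

A scenario selects items (by step, cost type and/or label pattern) and
perturbs them multiplicatively (or replaces their cost outright). Because
aggregation is linear, the relative change of the capital-inclusive total
under factor `f` equals `(f − 1)` times the selected component's share of
that total; the test suite verifies the engine against this closed form
and against brute-force recomputation on synthetic cohorts. The default
scenario set mirrors the standard analysis: the combined library
preparation + sequencing price ±10%, scientist wages ±20% applied to
**all** labour-typed items (a step filter is available for narrower
scopes; the all-labour default is what reproduces the published 0.5–5.4%
range), and the storage tier moved to its coldline/regional neighbours.
Tornado tables sort scenarios by swing `|total_high − total_low|`, with
alphabetical tie-breaks so repeated runs are byte-identical. Cross-project
means are unweighted — each project counts once regardless of its patient
numbers — matching the published summary convention. Probabilistic
(bootstrap) sensitivity analysis is out of scope: the underlying resource
data are deterministic point estimates, not patient-level observations.

## Numerical conventions

All arithmetic runs at full double precision; rounding happens only in
renderers (2 dp for AUD, whole dollars for USD, 1 dp for percentages).
Published tables rounded each component to the cent, so their printed
sums carry ±0.01 residues (and two genome columns a +0.10 residue in the
capital-inclusive row); the fixtures encode the printed components, and
fixture-level comparisons therefore use cent-level tolerances (0.005 at
item level, 0.05 at table level) rather than exact equality. Validation
errors name the offending item or field; an inventory row may give both
costing forms only if they agree within 0.005 AUD.

## The synthetic generator

`generate_project()` draws projects that look like real sequencing
applications without reproducing any real inventory: lognormal per-step
cost components whose log-scale locations are centred on the magnitudes
of the six fixtures (sampling ≈ 25 AUD, extraction consumables + QC ≈ 80,
library prep + sequencing ≈ 320/1400/3200 for panel/exome/genome),
labour expressed as hours at the two wage levels (46.57/51.86 AUD/h), a
technology-ordered storage footprint (2–4 / 10–40 / 150–250 GB, pairs
adding a 0.48 germline fraction, i.e. 72/150), a lognormal instrument
price annuitized through the capital module, and a rework rate
(default 0.3, the observed fraction of tumour biopsies failing the
minimum tumour-content requirement) that inflates every DNA-extraction
item by `1 + rework_rate`. Each project is deterministic in
`(seed, index)`; drawing is done under a locally restored RNG state so the
caller's random stream is never disturbed, and the rework multiplier is
applied after the draws so rework-on/off cohorts differ by exactly that
factor.

What the generator does **not** emulate: correlated component costs (bulk
pricing discounts), per-patient cost variation within a project (the
model is deterministic per project, like the source data), failed-run
repeat sequencing fees, or any wet-lab detail. Tests that pass on
synthetic cohorts therefore demonstrate accounting correctness —
conservation, linearity, determinism — not realism of any particular cost
level.

## Problem sizes and limitations

The packaged analyses are small by construction: six fixture projects,
scenario grids of a few factors, and synthetic cohorts of 1000 projects
for the property checks (a cohort of that size costs well under a minute
to generate and verify). Known limitations: fixtures encode published
per-patient component costs, not raw resource quantities, so re-deriving
a component from first principles (hours × wage for every labour row) is
only possible for synthetic projects; the breast panel's MLPA assay is
embedded in its sequencing-step rows and cannot be isolated as its own
item; and the package models sequencing costs only — no downstream
patient management, cost-effectiveness or budget-impact modelling.
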
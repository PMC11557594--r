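---
title: "Methods: reactivity descriptors, DOS/PDOS and vibrational band analysis with qcpost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reactivity descriptors, DOS/PDOS and vibrational band analysis with qcpost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcpost)
```

`qcpost` implements the analysis stage that sits *after* an electronic-structure
calculation: everything here starts from summary records (orbital energies,
total energies, dipoles, harmonic frequencies, population weights) and never
touches a wavefunction. This vignette explains the models and conventions
behind each stage, the parameters that matter, and the choices made where the
field's conventions are genuinely ambiguous.

## The structure-summary record

A `qc_record` stores orbital energies in eV with an explicit per-orbital
occupancy flag, the total energy in hartree, the dipole vector in Debye and
the harmonic frequencies in cm⁻¹. Unit conversions are explicit operations
(`hartree_to_ev()`), never implicit. Occupancy is a stored flag rather than
being inferred from an electron count because summaries are often truncated to
the frontier region, where counting is meaningless. Validation is strict on
the one property every downstream stage relies on: every occupied orbital must
lie below every virtual one, otherwise HOMO/LUMO and the occupied/virtual DOS
split are ill-defined and the record is rejected. Imaginary frequencies
(encoded as negative wavenumbers, the usual output convention) are kept but
flagged, and excluded from frequency scaling.

The canonical JSON serialization fixes key order and writes floats at full
precision, so `write ∘ read` is byte-stable and golden-file tests work.

## Koopmans-type reactivity descriptors

From a frontier pair $(\varepsilon_\mathrm{HOMO}, \varepsilon_\mathrm{LUMO})$
in eV the cascade is

$$I = -\varepsilon_\mathrm{HOMO},\quad A = -\varepsilon_\mathrm{LUMO},\quad
\chi = \tfrac{I+A}{2},\quad \mu = -\chi,\quad
\eta = \tfrac{I-A}{2},\quad \sigma = \tfrac{1}{\eta},\quad
\omega = \tfrac{\mu^2}{2\eta},$$

with the gap $\Delta E = \varepsilon_\mathrm{LUMO} -
\varepsilon_\mathrm{HOMO} = 2\eta$ an exact algebraic identity that the test
suite asserts rather than measures. $\omega \ge 0$ whenever $\eta > 0$, and
$\sigma\eta = 1$ to machine precision; these invariants are checked across
randomly generated frontier pairs.

The fraction of transferred electrons toward a metal surface is computed as

$$\Delta N = \frac{\chi_\mathrm{ref} - \chi_\mathrm{inh}}
{2(\eta_\mathrm{ref} - \eta_\mathrm{inh})}$$

with the default reference $\chi_\mathrm{ref} = 0$, $\eta_\mathrm{ref} = 7$ eV
and a *difference* in the denominator. This is deliberately the literal
parameterization used in the corrosion-inhibition literature this package
accompanies, even though the broader conceptual-DFT literature more commonly
uses $\chi_\mathrm{Fe} = 7$ eV, $\eta_\mathrm{Fe} = 0$ and a *sum* in the
denominator. Since no tabulated $\Delta N$ values exist to adjudicate between
the two, the package refuses to guess: the literal form is the default and the
conventional rule is one explicit flag away
(`reference_metal(7, 0, rule = "sum")`). Both forms error on a vanishing
denominator rather than returning an infinity.

### Reproducing printed tables, and refusing to over-fit them

Printed descriptor tables round at 3 decimals; the apparent convention is
round-half-away-from-zero, which `round_half_away()` implements (base R's
`round()` is half-to-even). Comparisons of full-precision values against
printed cells use an absolute tolerance of 0.0015 on the printed scale —
printing precision plus rounding slack — through `compare_to_reference()` /
`consistency_vs_table()`, which *flag* failing cells instead of silently
tolerating them.

This matters because the bundled reference tables are internally inconsistent
in a handful of cells, reproducible by hand arithmetic:

* the GO row's printed $\mu$ (−4.156) disagrees with its own $I, A$
  (−4.160), and its $\sigma$ (11.855) and $\omega$ (102.575) disagree with
  the printed $\eta = 0.084$ ($1/0.084 = 11.905$);
* the CN row's printed gap (6.571 eV) disagrees with its own frontier
  energies (7.461 eV);
* the CHO row's $\mu$ and $\omega$ sit between the printed value and its
  correct 3-dp rounding (e.g. $\omega = 1.6117$ printed as 1.611).

The test suite asserts that exactly these cells — and no others — are flagged.
A pipeline that "reproduced" them would be wrong.

## Binding energetics

`binding_energy()` reports the raw difference
$\mathrm{BE} = E_\mathrm{complex} - \sum_i E_{\mathrm{fragment},i}$ in hartree
and eV (27.2114 eV/hartree by default, configurable to the full CODATA value),
negative meaning favorable. On the bundled cellulose + OH reference energies
the raw arithmetic gives +0.560/+0.589 hartree for the center/terminal
complexes while the printed table shows −0.564/−0.594; the ~0.004 hartree
offset and sign are unexplained by the printed inputs. The package documents
and surfaces this (the consistency report, and the pipeline printing
recomputed next to supplied values) and never flips signs to match.
`rank_sites()` orders by ascending BE with lexicographic site-tag tie-breaks,
so ranking the *printed* BEs places the terminal site first, consistent with
the study's conclusion.

## DOS and PDOS construction

The density of states is a sum of unit-area Gaussians centred at the orbital
energies,
$\mathrm{DOS}(E) = \sum_i G(E - \varepsilon_i;\ \mathrm{fwhm})$, evaluated on
a uniform grid padded beyond the extreme orbitals. Defaults: fwhm 0.3 eV,
grid step 0.01 eV, padding 4 × fwhm. These are conventional molecular
post-processing values (GaussSum-style); the figures this emulates do not
state their broadening, so only property-based checks are possible — and they
are strong ones:

* the trapezoidal integral equals the orbital count (within 1%; with 4 × fwhm
  padding the truncated tail mass is ~10⁻¹⁰ of a state, so the observed error
  is at grid level);
* the projected curves obey partition of unity,
  $\sum_g \mathrm{PDOS}_g(E) = \mathrm{DOS}(E)$ pointwise to < 10⁻⁹, because
  each orbital's population row sums to 1;
* translation invariance and additivity under concatenation of orbital lists.

The Fermi reference of molecular DOS plots ("occupied below 0, virtual
above") is not uniquely defined; the default here is the midgap point
$(\varepsilon_\mathrm{HOMO} + \varepsilon_\mathrm{LUMO})/2$, which guarantees
the occupied/virtual split straddles 0 for any valid record, with
`mode = "homo"` available. PDOS grouping is by named atom group supplied in
the record — the package partitions states, it does not compute populations
from wavefunctions.

## Vibrational band analysis

Band lists model both single-valued bands and envelopes (intervals such as
the C–O–C region 1030–1160 cm⁻¹); a `present = FALSE` flag represents the
tabulated "-" of a mode a method fails to produce, which never participates in
matching.

**Matching** is one-to-one and *monotone*: both lists are in wavenumber order
and assignments never cross, because band order is physically meaningful. The
matching minimizes total residual by dynamic programming, with each skipped
band costing `tol`, so a pair forms only when cheaper than leaving both sides
unmatched; pairs with residual above `tol` are then dissolved. The residual
to an interval is 0 inside/overlapping it, else the distance to the nearest
endpoint. Greedy nearest-neighbour matching was rejected: it is
order-unstable under ties and can cross.

**Model scoring** (`model_error()`) computes MAD and RMSD over matched
single-valued pairs; interval pairs are excluded by default since an overlap
residual is not a like-for-like distance. Ranking is by MAD, then RMSD, then
tag. Over the eleven bundled method/basis columns, restricted to the seven
single-valued bands every column shares with experiment, this selects
B3LYP/3-21G (MAD 131/7 ≈ 18.71 cm⁻¹) ahead of HF/3-21G (142/7 ≈ 20.29 cm⁻¹)
— the table-driven route to the study's stated conclusion, for which no MADs
are printed. The ranking run uses `tol = Inf` (row-aligned tables, maximal
matching); the default `tol = 100` cm⁻¹ is for generic model-vs-experiment
assignment where distant pairs should dissolve.

**Differencing** (`diff_bands()`) uses the same matcher at a default
50 cm⁻¹, chosen for experiment-vs-experiment comparison so that the shifted
C–O pair 1640↔1620 matches while the genuinely new carbonyl feature at
1710 cm⁻¹ is isolated as *new*. On the bundled cellulose vs cellulose–GO
film tables this yields exactly one new band (1710 cm⁻¹, the carboxyl of GO)
and no upward shift in any matched pair — every band moves down or, in one
case (C–CO at 1280 cm⁻¹), stays put.

**Scale estimation** (`estimate_scale()`) is the least-squares slope through
the origin of experimental on calculated wavenumbers,
$\hat s = \sum c_i e_i / \sum c_i^2$ — the standard effective scaling factor.
It is scale-equivariant and recovers a noiseless factor exactly. The scaled
reference tables never state the factors actually applied, so the estimator
recovers effective factors but cannot validate a historical choice.

## The synthetic generator

`synthetic_spec()` + `gen_qc_record()` generate records with the statistical
structure the analysis assumes: an occupied and a virtual normal cluster
separated by a prescribed gap (clipped at ±gap/2, frontier pinned so the
generated gap is exact), symmetric-Dirichlet population rows, normal dipole
components, and uniform mid-IR frequency sets. `gen_freq_pair()` emulates the
calculated/experimental pairing with a known true scale factor (default
0.9614, a typical harmonic correction) and additive Gaussian noise (default
5 cm⁻¹, the scale of tabulation/readout error). Defaults mirror the bundled
cellulose tables: a ~7.9 eV gap, three atom groups (C, H, O), 30 bands.

Each spec carries its own seed; generation saves and restores the global RNG
state, so fixtures are reproducible and tests cannot interact through the
RNG. What the generator does *not* emulate: realistic orbital spacing beyond
the cluster-plus-gap model, mode-dependent scaling error, band intensities,
or correlated noise. Passing tests therefore demonstrate correctness of the
*analysis* under its stated assumptions, not fidelity of any electronic
structure.

Problem sizes used in the validation suite — 100 seeded records for the
DOS/PDOS properties, 50 seeds × 30 bands for scale recovery (mean recovery
within ±0.002, each seed within ±0.005) — are large enough that the checked
tolerances are meaningful yet the whole suite runs in seconds.

## The pipeline

`run_pipeline()` wires the stages over a record set and writes one CSV per
report, each with a full-precision `_full.csv` sidecar next to the rounded
view (`precision`, default 3). Configuration comes from `run_config()` or a
YAML file with the same keys (`read_run_config()`), with explicit arguments
overriding file values. Per-stage failures are logged and counted without
aborting the remaining stages; re-running a configuration reproduces
byte-identical outputs. This function surface *is* the package's command
interface: users drive it from R or an Rscript one-liner.

## Known limitations

* Descriptors are Koopmans-type estimates from orbital energies; no
  ΔSCF, no correlation correction.
* No condensed (per-atom) Fukui functions or local reactivity indices.
* No counterpoise/BSSE correction in binding energies.
* No peak-picking from absorbance traces and no anharmonic corrections;
  band lists enter as tabulated.
* DOS/PDOS curves are data products; publication-style stick-plus-envelope
  figures are left to the user (`plot()` gives a simple line plot).
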
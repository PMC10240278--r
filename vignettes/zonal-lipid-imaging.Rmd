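---
title: "Zone-resolved hepatic lipid signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zone-resolved hepatic lipid signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonalipid)
```

# The problem

The liver lobule distributes oxygen and nutrients asymmetrically along the
porto-central axis, so hepatocytes in the periportal zone (Z1), midzone (Z2)
and pericentral zone (Z3) run different lipid metabolism. Ambient mass
spectrometry imaging (DESI-MSI) measures a full mass spectrum at every
50-micrometre pixel of a tissue section, which makes it possible to ask, per
lipid species, whether its abundance differs across the three zones.

`zonalipid` implements that analysis end to end — and, because raw imaging
data of this kind are rarely public, it pairs the analysis with a generator
that simulates lobule-structured imaging datasets with *known* zonal
effects, so every stage can be validated against ground truth.

The pipeline is:

1. **simulate** — per-pixel centroided spectra over an idealised hexagonal
   lobule, for several mice and both ionisation modes;
2. **preprocess** — cross-pixel peak alignment, mass-range filtering,
   total-ion-count (TIC) normalisation (plus smoothing, baseline correction
   and peak picking for profile-mode spectra);
3. **annotate** — accurate-mass lipid identification with adduct rules and
   an M+1 isotope-pattern check;
4. **zones** — random sampling of three 10-pixel regions of interest (ROIs)
   per zone and extraction of per-ROI median lipid intensities;
5. **stats** — a per-lipid mixed model of zonation with mouse as a random
   effect, likelihood-ratio chi-square tests, Benjamini–Hochberg control;
6. **pathways** — ranking of metabolic pathways by a betweenness-centrality
   score plus hypergeometric over-representation.

# The lobule geometry and the zonal coordinate

A lobule is modelled as a hexagon with the central vein at its centre and
portal triads at the six vertices. Each pixel's zonal coordinate is

$$u = \frac{d_\text{vertex}}{d_\text{vertex} + d_\text{center}},$$

with $d_\text{vertex}$ the distance to the *nearest* vertex: $u = 0$ at a
portal triad and $u = 1$ at the central vein. Zones are obtained by
thresholding $u$ at two cut points.

**Design choice — tercile thresholds.** Fixed thresholds at (1/3, 2/3) do
*not* give three zones of similar area under this coordinate: brute-force
enumeration on a 120×120 grid yields area fractions of roughly 0.33 / 0.53 /
0.14, because the level sets of $u$ are not equally spaced in area. Since
the zones of a lobule are conventionally drawn as three bands of comparable
tissue mass, the default thresholds are the *empirical terciles* of the
in-lobule coordinate distribution, which gives three near-equal zones by
construction. Fixed thresholds remain available via
`lobule_geometry(zone_thresholds =)`.

# The synthetic lipidome

`hepatic_lipid_library()` builds a deterministic 269-entry library across 12
lipid classes; 117 entries carry a non-flat zonal profile with a
dominant-to-minimum fold change of at least 2. The zonal directions follow
the known biology: fatty acids and arachidonate/docosahexaenoate-containing
phospholipids periportal, a phosphatidylinositol subset midzonal,
di-/triacylglycerols and most sphingolipids pericentral, and
phosphatidylglycerols flat. Sum-composition formulas are derived from
backbone arithmetic (e.g. a PC with $n$ acyl carbons and $d$ double bonds is
C$_{n+8}$H$_{2n-2d+16}$NO$_8$P) and validated against reference
monoisotopic masses, e.g. PC(34:2) = C₄₂H₈₀NO₈P = 757.5622 Da, protonated
758.5694.

Two design rules make the library identifiable by accurate mass alone,
which real lipidomes are not:

* **Adduct-lattice screening.** On the (carbons, double bonds) lattice,
  `[M+Na]+` of species $(n{:}d)$ lies only ~3 ppm from `[M+H]+` of
  $(n{+}2{:}d{+}3)$, and PE$(n{+}3{:}d)$ is exactly isobaric with
  PC$(n{:}d)$. The library greedily accepts compositions whose
  mode-compatible adduct positions are pairwise at least 30 ppm apart;
  where two literature species fall on a colliding pair, the one whose m/z
  the analysis anchors on wins and the other is replaced by a same-zone
  alternative composition.
* **Isotopologue screening.** An M+1 isotopologue of a *zonal* lipid that
  co-bins with another lipid's monoisotopic feature would leak its zone
  profile into that lipid's quantification. Differential entries are
  therefore additionally screened so their M+1 positions stay ≥ 15 ppm from
  every other monoisotopic position (the nearest systematic lattice
  relation sits at ~11 ppm; 15 ppm keeps it un-mergeable at the 10 ppm
  alignment tolerance). Flat-lipid M+1 overlap is deliberately *not*
  screened — deisotoping is out of scope, and the residual contamination is
  part of what the pipeline must tolerate.

**Zone-balanced totals.** TIC normalisation divides each pixel by its total
signal. If total lipid content itself were zonated, this would imprint
spurious anti-correlated zone effects on every flat lipid — a compositional
artifact, not a statistical one. The generator therefore emulates tissue in
which total lipid signal per unit area is zone-independent (zonation
redistributes composition, not total content): after profiles are assigned,
non-dominant profile entries are adjusted by a bounded iterative scheme
until the expected per-pixel totals agree across zones exactly, preserving
each lipid's dominant zone and its ≥ 2 fold change.

# The generative model

For mouse $m$, pixel $p$ in zone $z(p)$, and lipid $L$, the pre-split amount
is

$$A_{mpL} = b_L \, \rho_L(z(p)) \cdot e^{\varepsilon_{mL}} \cdot
  e^{\eta_{pL}} \cdot e^{\tau_p},$$

with $b_L$ the base abundance, $\rho_L$ the zonal profile,
$\varepsilon_{mL} \sim N(0, \sigma_\text{mouse}^2)$ a per-(mouse, lipid)
random intercept, $\eta_{pL} \sim N(0, \sigma_\text{noise}^2)$ pixel noise
and $\tau_p \sim N(0, \sigma_\text{tic}^2)$ a whole-pixel TIC factor. The
amount is split across the class's adducts (weights summing to one, so the
adduct intensities conserve the pre-split amount exactly), an M+1
isotopologue is added at the natural ¹³C ratio $0.0107 \times n_C$, and
every peak's m/z is jittered with a relative SD of `mass_error_ppm`.

The mouse intercept is drawn per (mouse, lipid) rather than per mouse: a
single per-mouse factor would be removed entirely by TIC normalisation and
the mixed model's random effect would have nothing to absorb; per-lipid
biological variation between animals is also the realistic reading.

On top of the lipids, each mode carries zone-flat **background ions**
(default 500 positive, 250 negative, each present in 60 % of pixels, with
twice the lipids' total signal). They emulate the untargeted feature space
of ambient ionisation — in real acquisitions thousands of features are
detected of which only a few hundred annotate to lipids — and they dominate
the TIC the way chemical noise does in practice. Their m/z are drawn at
least 30 ppm away from every possible lipid adduct or isotopologue
position, so they can never be annotated.

Default noise scales (`mouse_sd` 0.3, `noise_sd` 0.4, `tic_sd` 0.25,
`mass_error_ppm` 2) are chosen once as typical for ambient MSI: ~40 % CV at
the single-pixel level, a few percent at the ROI-median level, and m/z
precision appropriate for a QTof. The default grid is 40×40 pixels at 50 μm
(a 2 mm field holding one lobule, ~940 in-tissue pixels, ~310 per zone).

# Preprocessing

Alignment pools all centroids of a mode and scans them in ascending m/z; a
peak joins the current bin while it is within `tol_ppm` (default 10) of the
bin's running intensity-weighted mean, implemented in compiled code. On
well-separated centroids this equals single-linkage clustering at the same
tolerance (property-tested). TIC normalisation rescales each pixel so its
feature sum equals the mean pre-normalisation TIC — keeping intensities on
an interpretable scale rather than normalising to 1 — and is idempotent.
Mass-range bounds (default the acquired m/z 100–1200) are inclusive.
Normalisation is applied per pixel before ROI extraction. The profile-mode
operations (moving-average smoothing, rolling-minimum baseline subtraction,
SNR-thresholded peak picking with half-maximum centroiding; defaults window
5, half-window 50 points, SNR 3) are provided for profile spectra; the
generator emits centroided sticks, so the end-to-end path starts at
alignment.

# Annotation

Each feature is matched against every mode-compatible (lipid, adduct) pair
within `tol_ppm` (default 10 ppm, QTof-appropriate); candidates are ranked
by absolute ppm error, ties broken by the isotope score and then lexical
id. The isotope score compares the observed (M+1)/M ratio — taken from the
feature found at m/z + 1.0034 — with the expected $0.0107 \, n_C$, as
$\max(0, 1 - |obs - exp|/exp)$. Adduct shifts use proton-bound values; the
electron mass (< 1 ppm here) is neglected. Annotations are reported at sum
composition; chain-resolved names are synonyms at this level since MS/MS is
out of scope. Unannotated features (background ions, isotopologues) stay in
the matrix but never enter the zonal statistics.

# ROIs and the zonal table

Manual, histology-guided ROI placement is replaced by seeded random
sampling: per zone, three disjoint 4-connected regions of 10 pixels are
grown breadth-first from random in-zone seeds (10 px/ROI × 3 ROIs × 3 zones
= 90 pixels per mouse, 30 per zone). A lipid's pixel intensity is the sum
over its rank-1 adduct features — the adduct split is instrumental, not
biological — and each (lipid, mouse, zone, ROI) row of the zonal table is
the median over the ROI's 10 pixels (even counts: mean of the two central
order statistics). The dominant zone is the zone with the largest mean ROI
median; exact ties are flagged and resolved toward the lower zone index.

# The zonation test

Per lipid, on $y$ = log median intensity (intensities are positive and the
noise is multiplicative; zeros, which cannot arise under the generator's
model but may in user data, are replaced by half the lipid's smallest
positive value, with a message):

$$y_{mzr} = \mu + \beta_z + b_m + e_{mzr}, \qquad
  b_m \sim N(0, \sigma^2_\text{mouse}),\;
  e \sim N(0, \sigma^2_\text{resid}),$$

fitted by maximum likelihood: for a given variance ratio
$\lambda = \sigma^2_\text{mouse}/\sigma^2_\text{resid}$ the GLS estimates
and the profiled $\hat\sigma^2_\text{resid}$ are closed-form (the
within-group inverse is $I - \tfrac{\lambda}{1+k\lambda}J$), and $\lambda$
is maximised on a log-spaced grid with local refinement. ML rather than
REML because the zone test is a likelihood ratio between fixed-effect
structures: $\chi^2 = 2(\ell_\text{full} - \ell_\text{null})$, clipped at
zero, referred to $\chi^2_2$ (the 3-level zone factor has 2 df).
Benjamini–Hochberg adjustment is applied across lipids and significance
declared at $q \le 0.05$. The fit is cross-checked against `lme4` in the
test suite, and the LRT's type-I error at five mice is verified to sit in
[0.03, 0.08] at nominal 0.05 over 1000 null simulations.

With the default design (5 mice × 3 zones × 3 ROI medians = 45
observations, ≥ 2-fold planted effects against an ROI-median residual SD of
roughly $1.25\,\sigma_\text{noise}/\sqrt{10} \approx 0.16$ on the log
scale), power for the 117 planted lipids is essentially 1, and the BH
step-up at the resulting threshold admits a handful of the 152 flat lipids,
so a default run reports ~117–127 significant lipids with false-discovery
proportion well under 0.10.

# Pathway ranking

Pathways are undirected graphs over compound and reaction nodes (a small
synthetic PathBank-style fixture ships in `inst/extdata/`; real pathway
databases are out of scope). Relative betweenness divides the unordered-pair
betweenness by $(N-1)(N-2)/2$; disconnected pathways are normalised per
connected component. The pathway score is the *hit-mass fraction of
compound-node centrality*: the summed centrality of hit compounds over that
of all compound nodes, bounded in [0, 1], with 0/0 defined as 0 — the
aggregation of node centralities into a pathway score is a genuinely open
choice, and this one rewards hits on topologically central intermediates
rather than peripheral leaves. Reaction nodes shape the topology but are
never hits. Over-representation uses the exact hypergeometric upper tail
with the background defined as the union of all pathway compounds; lipids
map to species-generic compound nodes at class level. Results are sorted by
descending score, then ascending ORA p, then name. In the default run the
significant lipids cover the glycerolipid backbone (FA, LPA, PA, DG, TG),
so de novo triacylglycerol biosynthesis — whose compounds are exactly that
chain — ranks first.

# Reproducibility metrics

Replicate acquisitions of one section share the tissue's lipid amounts and
differ only in measurement noise (`simulate_replicates()` sets the mouse SD
to zero). For each lipid and zone the zone-median intensity is computed per
replicate; the percent coefficient of variation ($100\,\mathrm{SD}/\mathrm{mean}$)
is taken across replicates and averaged over zones. Under default noise the
high-abundance half of the library shows a median %CV around 8 — comfortably
below the 20 % acceptance line used in bioanalytical method validation.

# Problem sizes and determinism

Default analyses use a 40×40-pixel lobule, 5 mice (3 replicates for the
reproducibility module), both modes, and the full 269-lipid library; null
calibration uses 1000 simulated lipids. One seed governs every stochastic
stage, with per-stage derived substreams (large co-prime offsets), so any
stage can be rerun reproducibly; `simulate_dataset()` restores the caller's
RNG state.

# What passing tests do and do not show

The generator emulates zonal gradients, between-animal variation,
multiplicative pixel noise, TIC drift, adduct chemistry, M+1 isotopologues
and an unannotatable background — but not profile-mode peak shape,
in-source fragmentation, chimeric features, ion suppression that varies
with tissue composition, isomeric lipids sharing an exact mass, or
histology imperfections in zone assignment. Recovery of the planted
269/117 funnel therefore validates the pipeline's statistical and
computational machinery, not the instrument-facing steps it abstracts away;
on real data, annotation would need MS/MS confirmation and ROIs would come
from co-registered histology.

# Known limitations

* Accurate-mass annotation is only unambiguous because the synthetic
  library is collision-screened; applied to a real lipidome the same code
  would return ranked candidate lists with genuine ties.
* The mixed model assumes log-normal residuals and a single random
  intercept; zone-by-mouse interactions are absorbed into the residual.
* Pathway scoring depends on fixture topology; with hit sets that cover
  most compounds the score saturates at 1 and ordering falls to the ORA p
  value.
* The ML likelihood-ratio test is mildly liberal at very small mouse
  numbers (noticeable at n = 2); at the default n = 5 its size is verified
  empirically.
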
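---
title: "Modelling DNA damage by light ions: physics, surrogates and calibration"
author: "IonTrackDamage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DNA damage by light ions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IonTrackDamage)
```

# The problem

Ions used in radiotherapy (protons through neon, roughly 0.01–256 MeV/u)
deposit energy along dense tracks whose microscopic structure controls how
much DNA damage a cell nucleus sustains per unit dose. This package
simulates that chain end to end at a deliberately coarse, desk-scale level:
interaction data for all ions are scaled from a hydrogen baseline, ions are
transported through a spherical lymphocyte nucleus, the absorbed dose is
converted to LET, energy deposits are superposed on a voxelized chromatin
model to produce strand breaks, and the breaks are classified into the
nested hierarchy of double-strand breaks (DSB), DSB clusters, DSB sites and
single-track DNA fragments.

# Effective-charge scaling

A slowing ion carries electrons and screens its nuclear charge. The Barkas
parameterization of this effect is

$$Z_{\mathrm{eff}}(Z, \beta) = Z\left(1 - e^{-125\,\beta\,Z^{-2/3}}\right),$$

with $\beta = v/c$ from relativistic kinematics (rest energy
931.494 MeV per nucleon). Interaction data for an ion of atomic number $Z$
are obtained from the hydrogen data at the same velocity by the generalized
factor

$$F(Z, \beta) = \frac{Z_{\mathrm{eff}}(Z,\beta)^2}{Z_{\mathrm{eff}}(1,\beta)^2},$$

whose hydrogen denominator makes the scheme exactly self-consistent
($F \equiv 1$ for hydrogen) and extends its applicability down to about
10 keV/u. $F$ runs from $Z^{2/3}$ at vanishing velocity to $Z^2$ at high
velocity; the radiation-quality parameter $(Z_{\mathrm{eff}}/\beta)^2$
correspondingly saturates at $15625\,Z^{2/3}$. The constants 125 and
$-2/3$ are hard-coded: they fix those printed limits, and a configurable
constant would silently break them. The scaling is applied to the single
aggregate inverse mean free path (IMFP) and stopping power; energy-transfer
spectra are taken over from isotachic hydrogen unchanged.

# The hydrogen baseline

The baseline (`defaultBaseline()`) is a self-contained closed-form
parameterization of hydrogen-in-water interaction data, not a measured
cross-section set. It has three branches:

* **Above 1 MeV** — relativistic Bethe stopping for water with mean
  excitation energy $I = 75$ eV and the kinematic maximum energy transfer.
* **0.08–1 MeV** — $\ln S$ is a quintic in $\ln E$ pinned by six
  conditions: value and slope continuity with Bethe at 1 MeV, zero slope at
  the 0.08 MeV stopping maximum, and three conditions imported from
  ICRU-anchored values of the *scaled* stopping — the carbon maximum of
  870 keV/μm at 0.25 MeV/u and the positions of the carbon (0.25 MeV/u)
  and neon (0.40 MeV/u) maxima, which translate into one value and two
  slope constraints on the hydrogen curve through $F$.
* **Below 0.08 MeV** — a power law in $E$ whose exponent is calibrated so
  the 10%-extrapolated range of a 0.25 MeV proton is 4.0 μm.

Two consequences are worth stating plainly. First, the sub-MeV branch
represents the stopping of the *hydrogen charge-state mixture* (protons
plus neutral atoms), which the scaled-carbon anchor places roughly 15–20%
above proton-only tabulations near 0.25 MeV; this is a feature of
hydrogen-referenced scaling, not an error. Second, above 1 MeV the curve is
plain Bethe with $I = 75$ eV and no shell or density corrections; the
integrated proton slowing-down range at 256 MeV therefore comes out at
about 39.5 cm (and 13.2 cm for 256 MeV/u carbon), consistent with standard
tabulations at that energy.

The collision spectrum is a truncated inverse-square distribution on
$[t_{\min}, t_{\max}(E)]$ with $t_{\min} = 12$ eV and $t_{\max}$ following
the kinematic free-electron maximum, floored at 30 eV and capped at 5 keV.
The cap keeps the heavy tail of the per-collision loss manageable; energy
beyond it is represented by the kernel's displacement tail rather than by
rare huge transfers. The IMFP is *defined* as stopping divided by the mean
transfer, so the identity
$\mathrm{IMFP} \times \langle t \rangle = S$ holds exactly at every grid
point, for the packaged table and for any user table loaded from TSV (the
loader re-solves $t_{\min}$ per grid point to preserve it). Tables are
interpolated log–log; queries outside the grid span are an error, never an
extrapolation, because stopping varies over four decades and silent
extrapolation at keV energies would produce nonsense.

# Transport

Ions travel in straight lines (no nuclear scattering, no straggling beyond
collision statistics, no projectile fragmentation). Free paths are
exponential with mean 1/(scaled IMFP); each collision deposits a small
fixed share (15 eV) at the collision point and hands the remainder to a
secondary-electron kernel that drops it in ~40 eV chunks along a straight,
forward-biased path of exponential length with scale
$0.05\,(E_e/1\,\mathrm{keV})^{1.7}$ μm, capped at 5 μm. A continuous
residual closes any interpolation gap between the discrete losses and the
scaled stopping, and rates are evaluated at the anticipated mid-chunk
energy so the mean energy loss per unit path reproduces the scaled
stopping power within the 2% transport tolerance at all supported energies.
Tracks end below 0.01 MeV/u (the remaining energy is deposited at the
endpoint) or on leaving the 14.22 μm scoring sphere. Energy is conserved
per track to numerical precision; the kernel constants are tuning knobs of
a declared surrogate for full electron transport, documented, not claimed.

The deterministic range integrates $dE/dx = -S$ on a fine log grid. The
default range rule (`extrapolate10`) locates the depth at which the energy
has fallen to 10% of its initial value and extrapolates linearly to zero
along the local slope, which avoids the poorly known lowest-energy region;
`csda` integrates to the table floor.

# Irradiation geometry and LET

Each run rotates an 80 μm² circular source, tangent to the 10 μm nucleus,
by a uniform random 3D rotation, and starts 5 ions exactly parallel from
uniform positions on the disc — a planar fluence of 0.0625 μm⁻² per run.
LET is scored from dose and fluence,
$\mathrm{LET} = D / (0.1602\,\varphi)$, with dose from all deposits inside
the nucleus. For stoppers (range shorter than the nucleus diameter) the
reference volume is the spherical cap of height equal to the range. For
0.25–0.5 MeV/u ions the depth dependence is resolved in 50 slabs of
200 nm; slab volumes are the slab–sphere intersections, and slab doses use
the run fluence (stoppers stop contributing below their stopping depth).
Because the integral of track chord lengths over the source plane equals
the slab–sphere volume, slab LET recovers the local stopping power in
expectation for a parallel beam — verified against the deterministic
slowing-down curve in the tests. Energy deposited outside the nucleus but
inside the scoring sphere is tracked yet excluded from dose, so at high
energy the LET sits below the stopping power (electrons carry energy out;
no electronic equilibrium is established with a tangential source).

# Chromatin target and break induction

The genome (default 6.4 Gbp, diploid, 46 chromosomes with
human-proportioned lengths) is laid out as a randomized lattice walk on a
50 nm grid inside the nucleus, 5500 bp per voxel — the midpoint of the
5–6 kbp chromatin-fiber content the voxel stands for. Walks are
self-avoiding in the sense that each voxel is claimed once; when locally
trapped the walk re-attaches at a free voxel, which plays the role of a
loop returning to the nuclear matrix. Loop (~100 kbp) and 1 Mbp domain
boundaries are bookkept. At full scale the genome occupies ~28% of the
sphere's voxels. Sub-voxel genomic coordinates come from projecting a
position onto the walk direction, and the strand from the side of the walk
axis, so spatial proximity maps to genomic proximity deterministically —
the correlation the 10/25 bp classification rules need.

Break induction has three routes:

* **Direct**: a deposit in a chromatin voxel hits a sugar-phosphate group
  with probability `f_dna` (default 0.017); energies accumulate per group
  per exposure, and the group breaks with probability rising linearly from
  0 at 5 eV to 1 at 37.5 eV.
* **Indirect**: non-DNA deposits spawn a hydroxyl-radical surrogate with
  probability `p_oh` (0.35) that walks isotropically (4 nm steps, at most
  120 — the scavenging lifetime), reacts with deoxyribose in a chromatin
  voxel with probability `p_deoxy` (6.5×10⁻⁴ per step), and 65% of those
  reactions break the strand. At most `k_max` (12) radicals per voxel and
  track survive, a surrogate for radical–radical recombination in dense
  track cores that drives the high-LET decline of indirect damage.
* **Conversion**: every break independently gains an opposite-strand
  partner at the same position with probability 1%.

`f_dna` and `p_deoxy` were calibrated once, on a fixed ~1 Gy set of
16 MeV proton deposits, so that sparsely ionizing radiation yields roughly
60 direct and 100 indirect strand breaks per Gy per Gbp (the calibration
reference for the full-physics yields of ~150–170 total SB with >60%
indirect); they absorb the DNA volume fraction, hydration shell, histones
and the whole radiolysis stage, none of which is modelled explicitly.

# Damage classification

The calculus is applied per exposure in a fixed order: (1) breaks on
directly adjacent nucleotides of the same strand merge into one (a break
is individual only if an intact sugar-phosphate group separates it from
the next); (2) DSB are called by greedy nearest-neighbour pairing of
opposite-strand breaks within 10 bp, scanning by ascending position with
lower-position, then plus-strand tie-breaks — the pairing rule itself is a
design choice, since only the 10 bp criterion is physically fixed, and the
tests bound it against the maximum bipartite matching; (3) DSB
representative positions (floor of the pair midpoint) are chained by
single linkage at 25 bp — chains of two or more are DSB clusters, the
rest isolated DSB, and sites = isolated + clusters; (4) the cluster
multiplicity is the mean number of DSB per cluster; (5) single-track
fragments are the gaps between consecutive DSB sites of one track on one
chromosome, binned into 60–100 bp, 0.3–3 kbp, 10–100 kbp, 0.3–3 Mbp and
the PFGE-detectable 5 kbp–6 Mbp window; intra-cluster micro-fragments
(≤25 bp) are tallied separately and never enter those bins. Per-track
scoring matches the low-dose regime in which inter-track fragments are
negligible. Three canonical 7-DSB configurations pin the bookkeeping:
seven mutually distant DSB are 7 sites; two pairs within 25 bp plus three
distant DSB are 5 sites; a chain of seven at 20 bp spacings is one site of
multiplicity 7.

An open corner of the rules: whether a third break within 10 bp of an
existing pair may re-pair with one partner is unspecified; greedy
exclusivity is assumed (the extra break stays an SSB). Cluster chaining
uses representative positions, not closest member breaks.

# Experiments, statistics, problem sizes

`runExperiment()` builds the chromatin model once per seed, then loops
runs: rotate, transport, score dose/LET, induce and classify damage.
Reported values are means over runs with twice the standard error of the
mean as uncertainty (a single run reports NA). All randomness flows from
the single configuration seed; identical configurations are bit-identical.
Full-scale conditions are 256–4096 runs and the 6.4 Gbp genome; the test
suite and examples run 2–32 runs on 0.05–1 Gbp genomes and verify the
statistical machinery (1/√n SEM scaling) rather than full-physics yields,
and the transport oracle uses ~3×10⁵ collisions per ion–energy pair.
Because break yields per Gy per Gbp are genome-size-independent in the
linear (low-occupancy) regime, the reduced-genome tests exercise the same
calibration the full genome would.

# What passing tests do and do not show

The synthetic generator and surrogates reproduce the *structure* of the
problem — scaling limits and anchors, transport consistency, the complete
classification calculus, geometry and normalization arithmetic — under
exactly the stated study conditions. They do not reproduce the absolute
yield curves of the full-physics code: the atomic-resolution DNA target,
explicit electron transport to 10 eV and the reaction–diffusion chemistry
are all collapsed into a handful of calibrated constants. In particular,
low-LET DSB yields here (~2–3 per Gy per Gbp) undershoot the ~7 of the
full model, because correlated opposite-strand hits from a single electron
spur are only partially represented by the chunked kernel; qualitative
trends (DSB and cluster yields rising with LET, indirect fraction
falling) are reproduced, absolute cluster statistics are not claimed.
Known limitations beyond that: no base damage, no repair, no nuclear
stopping or fragmentation, no charge-state-resolved H/He cross sections,
straight-line transport only.

# Numerical choices

Log–log linear interpolation everywhere on the baseline grid (dense —
100 points per decade — across the Bragg region so argmax queries are not
quantized); hard range errors outside the grid; the 0.01 MeV/u
applicability floor warns rather than stops; ties in DSB pairing break
deterministically (lower position, then plus strand); cluster
representatives are means of member positions; degenerate inputs (no
breaks, empty regions, zero-volume slabs) return empty results or zero
rather than erroring, except per-Gy normalization at zero dose, which is
an error.
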
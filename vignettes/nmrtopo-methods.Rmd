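---
title: "From NMR observables to a membrane-embedded topology: models and design choices"
author: "nmrtopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From NMR observables to a membrane-embedded topology: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrtopo)
```

# The problem

The cytosolic MSP domain of human VAPB folds as a seven-stranded
beta-sandwich. The ALS-linked P56S substitution abolishes that fold; in a
membrane-mimicking DPC micelle the 125-residue mutant domain instead forms
five alpha-helices (residues 3--7, 22--30, 90--94, 98--107 and 116--125)
linked by a long unstructured loop (Gly33--His86), largely embedded in the
micelle. Because such a system yields few long-range NOEs, its
three-dimensional topology must be assembled from indirect observables:
chemical shifts for secondary structure, nitroxide spin-label PREs for
long-range distances, heteronuclear NOE and CPMG dispersion for backbone
dynamics, paramagnetic titrations for solvent accessibility, and
sequence-based amphiphilicity analysis for the partitioning mechanism.
`nmrtopo` implements this whole computational chain, together with forward
simulators that generate every input from a known ground truth, so each
stage has a closed-loop test.

# Secondary chemical shifts and helix calling

For each residue the index is
$(\delta C\alpha_{obs}-\delta C\alpha_{rc})-(\delta C\beta_{obs}-\delta C\beta_{rc})$,
computed against a packaged random-coil table (Wishart-style values,
recorded in the output's `reference_set` attribute and overridable).
Glycine has no C$\beta$, so its index reduces to the C$\alpha$ secondary
shift alone. Sustained positive runs mark helix.

The literature gives no universal numeric rule for calling "large"
values, so the caller exposes three parameters: threshold 1.4 ppm, minimum
length 4, and a tolerated in-run gap of 1 residue (missing assignments and
single outliers should not split a helix). Raising the threshold can only
shrink the called set — a property the tests assert. Strand calling (the
symmetric rule at $-$threshold) exists but is off by default because the
micelle-bound P56S MSP retains no beta structure.

# PRE distance restraints

Spin labels are introduced at seven sites (Q6C, D24C, A53C, N68C, M89C,
M102C, A121C). For each site the paramagnetic/diamagnetic peak-intensity
ratio is converted in two steps:

1. **Ratio to rate.** The attenuation model
   $I_{para}/I_{dia} = R_{2,dia}\,e^{-R_{2sp}t_{INEPT}}/(R_{2,dia}+R_{2sp})$
   is inverted for the unique positive root $R_{2sp}$ (the right side is
   strictly decreasing), by bracketed root finding to 1e-8 relative
   tolerance. An independent bisection oracle checks this in the tests.
2. **Rate to distance.** The Solomon--Bloembergen form
   $d = [K/R_{2sp}\,(4\tau_c + 3\tau_c/(1+\omega_h^2\tau_c^2))]^{1/6}$.

Classification: ratios above 0.85 are unrestrained (peak unaffected);
ratios below 0.15 are treated as vanished and yield an upper bound only,
at the distance corresponding to 0.15; everything between becomes a
bounded restraint $d \pm 4$ Å. The label-site residue itself is excluded.

Defaults that the experiment does not pin down are config-exposed and
deliberately conservative for a protein--micelle complex: $R_{2,dia}=20$
s$^{-1}$, $t_{INEPT}=10$ ms, $\tau_c=15$ ns, $\omega_h$ at 800 MHz, and
$K = 1.23\times10^{16}$ Å$^6$s$^{-2}$, the standard nitroxide--proton PRE
constant. Note that distances scale only as $\tau_c^{1/6}$, so even a
factor-two error in $\tau_c$ shifts distances by about 12%.

# Backbone dynamics and accessibility

The hNOE is the plain ratio $I_{sat}/I_{ref}$, unclamped because negative
values are physically meaningful (large-amplitude fast motions). CPMG
dispersion uses the constant-time relation
$R_{2,eff}=-\ln(I(\nu_{CPMG})/I_0)/T_{CP}$ with $T_{CP}=50$ ms and the
40--960 Hz frequency schedule (120 Hz in duplicate; repeats are averaged
on the intensity scale before conversion). The exchange indicator is
$\Delta R_2 = R_{2,eff}(80\,\mathrm{Hz})-R_{2,eff}(960\,\mathrm{Hz})$ with
two flag tiers at 2 and 6 s$^{-1}$. No Carver--Richards fitting is
attempted: single-field dispersion data cannot constrain the exchange
parameters reliably, so the package only flags exchange.

Accessibility uses two titrants: gadodiamide stays in bulk water, Mn$^{2+}$
also partitions into the phosphocholine head-group layer. A residue
attenuated by gadodiamide (endpoint ratio below the 0.5 default cutoff) is
water-exposed regardless of Mn$^{2+}$ (precedence rule); Mn$^{2+}$-only
attenuation means head-group layer; neither means buried in the
hydrocarbon phase or hydrogen-bond protected.

# Amphiphilicity

Three packaged scales: Kyte--Doolittle (general hydropathy),
Goldman--Engelman--Steitz transfer free energies (transmembrane
detection, 19-residue window, mean $\ge 1.0$ kcal/mol per residue), and
the Eisenberg consensus scale for hydrophobic moments
$\mu_H = |\sum_n H_n e^{in\delta}|$ with $\delta = 100^\circ$/residue,
reported per residue ($\mu_H/N$, 11-residue window) so different window
lengths are comparable. The per-residue normalization is a package
decision; the alternative (total moment) changes only the scale of the
profile, so tests assert ordinal and positional claims, not axis values.

The amphiphilic-segment threshold of 0.35 on $\mu_H/N$ was calibrated once
so the detected segment structure of the P56S MSP domain reproduces the
known amphiphilic regions (helix 2 around 22--32, the 53--63 stretch, and
the C-terminal helix 116--125); it is config-exposed. Profile comparison
reports a profile-level verdict and per-segment verdicts against a
reference peptide's peak moment (fraction `f = 0.9` by default). Under the
packaged Eisenberg scale the MSP segments reach 70--85% of melittin's peak
moment, so at the default `f` the per-segment verdict against melittin is
negative; the regression tests freeze these computed fractions rather
than forcing a verdict.

The packaged MSP sequence (residues 1--125 of human VAPB) is pinned by
more than thirty residue-specific positions quoted in the study design
(mutation sites, helix boundaries, native cysteines), all of which match.
The full-length 243-residue construct is explicitly synthetic beyond
residue 125 — a polar linker plus an idealized 21-residue transmembrane
anchor — and is used only for the qualitative claim that transmembrane
propensity lives C-terminal of the MSP domain while no window inside
1--125 reaches the transmembrane threshold.

# Geometry engine

**Superposition** is closed-form least squares (Kabsch via SVD) with the
proper-rotation correction; a degenerate (collinear) selection is an
error. **Ensemble RMSD** offers two conventions, because published
"average RMS deviation" numbers may reflect either: (i) iterative
superposition of all models onto the evolving mean over the fit selection
(to mean-shift $<10^{-6}$ Å), then the average RMSD to the mean over the
reporting atom class; (ii) the average over all model pairs. Atom classes
are backbone (N, CA, C, O), heavy (non-hydrogen) and all.

**Restraint violation scoring** uses the C$\alpha$--C$\alpha$ distance as a
proxy for the label--amide distance and widens bounds by 3 Å to absorb
the MTSSL linker, which the restraint conversion itself does not model.

**Topology reconstruction** is a deliberately lightweight stand-in for an
all-atom simulated-annealing structure calculation, operating on a
C$\alpha$ chain. The energy is a sum of flat-bottom restraint wells,
chain-connectivity terms (target 3.8 Å), and helix-geometry terms
($i,i{+}3 \approx 5.1$ Å, $i,i{+}4 \approx 6.2$ Å inside declared
helices); undeclared regions, such as the long 33--86 loop, carry chain
terms only. Bounded restraints additionally contribute a weak harmonic
pull (relative weight 0.2) toward the converted distance: the wells alone
admit a feasible set several Å across, and the pull selects its most
probable point without materially penalizing any zero-violation
structure. Minimization is simulated annealing (single-bead Gaussian
moves, geometric cooling from $T_0=50$ to $10^{-2}$ over 50,000 steps per
restart, 10 restarts) followed by an L-BFGS-B polish on the same surface;
all randomness flows through R's RNG, so a seed fixes the result exactly.

Distance information cannot fix chirality, so any reconstruction and its
mirror image are equally valid; recovery metrics therefore always take
the minimum over the model and its inversion (`ca_rmsd_to(...,
mirror_correct = TRUE)`).

When scoring or reconstructing against *simulated* PREs, the bound
widening is set to zero: the simulator places the label at the site
C$\alpha$, exactly matching the analysis-side proxy, so there is no
linker offset to absorb.

# The synthetic-data generator

`make_bundle()` builds the study-shaped truth: five ideal helices
(rise 1.5 Å, 100°/residue, consecutive C$\alpha$ distance exactly 3.8 Å)
arranged antiparallel on an 8.5 Å circle, joined by bond-equilibrated
random loops, 125 residues carrying the P56S MSP sequence. Rigidity
classes follow the helix/loop partition; burial-depth classes are
assigned from the depth coordinate with the study fractions (17
water-exposed, 30 head-group, remainder buried out of 125).

Forward models are the exact inverses of the analysis operations, so the
noise-free closed loops are identities: shifts (random coil + 3 ppm
helical offset, split 2:1 between C$\alpha$ and $-$C$\beta$; glycine all
on C$\alpha$), PREs (true distance → rate → ratio, log-normal diamagnetic
intensities, multiplicative noise), CPMG (Luz--Meiboom fast-exchange
closed form, which doubles as the flagging oracle; Carver--Richards is
deliberately out of scope since single-field data cannot discriminate
regimes), hNOE (class means: micelle preset 0.95 rigid / 0.60 flexible,
which reproduces the study's 0.71 overall and 0.6 loop averages given 39
helix and 86 loop residues; water preset mean 0.08 with spread enough for
negative N-terminal values), and titration ratios (attenuated classes
centred at 0.25, unattenuated at 0.80).

What the generator does **not** emulate: spectral overlap and missing
assignments, a flexible label linker ensemble, differential line
broadening, micelle geometry, and NOESY spectra. Passing closed-loop
tests therefore demonstrates internal consistency of the computational
chain at realistic noise, not robustness to every pathology of real
spectra.

# Problem sizes and numerical choices

Tests and the acceptance script run the full 125-residue system for
analysis stages; reconstruction benchmarks use 10 restarts × 50,000 steps
per seed (about 5 s per seed on one core), five seeds for the recovery
experiment, and 200--300 replicates for flagging-specificity estimates —
sizes chosen so the whole suite completes in well under its budget while
keeping Monte-Carlo noise far from the asserted margins. Root finding is
bracketed (`uniroot`) with relative tolerance 1e-8; the forward/inverse
PRE round trip is verified to 1e-6 over $R_{2sp}\in[1,200]$ s$^{-1}$.
Degenerate inputs are contracts, not crashes: empty shift files parse to
empty tables with a warning, vanished CPMG peaks become `NA` rates,
missing titration residues are `unobserved`, and a reconstruction with no
long-range restraints runs but is flagged low-confidence.

# Known limitations

* The deposited 10-model ensemble of the micelle-bound P56S MSP domain
  (PDB 2MDK) is not shipped; `fetch_pdb("2MDK")` retrieves it when the
  network is available, and the ensemble-statistics checks run against
  the live download.
* The C$\alpha$ reconstruction resolves topology (helix packing and
  orientation), not atomic structure; 2--4 Å C$\alpha$ RMSD over helices
  is its designed resolution.
* PRE conversion assumes a single effective correlation time and a rigid
  label at the backbone; both idealizations bias distances for highly
  mobile sites.
* Exchange flagging is qualitative by design; quantitative exchange
  parameters require multi-field data.
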
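---
title: "Rigid-base shape and nonlocal stiffness of nucleic acid duplexes"
author: "duplexmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-base shape and nonlocal stiffness of nucleic acid duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexmech)
```

## The model

`duplexmech` treats a DNA or RNA double helix as a chain of rigid bases. The
configuration of an N-bp duplex is the coordinate vector `w` of length
12N - 6: six intra-basepair coordinates per pair (shear, stretch, stagger,
buckle, propeller, opening) interleaved with six step coordinates per step
(shift, slide, rise, tilt, roll, twist), ordered pair 1, step 1, pair 2, ...,
pair N. Translations are in Angstrom, rotations in degrees.

The free-energy cost of a deformation is harmonic,

    E = 1/2 (w - what)' K (w - what),

where `what` is the equilibrium (ensemble-mean) coordinate vector and the
stiffness matrix is the inverse covariance scaled by thermal energy,
`K = kBT Sigma^-1` (kBT = 0.59616 kcal/mol at 300 K). Both `what` and `K` are
sequence-dependent, and the model's central assumption is that this dependence
is captured by a *hexameric* context for steps and a *heptameric* context
(the average of two overlapping hexamers) for pairs:

* step j of a sequence takes the central-step parameters of the hexamer
  spanning pairs j-2..j+3; the major groove width (a P-P distance across the
  hexamer's 5' ends) is assigned to the same central step;
* pair j takes the central-pair parameters of the heptamer spanning pairs
  j-3..j+3, computed as the arithmetic mean of the 4th-pair and 3rd-pair
  values of its two constituent hexamers; the minor groove width (P-P distance
  at the 3' ends of a pentamer inside that heptamer) is assigned to the
  central pair.

A sliding window therefore leaves three pairs at each end uncovered. Uncovered
positions are reported as `NA` and never silently filled;
`predictProfile(..., fillEnds = TRUE)` substitutes the parameter set's
sequence-averaged values behind that explicit flag.

### Strand symmetry

On a double helix a hexamer and its reverse complement are the same physical
context read from the other strand. Under a reference-strand flip the *odd*
coordinates (shear, buckle, shift, tilt, Y-disp, tip) change sign while all
others - including groove widths and every stiffness constant - are even.
A hexamer record transforms by reversing the pair and step order, negating
odd coordinates, and transforming the 66x66 stiffness block by the signed
permutation that reverses the eleven coordinate sextets and flips odd-even
couplings. The transform is orthogonal (an involution preserving symmetry,
definiteness and the spectrum), so only the 2080 canonical hexamer classes are
ever stored; complements are always derived. For self-complementary hexamers
the transform maps the record onto itself, which forces the odd central-step
coordinates to exactly zero and the block to be complement-invariant; the
package stores literal zeros there, not approximate ones.

### The nonlocal banded stiffness matrix

The stiffness matrix of an arbitrary sequence is assembled from precomputed
66x66 hexamer blocks (6 pairs + 5 steps per window): each window's block is
placed at its position along the diagonal, entries covered by several windows
(up to six) are arithmetic means of the contributing blocks, and entries
outside the union of windows are exactly zero. Hexameric blocks couple
coordinates up to five steps apart - empirically the minimum range needed to
keep truncated stiffness matrices positive definite (a band of two or three
off-sextets is provably indefinite for strongly coupled helices; see the
band-truncation test).

Averaging independent SPD blocks does not guarantee an SPD result: a few
assembled matrices have near-zero or slightly negative eigenvalues, usually in
very soft buckle-dominated modes. The repair is spectral: the matrix is first
nondimensionalized (entry (i,j) multiplied by scales s_i s_j with s = 1 A for
translations and 11 deg for rotations, so everything is in kcal/mol), then all
eigenvalues below a cutoff lambda_c are raised to lambda_c with eigenvectors
untouched, and the matrix is redimensionalized. The defaults are
lambda_c = 0.48 (DNA) and 0.44 (RNA); the cutoff is the model's single
adjustable parameter and is deliberately insensitive. The 11-degree angle
scale is the twist density common to B-DNA (360/34 A = 10.6 deg/A) and A-RNA
(360/32 A = 11.3 deg/A), rounded to one convenient value. After the repair the
matrix is no longer banded; by default it is re-trimmed to the hexameric band
(`trim = FALSE` disables this), since the out-of-band entries created by the
repair are mostly noise. We apply the cutoff per assembled sequence and
redimensionalize before any energy or sampling use, for unit consistency.

### Estimating blocks from ensembles (maximum-entropy banding)

Given a coordinate ensemble (e.g. an MD trajectory), `estimateMeanCov` gives
the sample mean and covariance, and `bandedMaxentStiffness` constructs the
banded precision matrix whose implied covariance agrees with the sample
covariance on *every in-band entry*: invert each diagonal 66x66 covariance
block and add it at its position, then invert each 54-coordinate covariance
block of adjacent-window overlaps and subtract it, and multiply by kBT. This
is the maximum-entropy completion of a decomposable Gaussian model whose
junction tree has the hexamer windows as cliques and their overlaps as
separators; the in-band reproduction is exact for any SPD input (tested to
1e-8), and if the true precision is already banded it is recovered exactly.
`extractHexamerBlocks` then cuts the hexameric blocks out (first occurrence
wins for duplicated windows, with the deviation between duplicates reported as
a consistency diagnostic), and reassembly reproduces the source banded matrix
exactly - except at self-complementary windows, where the zero rule for
odd-even entries symmetrizes the extracted block first.

Snapshots enter the estimation only if no Watson-Crick hydrogen bond in the
central part of the duplex is broken (heavy-atom distance > 4 A); the outer
cap pairs are ignored. Base-pair opening itself is analysed from the excluded
events: maximal runs of open snapshots give event durations, the survival
function S(t) is their exceedance fraction, and the mean opening time is
tau_open = -1/slope of a straight line fitted to ln S(t). Because the
empirical ln S(t) has variance ~ (1 - S)/(N S), the fit is weighted by the
inverse of that variance - an unweighted fit lets the noisy tail dominate.
The fit window is user-specified or auto-selected as the widest interval whose
weighted fit reaches R^2 >= 0.99; auto-selection is a heuristic and is flagged
in the result.

### Global elasticity

At the rod level the global length l is the sum of helical rises and the
global twist omega the sum of helical twists (radians). Helical rise and twist
come from the mid-step triad convention: the step rotation is
Rz(twist/2 - phi) Ry(Gamma) Rz(twist/2 + phi) with Gamma = sqrt(tilt^2 +
roll^2) and phi = atan2(tilt, roll); the helical twist is its total rotation
angle and the helical rise the displacement projected on the rotation axis
(when the angle vanishes the axis is undefined and the documented limit is
h-twist = 0, h-rise = displacement along the mid-step normal).

From fluctuations of (l, omega) over an ensemble:

* stretch modulus `Y = kBT l0 / var(l)` (pN),
* twist stiffness `C = l0 / var(omega)` (reported in nm),
* twist-stretch coupling `k = cov(l, omega)/var(omega)`, reported in nm/turn
  via the factor pi/5 (A/rad x 2 pi rad/turn / 10 A/nm); positive k means
  overtwisting lengthens the helix,
* the 2x2 material stiffness `Krod = kBT l0 Sigma_rod^-1`, whose l0 factor
  makes the entries material constants rather than length-dependent apparent
  stiffnesses.

The dynamic bending persistence length l_d comes from directional
correlations of base-pair normals with the static structure factored out:
`<t_i . t_0> / (that_i . that_0) = alpha_d exp(-l_i0 / l_d)`, fitted on a
semilog plot against the mean contour distance l_i0, by default over pair
separations i = 1..24 (configurable); the prefactor alpha_d absorbs a
non-zero intercept. The twist persistence length uses
`<cos(omega_i - <omega_i>)> = alpha_tw exp(-l_i0 / l_tw)` analogously. For an
intrinsically straight, homogeneous, isotropic rod C = l_tw / 2; the package
recovers that identity within Monte Carlo error. Static (sequence-disorder)
persistence lengths treat the predicted equilibrium structures of random
sequences as snapshots of a virtual ensemble, with the sequence-averaged
structure as the reference; the same fits and the same prefactor convention
are applied.

Length-scale profiles follow the fragment procedure: every contiguous
fragment (2 bp up to full length, every start offset) of every snapshot
contributes its own (l, omega), constants are computed per fragment length
and offset and averaged over offsets.

Template threading reduces the model to a constrained subset of step
coordinates (by default roll, twist and slide, the step coordinates most
conserved across nucleosome structures) via the Schur complement
`K_cc - K_cf K_ff^-1 K_fc` - the partially relaxed stiffness in which all
other coordinates adopt energy-optimal values - and scores
`1/2 delta' K_eff delta` for each placement of the template along the covered
region.

## Sequence design

`minimalCoveringSequence(k, seed)` searches depth-first for a sequence in
which every reverse-complement k-mer class appears exactly once, counting both
strands. There are 4^k/2 classes for odd k and (4^k + 4^(k/2))/2 for even k
(512 pentamer classes, 2080 hexamer classes). For odd k no k-mer is
self-complementary and the backtracking search finds an optimal sequence of
length 4^k/2 + k - 1 in well under a second (516 bp for k = 5). For even k
self-complementary classes make the search tree unfavourable; the designer
falls back to a duplication-tolerant greedy walk and reports the duplicated
classes - optimal even-k design is out of scope. Traversal order is
randomized by the seed with deterministic tie-breaking, so designs are
reproducible. `partitionIntoOligomers` tiles a designed sequence into cores
overlapping by k - 1 (the last core right-aligned so no window is lost), caps
each core with GCGC to isolate end fraying, and the census utilities verify
that no k-mer window is gained or lost except the double-counts inside the
k - 1 overlaps. Caps are excluded from census and model fitting.

## The synthetic parameter generator

The package never downloads the published parameter deposit; instead
`generateSyntheticParameters(seed, naType)` produces a schema-identical,
complete parameter set so every downstream module is testable offline:

* central-step means are anchored to MD-derived dinucleotide equilibrium
  values (`dimerAnchorTable("DNA")`) plus a per-hexamer context perturbation
  drawn at the printed dinucleotide variability scale and truncated at two
  standard deviations, so hexameric context effects stay within the observed
  range (a few degrees in twist); for RNA the anchors are the DNA ones shifted
  by the difference of the sequence-averaged A-RNA and B-DNA step coordinates,
  with odd coordinates and spreads scaled by the corresponding variability
  ratios - our own construction, chosen because the generator must emulate an
  A-form helix without access to RNA dinucleotide tables;
* intra-basepair coordinates and groove widths are anchored to
  sequence-averaged helix values (e.g. DNA minor groove 12.04 +/- 0.89 A,
  major groove 18.36 +/- 0.61 A);
* per-coordinate stiffness constants are drawn log-normally (20% spread)
  around physically sensible baselines (soft buckle ~ 0.008 kcal/mol/deg^2,
  stiff stretch ~ 25 kcal/mol/A^2, twist ~ 0.055 kcal/mol/deg^2);
* each 66x66 block is built SPD by construction: a banded unit-diagonal
  random factor (couplings decaying over ~ one pair-step sextet pair, i.e. a
  dimeric correlation range inside the block) gives a correlation matrix that
  is then scaled to per-coordinate diagonal magnitudes about 2.5x the marginal
  constants;
* self-complementary hexamers are exactly symmetrized (record averaged with
  its complement transform, making the odd central-step coordinates literal
  zeros and the block complement-invariant); complements are never drawn
  independently.

Everything is drawn from one seeded stream in a fixed class order, so two runs
with the same seed are byte-identical.

What the generator does *not* emulate: real sequence-specific correlation
structure between neighbouring contexts, anharmonicity, rare noncanonical
states, and the actual MD-derived magnitudes of couplings. Passing tests on
synthetic parameters therefore demonstrates the correctness of the machinery
(transforms, assembly, banding, estimators, fits) - not the biophysical
accuracy of any particular parameter value, which requires the MD-derived
deposit.

## Numerical choices and problem sizes

* The eigenvalue cutoff is applied on the nondimensionalized matrix and the
  result is redimensionalized before use; trimming back to the band is on by
  default.
* "Exact zero" rules (odd coordinates of self-complementary contexts, entries
  outside the band) are literal zeros, not tolerances.
* Monte Carlo test sizes were chosen so the full suite runs in minutes on one
  CPU: rod ensembles of 1e5 snapshots x 25 steps for the closed-form
  recoveries, 5e4 snapshots for the end-to-end parameter recovery at 8 bp,
  3e3 virtual sequences for static disorder. At these sizes Monte Carlo
  standard errors (estimated from disjoint batches) are ~0.5% and the
  recovery checks use 3-SE bands.
* The homogeneous-rod closed forms l_d = 2h/(sd_tilt^2 + sd_roll^2) and
  l_tw = 2h/sd_twist^2 are leading small-angle orders. At sd = 0.05 rad the
  exact i.i.d. decay - E[cos Gamma]^i against the mean helical rise, with
  E[cos Gamma] computed by quadrature over the Rayleigh bend-angle
  distribution - sits about 1.3% below the leading order (the helical rise is
  shortened by the axis projection, and E[cos Gamma] carries an O(sigma^4)
  term). The tests therefore check the exact oracle sharply (3 MC SEs) and
  the leading-order value at the size of its known correction.
* Semilog persistence fits are unweighted least squares over i = 1..24 by
  default (configurable); non-positive correlation ratios are excluded with a
  warning, and a non-decaying ordinate yields an unbounded persistence length
  rather than an error.
* Degenerate inputs: sequences shorter than 6 bp are refused; 6-bp input
  yields step-level output only (with a warning); singular covariances are
  reported and the per-coordinate constants are still returned; a singular
  free block in the Schur complement is an error.

## Known limitations

* Context effects beyond the hexamer/heptamer window are not representable;
  no banded-inverse (cgDNA-style) long-range propagation is implemented, by
  design.
* Phosphate rigid bodies, multistate/Ising descriptions and backbone torsions
  are out of scope.
* The assembled stiffness of sequences containing self-complementary windows
  is reproduced from extracted blocks only up to the symmetrization those
  windows require.
* Groove-width stiffness constants are treated as even scalars under
  complementation (re-indexed, never sign-flipped); nothing in the model
  suggests any other transform.
* At desk scale the absolute material constants of real DNA and RNA are not
  reproducible - they require the MD-derived parameter deposit; the package's
  tests validate machinery, symmetries and estimator consistency instead.
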
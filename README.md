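# duplexmech

Sequence-dependent shape and nonlocal harmonic stiffness of DNA and RNA
double helices at the hexanucleotide scale.

## What it is for

The three-dimensional shape and the deformability of double-stranded DNA and
RNA depend on the base sequence, with consequences from protein binding and
nucleosome positioning to nanostructure design. `duplexmech` implements a
transparent rigid-base model of that dependence for structural
bioinformaticians and biophysicists: given a parameter table of hexameric
contexts, it predicts for an arbitrary sequence

* the equilibrium intra-basepair, step and groove-width profiles
  (hexameric/heptameric sliding window),
* per-coordinate stiffness constants `k_x = kBT / var(x)`,
* the full nonlocal stiffness matrix `K = kBT Sigma^-1`, assembled from
  overlapping 66x66 hexamer blocks (arithmetic means on overlaps, zero outside
  the hexameric band), repaired by an eigenvalue cutoff
  (`lambda_c` = 0.48 DNA / 0.44 RNA, applied on the nondimensionalized matrix
  with scales 1 Angstrom / 11 degrees),

and derives from the quadratic energy `E = 1/2 (w - what)' K (w - what)`
global material constants (stretch modulus `Y = kBT l0 / var(l)`, twist
stiffness `C = l0 / var(omega)`, twist-stretch coupling
`k = cov(l, omega) / var(omega)` in nm/turn), bending and twist persistence
lengths from `<t_i . t_0>/(that_i . that_0) = alpha_d exp(-l_i0/l_d)` and
`<cos d omega_i> = alpha_tw exp(-l_i0/l_tw)`, static-disorder persistence
lengths, fragment length-scale profiles, and partially relaxed
(Schur-complement) template threading energies.

The estimation direction is also implemented: from a coordinate ensemble it
filters snapshots by the 4-Angstrom hydrogen-bond rule, estimates means and
covariances, constructs the maximum-absolute-entropy *banded* stiffness matrix
(in-band covariance reproduced exactly), cuts out hexameric blocks, checks
duplicate-context consistency and convergence, and fits base-pair opening
lifetimes from the survival function (`tau_open = -1/slope` of `ln S(t)`).

A depth-first-search sequence designer produces minimal sequences containing
every reverse-complement k-mer class exactly once (516 bp for all 512 pentamer
classes) and partitions them into GCGC-capped oligomers, and a synthetic
parameter generator emits complete, schema-identical parameter sets so the
whole pipeline runs and is tested without any external download.

## Worked example

```r
library(duplexmech)

ps <- generateSyntheticParameters(seed = 1, naType = "DNA")
ps
#> ParameterSet (DNA): 2080 canonical hexamer classes
#>   source: synthetic
#>   seed: 1

## minimal pentamer-covering sequence
d <- minimalCoveringSequence(5, seed = 1)
d$length                      # 516
all(d$census == 1)            # TRUE: every one of the 512 classes exactly once

## shape profile across an A-tract
prof <- predictProfile("GCGCAAAAAAAATTTTGCGC", ps)
round(stepProfile(prof)[8:11, ], 2)
#>      shift slide rise  tilt roll twist
#> [1,] -0.48 -0.38 3.37 -2.29 1.62 37.35
#> [2,] -0.48 -0.38 3.37 -2.29 1.62 37.35
#> [3,] -0.55 -0.01 3.30 -2.85 0.03 35.34
#> [4,] -0.39 -0.02 3.27 -1.98 3.23 34.90
round(prof@minorGroove[8:11], 2)
#> 12.76 12.76 11.97 12.64
```

Steps 8 and 9 sit in identical AAAAAA contexts, so their predicted
coordinates are identical; the minor groove narrows where the heptamer
window is most A/T-rich. Sampling the model's Gaussian ensemble yields the
global mechanics:

```r
model <- buildDuplexModel("GCGCATTTACGGATCCAGTACGCAT", ps, trim = FALSE)
X <- sampleModelEnsemble(model, 20000, seed = 2)
arr <- stepCoordinateArray(X, 25)
bt <- duplexmech:::.batchTrajectories(arr)
materialConstants(rowSums(bt$hRise), rowSums(bt$hTwist))
#> GlobalElasticRecord (n = 20000 snapshots)
#>   l0 = 78.81 A, omega0 = 14.3993 rad
#>   stretch modulus Y = 3538 pN
#>   twist stiffness C = 248.0 nm
#>   twist-stretch coupling k = -0.062 nm/turn
```

`l0` is the mean global length (sum of helical rises) and `omega0` the mean
global twist in radians; `Y`, `C` and `k` are the fluctuation-derived material
constants of the 25-bp duplex under the synthetic parameter set (synthetic
blocks are stiffer and less coupled than MD-derived ones, so these numbers
characterize the machinery, not real DNA). The bending persistence length
comes from the normal-correlation decay with the static structure factored
out:

```r
eq <- matrix(model@what[as.vector(sapply(1:24, duplexmech:::stepIndices))],
             24, 6, byrow = TRUE)
bendingPersistence(arr, eq)
#> PersistenceFit (dynamic-bend): 142.6 nm, alpha = 0.9991, R^2 = 0.9995
```

A command-line front end wraps the same functions
(`design`, `census`, `gen-params`, `predict`, `stiffness`, `energy`,
`mechanics`, `persistence`, `thread`, `analyze`):

```sh
Rscript exec/duplexmech design --k 5 --seed 1 --out pent      # FASTA + census TSV
Rscript exec/duplexmech gen-params --seed 1 --out params
Rscript exec/duplexmech predict --params params --seq GCGCATTTACGG --out profile.csv
```

## Parameter CSV layout

`writeParameterSet()` / `loadParameterSet()` use a directory of plain CSV
tables, one row per value, canonical hexamer classes only (complements are
derived by the parity transforms, and inconsistent hexamer/complement pairs
are rejected at load):

* `shape.csv` - `sequence, postype (pair1..pair6 | step1..step5), coordinate,
  mean, kx`
* `grooves.csv` - `sequence, groove (major|minor), position (step3 | pair3 |
  pair4), width, kx` (the two minor-groove rows per hexamer are the widths of
  its two pentamer centres, from which heptamer values are averaged)
* `blocks.csv` - `sequence, i, j, value` (upper triangle of each 66x66 block)
* `metadata.json` - `na_type`, `seed`, provenance

Units are Angstrom, degrees and kcal/mol throughout.

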
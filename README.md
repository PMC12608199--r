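# hpfold

Exact thermodynamics and folding kinetics of HP protein chains on the
simple cubic lattice.

Small proteins fold to a unique native structure, and the simplest model
that captures the competition behind that process is the HP model: a
self-avoiding walk of hydrophobic (H) and polar (P) beads whose energy is a
sum over nonconsecutive nearest-neighbour contacts,
`E = sum eps(Ai, Aj)` with `eps_HH < eps_HP < eps_PP < 0` (default
`-10, -6, -3`).  With integer contact energies the partition function is a
polynomial in `x = exp(1/kT)`,

    Z_N(x) = sum_E n(E) x^(-E) = n(E0) prod_k (x - x_k),

so its complex zeros `x_k` (Fisher zeros) carry the full thermodynamics.
`hpfold` is for researchers studying lattice-protein thermodynamics and
foldability criteria.  It provides:

* **Exact enumeration** of all conformations of a chain (practical through
  N = 16: ~4.4x10^8 symmetry classes), giving the exact density of states
  `n(E)` under the fixed-first-bond convention (degeneracies 1/4/8 for
  linear/planar/3-D structures, so a unique native structure means
  `n(E0) = 8`).
* **A sequence-space screen** that finds all unique-ground-state
  ("protein-like") sequences of a given length from a single enumeration
  pass — 5,248 of the 65,536 16-mers.
* **Partition-function zeros** at double-double precision, the per-zero
  **heat-capacity decomposition** `C_V = sum_k C_V,k`, and transition
  temperatures: the collapse temperature `T_theta` and folding temperature
  `T_f` are the component-peak positions of the *first zeros* (the zeros
  providing the leading contribution of each transition), with the
  Klimov–Thirumalai foldability measure `sigma = (T_theta - T_f)/T_theta`
  and a crossover score that separates fast folders (group 1) from slow
  folders with metastable-globule crossovers (group 2).
* **Gillespie kinetic Monte Carlo** of the physical small-step dynamics
  (corner flips and 90° end flips, Metropolis rates, exponential waiting
  times), measuring first-passage times from the straight chain to the
  native state and mean-FPT-versus-temperature U-curves.

## Worked example

```r
library(hpfold)

rep <- run_pipeline("HPPHPPPHPHPPHPHP")   # "sequence A", ~30 s (enumeration)
rep
#> <hp_report> HPPHPPPHPHPPHPHP
#>   E0 = -91, n(E0) = 8, degree 91 polynomial
#>   T_theta = 5.876219   T_f = 1.763969   sigma = 0.6998
#>   crossover score S = 0.2693 -> group 1
```

The chain has ground-state energy −91, a unique native structure
(`n(E0) = 8`), collapses at `T_theta ≈ 5.88` and folds at `T_f ≈ 1.76`
(reduced units, `k_B = 1`).  No significant heat-capacity component peaks
between the two transitions (`S = 0.27 < 0.5`), so the sequence is a fast
folder.  The slow folder `HHHHPHHPHPHPHPHP` ("sequence B") gives
`T_theta = 7.512336`, `T_f = 0.758160`, an intermediate ring of zeros and
`S = 0.56` → group 2.

Kinetics, scaled down for a quick look:

```r
curve <- mean_fpt_curve("HPPHPPPHPHPPHPHP", temperatures = seq(3, 7, 0.5),
                        runs = 100, seed = 1)
curve[which.min(curve$mean_fpt), ]
#> <hp_fpt_curve> HPPHPPPHPHPPHPHP (E0 = -91, 1 temperatures, 100 runs each)
#>   temperature mean_fpt   sem n_runs n_censored
#> 3           4   203496 20116    100          0
```

The mean first-passage time is U-shaped in temperature; the optimum lies
between `T_f` and `T_theta` (near 4.0–4.5 for sequence A), and sequence A
folds faster than sequence B at every temperature.

A thin command-line wrapper covers the same operations
(`exec/hpfold dos|screen|zeros|transitions|kmc|pipeline|fixtures`).

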
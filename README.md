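# loopdyn

Conformational-ensemble and dynamics analysis of flexible gating loops in
metalloenzymes.

Many bacterial multicopper oxidases carry a methionine-rich omega loop (a
"Met-loop") that sits over the T1 copper centre and gates substrate access.
Whether such a loop samples *open* or *closed* conformations in solution —
and in what proportions — is invisible to crystallography when the loop is
disordered, but it is encoded in small-angle X-ray scattering (SAXS) data
and in the correlated motions of molecular-dynamics trajectories. `loopdyn`
provides the full analysis chain for this problem, aimed at structural
biologists who have a conformer pool (e.g. from loop modelling), an
experimental SAXS profile, MD trajectory frames, and/or docking pose sets:

* **SAXS layer** — theoretical curves from coordinates via the Debye
  formula, discrepancy scoring, Guinier fits, and P(r) by regularised
  indirect transform;
* **ensemble inference** — open/closed classification of a conformer pool
  by its loop-to-site distance, genetic-algorithm selection of
  subensembles that fit the experimental curve, and a two-state
  population scan;
* **trajectory statistics** — RMSF, principal component analysis of the
  C-alpha covariance, dynamic cross-correlation (DCC);
* **residue networks** — correlation-weighted protein residue networks
  with optimal and suboptimal (Yen k-shortest) communication paths and
  variant-vs-wild-type path-length rankings;
* **structure comparison** — Kabsch superposition/RMSD, minimum
  inter-residue distances, Shrake-Rupley accessible surface area,
  Matthews coefficient;
* **docking geometry** — pose-to-site distance histograms with per-bin
  score summaries;
* **synthetic data** — seeded generators for every input above, each
  returning its planted ground truth, so the whole pipeline is testable
  end to end without any downloads.

## The core model

The scattering of one conformer with atoms at pairwise distances
`r_ij` is evaluated with the Debye formula

    I(s) = sum_i sum_j f_i f_j sin(s r_ij) / (s r_ij)

(the `i = j` terms contribute `f_i^2`, so `I(0) = (sum f_i)^2`).  A
subensemble of `N_se` conformers is scored against an experimental profile
`I_exp` with `K` points by the reduced chi-square

    chi2 = 1/(K-1) * sum_j [ (I_exp(s_j) - mu * I_theo(s_j)) / sigma(s_j) ]^2

where `I_theo` is the (weighted) average curve of the subensemble and the
scale factor `mu = sum(I_exp I_theo / sigma^2) / sum(I_theo^2 / sigma^2)`
is the analytic least-squares optimum.  A genetic algorithm searches
size-`N_se` multisets of the pool minimising `chi2`; conformers are
labelled *closed* or *open* from the distance between the loop's centre of
mass and a site atom (e.g. the T1 copper); and the closed-state population
`f` of a measured profile is read off a scan of `chi2(f)` for the mixture
`f * I_closed + (1-f) * I_open`.

Residue networks follow the WISP convention: nodes are residue centres of
mass, residues within 4.5 Angstrom are connected, and the edge length is
`-ln |C_ij|` with `C_ij` the DCC — the stronger the correlation, the
shorter the edge — so that shortest weighted paths trace putative
allosteric communication routes.

## Worked example

Generate a two-state pool with 70% closed conformers, simulate a noisy
SAXS profile from it, classify the pool, and recover the closed
population:

```r
library(loopdyn)

spec <- toy_protein_spec(closed_distance = 12, open_distance = 24,
                         jitter_sd = 1)
gen     <- make_two_state_ensemble(300, 0.7, spec, seed = 1)
s       <- seq(0.01, 0.4, length.out = 200)
profile <- simulate_saxs_profile(gen$ensemble, s,
                                 noise = noise_model(0.02), seed = 2)

site   <- list(chain = "A", resno = 999, elety = "CU")
d      <- loop_site_distance(gen$ensemble, c(41, 48), site)
states <- classify_states(d)
states
#> <state_labels> 300 conformers: 210 closed / 90 open (boundary 17.95 A)

curves <- pool_debye_curves(gen$ensemble, s)
fit <- population_scan(
  ensemble_average_curve(curves[states$labels == "closed"]),
  ensemble_average_curve(curves[states$labels == "open"]), profile)
fit
#> <population_fit> best closed fraction 0.69 (chi2 = 1.153)
```

The classifier separates the two planted distance modes (12 vs 24
Angstrom from the site; here it matches the generator's ground truth for
all 300 conformers, boundary 17.95 Angstrom), and the population scan
recovers the planted 70% closed fraction as 0.69 with a best chi-square
near 1, i.e. a fit within the simulated 2% noise.

Every stage is also reachable through `run_pipeline()` (one verb per
stage: `simulate`, `saxs-curve`, `saxs-fit`, `classify`, `popscan`,
`rmsf`, `dcc`, `network`, `paths`, `pathdelta`, `dockhist`,
`struct-compare`) with a YAML configuration and a JSON run manifest, or
from a shell via `inst/cli/loopdyn.R`.

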
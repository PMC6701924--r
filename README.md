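# dhfret

Kinetic analysis of Mcm2-7 double-hexamer formation from single-molecule
FRET traces.

During eukaryotic helicase loading, two Mcm2-7 hexamers are deposited
head-to-head on origin DNA and form a double hexamer (DH). In
colocalization smFRET assays this event is visible as a jump in apparent
FRET efficiency,

    E_FRET = I_Acceptor / (I_Acceptor + I_Donor)

between a donor-labeled and an acceptor-labeled Mcm2-7 on the same DNA
spot: from ~0.03 (two separate hexamers) to ~0.6 (wild-type DH) or ~0.47
(the unstable "pseudo-DH" of a double-hexamer-motif mutant). `dhfret`
turns per-frame two-channel intensity traces into:

* time-zero-aligned, outlier-filtered E_FRET records for qualified
  two-hexamer events (automated stand-in for manual spot selection);
* time-evolved 2-D E_FRET kernel densities (bandwidths 5 s / 0.05, each
  2.67 s slice normalized to unit integral) and windowed histograms
  globally fit to two Gaussians with shared peaks and widths;
* a generalized three-state kinetic model — pre-DH, DH (or pseudo-DH), and
  a long-lived non-DH/post-DH trap — fit to the pooled records by
  variational Bayes with pinned state means, yielding rate constants with
  credible intervals and significance calls, initial state fractions,
  decoded per-molecule state paths, sorted rastergrams, and cohort dwell
  statistics.

The two low-FRET states have indistinguishable E_FRET and are separated
purely by their lifetimes; the package's coupled (pooled-transition) fit is
built around exactly that identifiability. A continuous-time Markov-chain
simulator with full ground truth (`simulate_dataset`,
`simulate_efret_records`) makes every stage verifiable without
experimental data.

## Worked example

```r
library(dhfret)

sim <- simulate_efret_records(wt_scheme(), n_records = 100, seed = 1)
fit <- eb_fit_population(sim$records, make_priors(preset = "wt"))
print(fit)
```

```
<population_fit> K = 3 , 100 records
  state means: 0.05595 0.03732 0.6043
  state SDs:   0.1137 0.1014 0.1007
  evidence: 8184.857 after 10 EB rounds (start 1 )
  from to          k_s       ci_low      ci_high significant
1    1  2 2.892152e-03 7.350640e-05 0.0107100992       FALSE
2    1  3 1.818381e-01 1.352680e-01 0.2373992643        TRUE
3    2  1 1.029075e-04 2.605750e-06 0.0003796655       FALSE
4    2  3 1.029075e-04 2.605750e-06 0.0003796655       FALSE
5    3  1 6.407182e-05 1.622297e-06 0.0002363734       FALSE
6    3  2 6.407182e-05 1.622297e-06 0.0002363734       FALSE
```

State 3 is the high-FRET DH state (posterior mean 0.60); states 1 and 2 are
the two near-zero-FRET states. The only significant step is state 1 to
state 3 at 0.18 s^-1 — the pre-DH-to-DH formation step (this cohort was
generated at 0.15 s^-1; the credible interval covers it). All other rates
are flagged not significantly greater than zero, reproducing the
irreversibility of wild-type DH formation.

```r
segs <- segment_paths(decode_states(fit), label_states(fit, "wt"))
cohort_statistics(segs)
```

```
<cohort_stats> n = 100 records
  formed high state: 64/100 (64%), of which 15 already high at frame 0
  never high: 36/100 (36%); re-entries: 0
  co-residence duration: ever-high 252 +/- 29 s, never-high 272 +/- 47 s
```

The cohort was generated with 15% of records already in the DH state at
second-hexamer arrival and a 35% refractory population; zero re-entries
reflect the irreversible formation step. `plot_rastergram(build_rastergram(segs))`
draws the onset-sorted per-molecule state timeline.

The full pipeline (intensity traces -> preprocessing -> histogram fits ->
HMM -> kinetics, with all result tables and a run manifest) runs as

```r
run_pipeline(NULL, stages = "all", out_dir = "wt_run", seed = 1,
             variant = "wt")
```

or from the shell:

```sh
Rscript -e 'dhfret::cli_main()' all --seed 1 --out wt_run --variant wt
```

## Layout

* `R/scheme.R`, `R/simulate.R` — kinetic schemes, emission model, simulator
* `R/trace_io.R` — trace tables, configs, ground-truth sidecars
* `R/preprocess.R` — presence detection, baseline, selection, outliers
* `R/efret_hist.R` — 2-D KDE, windowed histograms, constrained mixture fit
* `R/ebhmm.R` — variational HMM machinery and the coupled population fit
* `R/kinetics.R` — semantic labels, segments, rastergrams, cohort stats
* `R/cli.R` — pipeline orchestration and command-line entry point
* `vignettes/double-hexamer-kinetics.Rmd` — model, assumptions, design
  choices, limitations
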
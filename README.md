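# fdlogic

Facilitated-diffusion kinetics of bacterial promoter occupancy.

Bacterial transcription factors (TFs) reach their operators by facilitated
diffusion — 3D excursions through the cytoplasm alternating with ~90 bp 1D
sliding walks along the DNA. Because each landing scans a window of
neighbouring DNA, the *spacing* of binding sites encodes kinetic logic that
equilibrium thermodynamics cannot express: overlapping sites act as
mutually exclusive **switches**, closely spaced sites for different TFs act
as **barriers** (a bound TF blocks one sliding approach of its neighbour),
and nearby sites for the same TF form **clusters** (molecules shuttle
between sites, but sites also trap each other's searchers).

`fdlogic` is for quantitative biologists who want to simulate and classify
this logic. It models a promoter as a continuous-time Markov chain over
occupancy configurations, with physically derived propensities:

* binding — a geometric search: one round lasts $t_{walk}+t_{3d}$ and hits
  a site with probability $s_{eff}/M$, where the effective catchment
  $s_{eff}$ (= the sliding length $s_l$ for an isolated site) shrinks when
  occupied intervals or empty same-TF traps obstruct a sliding approach;
  $k_{on} = n_{free}\, a\, (s_{eff}/M)/(t_{walk}+t_{3d})$;
* unbinding — a Boltzmann-weighted walk over a restricted region $W$:
  $k_{off} = |W| / (t_{walk} \sum_{i\in W} e^{-\lambda E_i})$, so barriers
  that restrict the walk and empty cluster partners that add a second
  energy well both prolong residence;
* relocation — direct 1D transfer between cluster sites at the reciprocal
  of the exact mean first-passage time of the walk (diffusive $d^2$ law,
  escape from the source well included).

Trajectories come from the exact Gillespie algorithm; ensembles are
seed-reproducible. Analyses include first-arrival distributions and their
bimodality (a built-in, LP-verified implementation of Hartigan's dip test
with bootstrap p-values), first-passage times to the all-bound "AND"
configuration, impulse-response profiles of the central-site-only state,
occupancy fractions, and Fano-factor noise comparisons. An explicit-walker
Monte-Carlo cross-validates the semi-analytical propensities on 1–2 site
systems, and TSV/BED site tables plus a small CLI round out the tool.

## Worked example

The double-sided barrier ABA — two identical outer sites flanking a
central site — at 100 bp vs 0 bp spacing, with 2 copies of the outer TF
(affinity scale 0.33) and 10 copies of the central TF:

```r
library(fdlogic)

far  <- run_ensemble(make_fixture("ABA_far"),  t_max = 20000, n_reps = 400, base_seed = 24)
near <- run_ensemble(make_fixture("ABA_close"), t_max = 20000, n_reps = 400, base_seed = 25)
summarize_times(first_passage_to(far)$first_passage)$mean
#> [1] 1832.727
summarize_times(first_passage_to(near)$first_passage)$mean
#> [1] 3386.154
```

Moving the sites from 100 bp to 0 bp apart slows the formation of the
all-bound AND configuration from ~1830 s to ~3390 s — the barrier effect
delays it by about half a cell cycle (~3000 s), purely through binding
site spacing. Classification and nomenclature:

```r
arch <- make_fixture("AABAA")
architecture_string(arch)
#> [1] "AABAA"
classify_pairs(arch)[1:3, ]
#>   site_a site_b gap relation
#> 1     a1     a2   0  cluster
#> 2     a1     b1  20  barrier
#> 3     a1     a3  40  cluster
```

Different-TF pairs closer than half a sliding length are barriers; same-TF
pairs within that range are clusters, whether or not another site sits
between them.

A shell interface is installed as `fdlogic` (see `exec/`):

```sh
fdlogic simulate --pattern ABA --gap 0 --reps 400 --seed 1 --out runs/aba
fdlogic classify --sites sites.tsv --census-threshold 10 --out runs/census
```

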
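# hashdemux

Demultiplexing, benchmarking and quality control for cell hashing
(hashtag-oligo) data.

## The problem

In multiplexed single-cell experiments, cells from several samples are
tagged before pooling with sample-specific hashtag oligos (HTOs) and
sequenced together. Each droplet then has to be assigned back to its sample
of origin from the HTO count matrix (an `N_HTOs x N_droplets` matrix of
non-negative integers). A droplet with exactly one "positive" HTO is a
**singlet** of that sample; two or more positives make a **doublet**; none
make a **negative** — and the difficulty lies in separating genuinely bound
tags from the ambient background counts present in every droplet.

`hashdemux` implements seven published demultiplexing strategies behind one
interface, plus the machinery to compare them against a known ground truth:

| engine | idea |
|---|---|
| `run_hasheddrops()` | thresholds on ambient-corrected log-fold changes between the top two counts |
| `run_htodemux()` | CLR transform, k-medoids with `k = N_HTOs + 1`, negative-binomial background quantile (0.99) per HTO |
| `run_gmm_demux()` | per-HTO two-component Gaussian mixture on CLR counts, posterior ≥ 0.8 |
| `run_demuxmix()` | per-HTO two-component negative-binomial mixture on raw counts, EM, posterior ≥ 0.9 |
| `run_demultiplex()` | iterative KDE anchors + quantile sweep maximizing the singlet fraction |
| `run_bff()` | KDE valley between the two modes (`raw`), plus bimodal quantile normalization (`cluster`) |
| `run_hashsolo()` | Bayesian comparison of singlet/doublet/negative likelihoods from a pooled noise/signal log-normal mixture, priors (0.75, 0.20, 0.05) |

`run_all()` runs nine configurations (hashedDrops at both the default
`confident_min = 2` and the tuned `0.5`, BFF in both modes).

Benchmarking follows the genetic-ground-truth protocol: for each HTO label
with mapped sample `s`,

```
F = TP / (TP + (FP + FN) / 2)
```

with TP/FP/FN counted over singlet calls against the truth (truth doublets
and negatives called as some singlet count as FP). `benchmark_report()`
adds per-method category proportions and the breakdown of how truth
doublets were called; `qc_density()` / `qc_embedding()` provide the
hashing-quality diagnostics (per-HTO log-count bimodality, PCA/tSNE
embedding). `simulate_experiment()` generates synthetic experiments with
known truth under three quality presets (`high`, `medium`, `low`).

## Worked example

```r
library(hashdemux)

sim <- simulate_experiment(quality_preset("high", n_samples = 8,
                                          droplets = 2000, seed = 1))
sim$counts
#> HashtagCounts: 8 HTOs x 2000 droplets
#> HTOs: HTO01, HTO02, HTO03, HTO04, HTO05, HTO06, HTO07, HTO08
#> total counts: 1184439

res <- run_all(sim$counts)
benchmark_report(res, sim$truth)
#> BenchmarkReport: 9 methods
#>   HashSolo             mean F = 0.999  (singlet 0.85, doublet 0.10, negative 0.05)
#>   demuxmix             mean F = 0.999  (singlet 0.85, doublet 0.10, negative 0.05)
#>   GMM-Demux            mean F = 0.999  (singlet 0.85, doublet 0.10, negative 0.05)
#>   BFF_raw              mean F = 0.999  (singlet 0.85, doublet 0.10, negative 0.06)
#>   BFF_cluster          mean F = 0.999  (singlet 0.85, doublet 0.10, negative 0.06)
#>   hashedDrops          mean F = 0.999  (singlet 0.85, doublet 0.10, negative 0.05)
#>   hashedDrops_tuned    mean F = 0.999  (singlet 0.85, doublet 0.10, negative 0.05)
#>   deMULTIplex          mean F = 0.979  (singlet 0.87, doublet 0.00, negative 0.13)
#>   HTODemux             mean F = 0.973  (singlet 0.81, doublet 0.14, negative 0.05)

qc_density(sim$counts)$bimodal_fraction
#> [1] 1
```

Reading the output: on cleanly bimodal data (all 8 HTOs flagged bimodal)
every method recovers essentially all singlets. The two lower rows show
characteristic behaviours, not bugs: deMULTIplex's singlet-maximizing
threshold sweep converts doublets into singlets (doublet fraction 0), and
HTODemux's fixed 0.99 background quantile lets ~1% of background counts per
HTO cross the threshold, promoting some singlets to doublets. The simulated
truth here is 85% singlets, 10% doublets, 5% negatives.

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "hashdemux.R", package = "hashdemux"))')
Rscript $CLI simulate  --preset high --htos 8 --droplets 5000 --seed 1 --out sim/
Rscript $CLI run       --counts sim/counts --method all --out results.tsv
Rscript $CLI benchmark --results results.tsv --truth sim/truth.tsv \
                       --mapping sim/mapping.tsv --out report.json
Rscript $CLI qc        --counts sim/counts --truth sim/truth.tsv --out qc/
```

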
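# consite

Locate protein–DNA binding sites — and flag those bound **constitutively**
across cell lines — from the centers of ChIP-seq peaks pooled over many
datasets.

## The problem and who this is for

Some transcription-factor binding sites are occupied in essentially every
cell type (CTCF is the classic example); finding them genome-wide requires
integrating peak calls for one protein across tens to hundreds of ChIP-seq
experiments. Motif scanning only works for factors with a reliable PWM and
direct DNA binding, and fixed-width genomic binning suffers boundary and
amalgamation artifacts. `consite` is for computational biologists who have
peak calls (BED/narrowPeak) from multiple cell lines with replicates and
want accurate binding-site locations plus a principled constitutive flag,
regardless of whether the protein binds DNA directly.

## The method

Every peak is reduced to its center `(start + end) / 2`. Per chromosome:

1. **Binary range tree.** Sorted centers are recursively split at the
   midrange `(min + max) / 2`; a split happens only when both children
   would keep centers from strictly more than a cutoff fraction (default
   90%) of all cell lines. Tight multi-cell-line clusters are never cut;
   work drops from `O(N log2 N)` to `sum_i O(N_i log2 N_i)` over terminal
   nodes.
2. **Kernel density estimation.** Within each terminal node, the density of
   peak centers is `f(x) = (1/(N h)) * sum_i K((x - x_i)/h)` with the
   standard Gaussian kernel and bandwidth `h` (default 100 bp).
3. **Mode finding.** All local maxima are found by mean-shift hill-climbing
   from every center, polished with Newton steps and classified by the
   second derivative; local minima between adjacent maxima delimit *modal
   regions* (leftmost to rightmost member center; singleton regions have
   width zero). Each maximum is a candidate binding-site summit.

A region is a **binding site** if some cell line contributes centers from
≥ 2 distinct datasets; it is **constitutive** if the supported fraction of
cell lines strictly exceeds 90% (both cutoffs configurable). A fixed-width
**binning baseline** (`call_binned_sites()`, default 400 bp bins) applies
the same decision rules per bin for comparison, and a synthetic generator
(`simulate_peaks()`) plants constitutive / cell-line-specific / noise loci
with known truth for validation.

## Worked example

```r
library(consite)

sim <- simulate_peaks(tempfile("demo"), n_specific = 30,
                      noise_per_dataset = 100, seed = 1)
calls <- call_binding_sites(sim$manifest, bandwidth = 100)
glance(calls)
#> # A tibble: 1 × 10
#>   n_centers n_nodes n_regions n_sites n_constitutive method bandwidth ...
#> 1      3340      70      1281     128             50 kde          100

score_recovery(sim$truth, calls, match_radius = 100)
#> # A tibble: 1 × 7
#>   n_truth n_calls n_matched recall precision median_distance max_distance
#> 1      50      50        50      1         1            3.91         11.2

bins <- call_binned_sites(sim$manifest, bin_width = 400)
score_recovery(sim$truth, bins, match_radius = 400)
#> # A tibble: 1 × 7
#>   n_truth n_calls n_matched recall precision median_distance max_distance
#> 1      50      41        41   0.82         1              97          159
```

Reading: 3,340 pooled peak centers were partitioned into 70 terminal nodes
yielding 1,281 modal regions; 128 passed the replicate filter as binding
sites, of which exactly the 50 planted constitutive loci were flagged
constitutive (recall and precision 1.0, median summit error 3.9 bp). The
400 bp binning baseline on the same input loses 9 of 50 loci to
bin-boundary splitting and localises the rest only to ~100 bp. `tidy()`
returns the calls as a plain tibble, `write_sites()` emits BED6+4 with a
per-chromosome summary, and `autoplot()` methods plot density models,
call sets and recovery distance CDFs.

A command-line wrapper ships at `inst/cli/consite` (installed under
`system.file("cli", "consite", package = "consite")`) with subcommands
`call`, `bin`, `simulate` and `compare`; see `?consite_main`.

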
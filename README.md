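# intervalmix

Model-based clustering of genomic regions by the co-occurrence of
multiple interval tracks.

## What it is for

ChIP-seq and similar assays summarize a protein's binding or a histone
mark as a *track*: a BED file of genomic intervals. Given D tracks and
N regions of interest (a user-supplied BED file, or the merged union of
all track intervals), `intervalmix` forms the binary overlap matrix
`Y[i, d] = 1` iff region *i* shares ≥ 1 bp with track *d*, and models
the rows of `Y` with a K-component mixture of products of Bernoulli
distributions:

    P(Y_i | Z_i = k) = prod_d q_kd^Y_id (1 - q_kd)^(1 - Y_id),
    P(Z_i = k) = pi_k

Each component is one co-occurrence pattern: `q[k, d]` is the
probability that track *d* occurs in a region of cluster *k*, and
`pi[k]` is the cluster's share of the regions. Parameters are fitted by
EM (K-means initialization, best of 10 restarts); the number of
clusters is chosen by BIC or by the elbow of the log-likelihood-vs-K
curve. Because tracks are independent within a component, the fitted
`(pi, Q)` answer *any* joint or conditional occurrence question —
"what fraction of regions bound by A and B is also bound by C?" —
without revisiting the raw intervals.

Audience: anyone comparing more than a couple of peak lists at once —
transcription-factor co-binding maps, histone-mark chromatin signatures
over promoters, or any multi-track interval co-occurrence problem.

## Worked example

Simulate a three-pattern data set as BED files, refit it, and query the
fitted parameters (all numbers below are the script's actual output):

```r
library(intervalmix)

truth <- sim_params(K = 3, D = 6)            # block-structured ground truth
beds  <- simulate_beds(truth, n = 1000, seed = 42, dir = "demo")

tracks  <- read_tracks(beds$track_beds)      # 6 BED files
regions <- read_bed(beds$regions_bed)        # 1000 regions
Y <- overlap_matrix(regions, tracks)

fit <- fit_em(Y, K = 3, seed = 42)
fit
#> Bernoulli mixture fit: N = 1000 regions, D = 6 tracks, K = 3 clusters
#> log-likelihood = -2971.794, BIC = 6117.579, 7 iterations (converged)
#> cluster sizes: 0.344 0.332 0.324

fit$params
#> Bernoulli mixture parameters: K = 3 components, D = 6 tracks
#>          cluster_1 cluster_2 cluster_3
#> pi           0.344     0.332     0.324
#> track_01     0.134     0.089     0.899
#> track_02     0.056     0.127     0.919
#> track_03     0.133     0.917     0.067
#> track_04     0.097     0.891     0.098
#> track_05     0.853     0.117     0.116
#> track_06     0.901     0.101     0.107
```

The fitted `pi` row says the three patterns split the regions roughly
evenly; each `q` column block near 0.9 marks a cluster's signature
tracks (compare `truth$q`: blocks of 0.9 on a 0.1 baseline — the fit
recovers them to about ±0.03).

Model selection scans a K range and reports both curves:

```r
scan_k(Y, 1, 6, seed = 42)
#> Model scan over K = 1..6
#>  K    loglik      bic n_iter converged
#>  1 -3946.216 7944.628      2      TRUE
#>  2 -3475.003 7063.101      9      TRUE
#>  3 -2971.795 6117.581      8      TRUE
#>  4 -2970.799 6176.485     15      TRUE
#>  5 -2967.156 6230.096     13      TRUE
#>  6 -2963.854 6284.388     52      TRUE
#> suggested K: BIC minimum = 3, log-likelihood elbow = 3
```

Both criteria agree on K = 3 here; on real genomic data with large N,
BIC often keeps decreasing and the elbow is the useful suggestion.

Occurrence queries against fitted parameters, including the published
15-protein mouse ES cell co-binding table shipped with the package:

```r
query_probability(fit$params, "track_01=1,track_02=1")
#> 0.273852
query_probability(fit$params, "track_03=1 | track_01=1")
#> 0.144341

es <- read_params(system.file("extdata", "mouse_es15_params.tsv",
                              package = "intervalmix"))
query_probability(es, "Oct4=1,Sox2=1")
#> 0.013430
query_probability(es, "Nanog=1 | Oct4=1,Sox2=1")
#> 0.767156
```

So only ~1.3% of those regions are Oct4+Sox2 co-bound, but among them
Nanog is present 77% of the time — the Nanog–Oct4–Sox2 enhanceosome
signature.

The same pipeline is available from the shell via `exec/intervalmix`
(subcommands `fit`, `scan`, `query`, `annotate`, `simulate`), e.g.

```sh
intervalmix fit --tracks a.bed --tracks b.bed --tracks c.bed \
    --regions union --k 3 --seed 1 --out results/
intervalmix query --params results/params.tsv --query "a=1,b=1 | c=1"
```

`annotate` compares each cluster's regions against feature tracks
(TSS, exons, ...) with length-based expected baselines: a feature
covering 1% of the genome is expected to overlap ~1% of randomly
placed regions.

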
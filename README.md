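# metahic

Normalization and genome binning for metagenomic Hi-C (metaHi-C) data.

In a metaHi-C experiment, proximity-ligation read pairs link assembled
contigs that were inside the same cell. The package turns filtered Hi-C
alignments into a contig-by-contig contact matrix, removes its systematic
biases with a two-stage negative-binomial regression, discards the weakest
contacts as inter-species noise, and clusters the contact graph into
metagenome-assembled genomes (MAGs). It is aimed at microbiome researchers
who have contigs (FASTA) and Hi-C alignments (BAM, or a pre-aggregated
contact table) and want draft genomes with reproducible, annotation-free
normalization.

## The model

Let `H_ij` be across-contig contacts, `N_i = H_ii` within-contig contacts,
and `M_i = Σ_{k≠i} H_ik` each contig's Hi-C signal. Raw contacts are biased
by restriction-site count `s_i`, length `l_i` and coverage `c_i`. The
signal is modelled as

&nbsp;&nbsp;`M_i ~ NB(μ_i, θ)`, &nbsp; `log μ_i = β₀ + β_s log s_i + β_l log l_i + β_c log c_i`,

but coverage — expensive to estimate — is eliminated through a companion
model `N_i ~ NB(ν_i, σ)` with the same log-linear form: assuming the
bias-free residual `N_i/ν_i` is constant across contigs, `c_i` can be
expressed through `(s_i, l_i, N_i)` and absorbed, leaving the single
regression that is actually fitted:

&nbsp;&nbsp;`log μ_i = β̃₀ + β̃_s log s_i + β̃_l log l_i + β̃_N log N_i`.

Contacts are then corrected by the scaled geometric mean of fitted means,

&nbsp;&nbsp;`H_ij → H_ij / √(μ̂_i μ̂_j) · Ĉ`, &nbsp; `Ĉ = max_k μ̂_k`,

the lowest 5% of nonzero normalized contacts are discarded as spurious, and
the remaining weighted graph is clustered by the Leiden algorithm under the
Reichardt–Bornholdt Potts modularity
`Σ_{Δij=1, i≠j} (e_ij − d_i d_j r / 2n)`, with the resolution `r` chosen as
the first grid value `{1, 20, 40, …}` whose count of resolved bins
(≥ 150 kbp) exceeds a marker-gene estimate of the genome number.
Discard–retain curves (AUDRC) and Fowlkes–Mallows / ARI / NMI scores
evaluate both stages against ground truth, and a synthetic community
generator provides ground-truthed test data. See the methods vignette
(`vignettes/metahic-methods.Rmd`) for assumptions, parameter rationales and
known limitations.

## Worked example

A full run on a simulated 10-genome community:

```r
library(metahic)
cfg <- sim_config(n_genomes = 10, seed = 1)
sim <- simulate_metahic(cfg)

filtered <- apply_contig_filters(sim$catalog, sim$contacts)
model <- fit_normcc(filtered$catalog, filtered$matrix)
print(model)
#> NormCC negative-binomial normalization model
#>   coefficients: beta0=1.4200, beta_s=0.7511, beta_l=-1.0314, beta_N=1.8655
#>   theta=1.5250  c_hat=20305530.7024  loglik=-3702.85 (3 iterations)

normalized <- normalize_contacts(filtered$matrix, model)
denoised <- remove_spurious(normalized)
print(denoised)
#> ContactMatrix [denoised]: 364 contigs, 15574 stored entries
#>   removal threshold: 1745.47

graph <- build_graph(denoised)
k <- estimate_genome_count(simulate_marker_counts(10, seed = 4))$k
cat("estimated genome count k =", k, "\n")
#> estimated genome count k = 9

sel <- select_resolution(graph, k, filtered$catalog, seed = 42)
sel$trace
#>   r k_r
#> 1 1  10

bins <- make_initial_bins(sel$partition, filtered$catalog)
clustering_scores(bins, sim$truth)
#> F-score = 1.0000  ARI = 1.0000  NMI = 1.0000

cat(sprintf("AUDRC raw = %.3f, normalized = %.3f\n",
            dr_curve(filtered$matrix, sim$truth)$audrc,
            dr_curve(normalized, sim$truth)$audrc))
#> AUDRC raw = 0.890, normalized = 0.994
```

Reading the output: the fitted coefficients make the within-contig count
the dominant predictor (it carries the coverage signal); 5% of normalized
contacts fall below the recorded threshold and are dropped; the marker
median under-counts the 10 genomes (k = 9, some markers go undetected), so
the resolution search stops at the first grid point whose 10 resolved bins
exceed it; the final bins reproduce the true species exactly, and
normalization lifts the spurious/intra separation (AUDRC) from 0.89 to
0.99.

The same pipeline runs from the shell over TSV interfaces:

```sh
metahic simulate --n-genomes 10 --seed 1 -o sim/
metahic norm --catalog sim/catalog.tsv --contacts sim/contacts_raw.tsv -o norm/
metahic bin  --contacts norm/contacts_denoised.tsv --catalog norm/catalog.tsv \
             --markers sim/markers.tsv -o bin/
metahic eval --pred bin/bins.tsv --truth sim/truth.tsv -o eval/
```

(the `metahic` script is installed under the package's `exec/` directory).

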
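# ddigip

Drug–drug interaction (DDI) prediction from a known-interaction network.

Co-administered drugs can modify each other's effects, and screening every
pair experimentally is infeasible: most of the pair universe is untested.
`ddigip` ranks untested drug pairs by how likely they are to interact, using
only (a) the network of already-known interactions and, optionally, (b) a
binary feature table describing each drug (chemical substructures, targets,
transporters, enzymes, pathways, indications, side effects). It is aimed at
computational pharmacologists who have an edge list of curated DDIs and want
a ranked list of candidate interactions, including for *new* drugs that have
no known interaction yet.

## Method

Let `Y ∈ {0,1}^{N×N}` be the symmetric adjacency matrix of known DDIs
(`y_ij = 1` when drugs *i* and *j* interact; zero diagonal). The row
`yd_i` is drug *i*'s **interaction profile**.

1. **GIP kernel.** Drug similarity is a Gaussian kernel on interaction
   profiles,

   `G[i,j] = exp(−γ_d ‖yd_i − yd_j‖²)`, with
   `γ_d = γ'_d / ( (1/N) Σ_i ‖yd_i‖² )`,

   so the bandwidth is normalized by the mean squared profile norm and the
   kernel is scale-free in `Y`. Default `γ'_d = 1`.

2. **RLS scoring.** A regularized least squares (kernel ridge) classifier
   scores every pair in closed form,

   `Ŷ_p = G (G + σI)^{−1} Y`, then `Y_p = (Ŷ_p + Ŷ_pᵀ)/2`.

   Default `σ = 1`. The solve uses a Cholesky factorization of the
   symmetric positive-definite `G + σI`; no explicit inverse is formed.

3. **KNN cold start.** A drug with an all-zero row (a "new" drug) carries
   no profile information. When features are available, its initial scores
   are imputed from the Pearson correlation `S` of binary feature vectors:
   with `K_set` its `K` most feature-similar drugs that have at least one
   known interaction,

   `Y'[i,j] = Σ_{l∈K_set} S[i,l]·y_lj / Σ_{l∈K_set} S[i,l]`.

   Default `K = 9`. The filled matrix feeds both the kernel and the label
   matrix of the RLS solve.

Candidate pairs (all unordered pairs not known to interact) are ranked by
descending score. Evaluation utilities provide repeated 5/10-fold
cross-validation over known pairs, leave-one-drug-out ("de novo")
validation, and rank-based (Wilcoxon–Mann–Whitney) AUC against the
unknown-pair universe.

## Worked example

The smallest network: two drugs with one known interaction.

```r
library(ddigip)
Y <- interaction_matrix(matrix(c(0, 1, 1, 0), 2, 2), c("A", "B"))
G <- gip_kernel(Y)
G["A", "B"]
#> [1] 0.1353353        # exp(-2): profiles (0,1) and (1,0), gamma_d = 1
Yp <- ddigip_predict(Y)
Yp["A", "B"]
#> [1] 0.4977           # (2 - e^-4) / (4 - e^-4), the RLS score of the pair
```

A full run on the synthetic benchmark (120 drugs in 6 latent groups;
compatible-group pairs interact with probability 0.35, others 0.02; 300
feature bits with 5% noise):

```r
sim <- generate_ddi_data(synth_config(seed = 7))
plan <- make_folds(sim$interactions, n_folds = 5, repeats = 3, seed = 7)
cross_validate(sim$interactions, sim$features, ddigip_params(), plan)
#> <ddigip_eval> protocol=cv5  AUC mean=0.7471 sd=0.0097  (15 folds)
denovo_validate(sim$interactions, sim$features)
#> <ddigip_eval> protocol=denovo  AUC mean=0.7846 sd=0.0555  (120 folds)
#>   pooled AUC = 0.7880
```

The cross-validation AUC of ~0.75 sits close to the Bayes ceiling of this
generator (~0.80 — see the methods vignette); the de novo run shows the
cold-start fill recovering partners for drugs stripped of every edge.

The same workflow from the shell:

```sh
inst/cli/ddigip simulate --n-drugs 120 --seed 7 --out-prefix demo/bench
inst/cli/ddigip predict --interactions demo/bench.edges.tsv \
    --features demo/bench.features.tsv --top 5 --output demo/ranked.tsv
cat demo/ranked.tsv
# rank  drug_id_1  drug_id_2  score
# 1     D0054      D0109      0.266268
# 2     D0048      D0109      0.265271
# 3     D0040      D0071      0.263911
# 4     D0040      D0114      0.261822
# 5     D0012      D0098      0.257141
```

Each listed pair is an untested candidate; the score is its symmetrized RLS
interaction probability estimate, and rank 1 is the method's best bet for a
yet-unknown interaction. `crossval` and `denovo` subcommands write JSON
reports that echo the full resolved configuration and seed, so every result
is reproducible bit-for-bit.

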
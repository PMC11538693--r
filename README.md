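# microhgt

Explainable classification of microbiome samples with a heterogeneous graph
transformer, and attention-based inference of the microbial community
associated with each phenotype class.

## The problem

Tumour tissues (and many other habitats) carry characteristic microbial
communities. Given a species × sample relative-abundance matrix
`A (M × N)` and a class label per sample (e.g. a cancer type), the question
is not only *can the samples be classified* but *which set of species is
responsible for each class*. `microhgt` answers both with one model:

1. build a heterogeneous graph with species and sample nodes; edges are
   `abundance` (species–sample, wherever `a_ij > 0`), `metabolic`
   (species consuming a common compound, or one producing what the other
   consumes — derived from a producer/consumer compound table), and
   `phylogenetic` (same genus);
2. initialise node embeddings with two autoencoders (species profiles and
   sample profiles);
3. train an `L`-layer, `h`-head, node- and edge-type dependent attention
   transformer to classify samples, with the focal loss
   `−(1/N) Σ α_c (1−p_ic)^γ y_ic log p_ic` (class weights
   `α_c = 1 − n_c/N`) plus a KL regulariser
   `α · Σ_j KL(a_·j ‖ softmax_i(S Pᵀ)_·j)` tying the final embeddings to
   the abundance profiles (`α = 0.003`);
4. threshold the trained species→sample attention per head and sample at
   `thr_kj = mean(A_kj[Q1,Q3]) + z_α · sd(A_kj[Q1,Q3])`, count for each
   species the class samples it contributes to (`T_ci`), score it with the
   binomial tail probability
   `P_ci ≅ Σ_{t=T}^{U_c} C(U_c,t) (S_max/M)^t ((M−S_min)/M)^(U_c−t)`,
   and report, per class, the species with adjusted `P_ci < 0.05`.

A stratified-subsampling reproducibility index, attention-rank
distributions with the exact 1-D Wasserstein distance, and a fully seeded
synthetic-data generator with planted communities complete the toolkit.

## Worked example

```r
library(microhgt)

# the package's reference synthetic study: 200 species, 120 samples,
# 3 classes, 15 planted class-elevated species per class (20-fold effect,
# 30% zero-inflation)
sim <- simulate_microbiome(synthetic_spec(seed = 1))
D1 <- metabolic_relations(sim$compound_table, rownames(sim$abundance))
D2 <- phylogenetic_relations(sim$taxonomy, rownames(sim$abundance))

fit <- hgt_fit(sim$abundance, sim$labels, D1, D2,
               control = hgt_control(epochs = 400, seed = 1))
fit
#> Heterogeneous graph transformer fit
#> Call: hgt_fit(A = sim$abundance, labels = sim$labels, D1 = D1, D2 = D2,
#>     control = hgt_control(epochs = 400, seed = 1))
#> Graph: 200 species, 120 samples; 16753 abundance / 156 metabolic / 400 phylogenetic edges
#> Classes: class1, class2, class3
#> Training: 400 epochs, final loss 0.35639 (focal 0.00092, kl 118.4921)
#> Training accuracy: 1.000

comm <- communities(fit)          # z_alpha calibrated automatically
comm
#> Class-associated microbial communities (adjusted p < 0.05 , method: bh )
#>   class1: 44 species
#>     s016, s009, s003, s010, s024, s002, s011, s015, ...
#>   class2: 44 species
#>     s037, s004, s009, s016, s023, s028, s006, s031, ...
#>   class3: 44 species
#>     s019, s006, s015, s023, s034, s027, s032, s010, ...

sapply(names(sim$truth), function(cl)
  length(intersect(community_sets(comm)[[cl]], sim$truth[[cl]])))
#> class1 class2 class3
#>     15     14     15
sapply(names(sim$truth), function(cl)
  jaccard(community_sets(comm)[[cl]], sim$truth[[cl]]))
#> class1 class2 class3
#>  0.341  0.311  0.341
```

The model classifies all 120 samples correctly, and the inferred
communities contain essentially every planted species (15, 14 and 15 of the
15 planted per class). They also contain species that are consistently
abundant across the whole study: the approximate binomial tail test scores
within-class consistency, not between-class contrast, so it cannot exclude
species that are strongly attended in every class. On sparse real profiles,
where a sample contains only a small fraction of the species catalogue,
this matters far less — see the methods vignette for the full analysis.

The fitted object answers the usual questions: `summary(fit)` adds the
confusion matrix, `predict(fit)` / `fitted(fit)` return classes and
probabilities, `coef(fit)` reports the trained meta-relation priors and
residual gates, `plot(fit)` draws the loss trace. `communities()` exposes
every intermediate (thresholds, per-sample calls, contribution counts, raw
and adjusted p-values). `run_pipeline()` wraps the whole chain and writes
all artifacts (communities, attention, thresholds, loss trace, graph
export, resolved configuration) into a directory, and
`run_reproducibility()` repeats it over stratified subsamples to compute
the reproducibility index `RJ`.

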
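---
title: "Attention-based inference of phenotype-associated microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based inference of phenotype-associated microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Given a species-by-sample relative-abundance matrix $A_{M\times N}$ and a
class label per sample (for instance a cancer type per tumour sample),
`microhgt` trains a graph transformer that classifies the samples and then
reads the species-to-sample attention of the trained model back out as an
explanation: for each class it returns the set of species that contribute to
that class's samples more consistently than chance would allow.

The data are represented as a heterogeneous graph with two node types
(species, samples) and three undirected edge types:

* *abundance* edges connect species $i$ to sample $j$ whenever $a_{ij} > 0$;
* *metabolic* edges connect two species that consume a common compound
  (competition) or where one produces a compound the other consumes
  (complementarity) — derivable with `metabolic_relations()` from a
  producer/consumer compound table such as a reformatted NJS16 export;
* *phylogenetic* edges connect species of the same genus
  (`phylogenetic_relations()` from a species-to-genus table).

Relation edges are binary and undirected; edge direction and interaction
strength are deliberately not modelled. For message passing each undirected
edge is realised in both directions, giving four meta-relations
(species-metabolic-species, species-phylogenetic-species,
species-abundance-sample, sample-abundance-species).

### Node embeddings

Each node type gets an initial $d$-dimensional embedding from its own
single-hidden-layer autoencoder (`initial_embeddings()`): a species is
encoded from its length-$N$ abundance profile, a sample from its length-$M$
profile, both with a ReLU hidden layer of width $d$, a linear decoder, and a
mean-square-error reconstruction loss. The two autoencoders are trained
independently but share $d$ so both node types enter the transformer with
equal width. $d$, the training schedule, and the activation are free choices; the
package defaults are $d = 64$, 200 epochs, Adam with learning rate
$10^{-3}$, all exposed in `ae_config()`.

### Typed multi-head attention

One transformer layer updates every node from its neighbours. For a source
node $s$ and target $t$ joined by an edge of type $\phi$, head $k$ computes

$$\mathrm{ATT}^k(s,e,t) = \frac{\mu_{\langle\tau(s),\phi,\tau(t)\rangle}}{\sqrt d}\,
K^k(s)\, W^{ATT}_\phi\, Q^k(t)^\top ,$$

where $K^k$, $Q^k$ are head-specific slices of node-type-dependent linear
maps of the layer's input embeddings, $W^{ATT}_\phi$ is a
$(d/h)\times(d/h)$ edge-type matrix shared across heads, and
$\mu_{\langle\cdot\rangle}$ is a trainable scalar prior per meta-relation
(initialised at 1). Scores are soft-maxed per head across **all** incoming
edges of a target, so each target's attention sums to one per head (a
`softmax_scope` option restricts the competition to within each edge type
instead). Messages are value projections passed through an edge-type matrix
$W^{MSG}_\phi$; the attention-weighted messages are summed and the target is
updated through a gated residual

$$H^l[t] = \theta\,\mathrm{ReLU}(\tilde H^l[t]) + (1-\theta)\,H^{l-1}[t],$$

with a trainable $\theta$ per node type. A variant sometimes written with
$(\theta - 1)$ as the residual weight makes the update $\approx -H^{l-1}$
for small $\theta$ and destroys the residual interpretation; the package
uses the standard gate $(1-\theta)$ and offers `literal_residual = TRUE`
for the $(\theta-1)$ form.

After $L$ layers (default 2, heads default $h = 8$) a fully connected
softmax layer on the sample embeddings predicts the class distribution.

### Loss

Classification uses the focal loss
$-\tfrac1N\sum_{ic}\alpha_c(1-p_{ic})^{\gamma}y_{ic}\log p_{ic}$ with class
weights $\alpha_c = 1 - n_c/N$, so rare classes weigh more, and focusing
exponent $\gamma \ge 0$ (default 2, the common focal-loss setting). The total loss adds a
Kullback-Leibler regulariser with weight $\alpha = 0.003$ that ties the
final embeddings back to the data: for every sample $j$,
$\mathrm{KL}(a_{\cdot j}\,\|\,\mathrm{softmax}_i(S P^\top)_{\cdot j})$,
summed over samples, where $S$ and $P$ are the final species and sample
embedding matrices.

Two aspects of this regulariser were genuinely open and deserve comment:

* **Orientation and scale.** The affinity matrix $S P^\top$ must be made
  comparable to $A$ somehow. We compare per *sample*: a sample's
  relative-abundance column sums to one and is therefore a natural
  distribution over species — and it is the same normalisation the attention
  softmax uses, so the regulariser and the attention operate on a shared
  geometry. Summing (not averaging) the per-sample divergences makes
  $\alpha\,\mathrm{KL}$ comparable in magnitude to the focal term at
  realistic sample counts with $\alpha = 0.003$, which is the stated reason
  that default was chosen.
* **Why it matters.** Without an effective regulariser the classifier is
  free to solve the task with attention patterns that carry no biological
  meaning. A softmax classifier over $C$ classes only needs $C-1$
  discriminative directions, and in controlled synthetic experiments we
  observed exactly that failure: the model concentrated attention on one
  class's informative species and encoded the remaining classes through
  arbitrary "class token" species. The KL term anchors the embedding
  geometry to abundance for every sample, which removes the degeneracy.

### Initialisation

The projection maps $K$, $Q$, $V$ initialise at the identity plus
$\mathcal N(0, 0.02)$ noise, $W^{ATT}$ and $W^{MSG}$ at the identity,
$\mu$ at 1, and $\theta$ at 1 (message-driven updates). With identity
projections an edge's initial attention score is the inner product of its
endpoint embeddings — the same affinity the KL term couples to abundance —
so attention starts inside, and is optimised within, an abundance-anchored
geometry rather than an arbitrary random one. Glorot initialisation of the
projections (the generic choice) re-introduces the class-token degeneracy
described above and is not offered.

Training is full-batch, transductive (all labelled samples; the goal is
attention extraction, not held-out prediction), with Adam at learning rate
$10^{-3}$ for 500 epochs by default, bit-reproducible for a fixed seed.
Gradients are computed by hand-written reverse-mode differentiation of the
whole model and are verified against central finite differences in the test
suite.

## From attention to communities

The species-to-sample attention of the final layer (`attention_layer =
"mean"` averages layers instead) is the explanation substrate. For head $k$
and sample $j$ the calling threshold is

$$thr_{kj} = \mathrm{mean}\left(A_{kj}[Q_1, Q_3]\right) +
z_\alpha\,\mathrm{sd}\left(A_{kj}[Q_1, Q_3]\right),$$

the mean plus $z_\alpha$ standard deviations of the non-zero attention
values inside the interquartile band (quartiles by linear interpolation,
type 7; sample standard deviation; a single-value band has sd 0). Species
$i$ is a *high-contribution* species for sample $j$ if its attention exceeds
$thr_{kj}$ strictly in at least one head. Per class $c$, $T_{ci}$ counts the
class samples species $i$ contributes to, and the tail probability

$$P_{ci} \cong \sum_{t=T_{ci}}^{U_c}\binom{U_c}{t}
\left(\frac{S^{max}_c}{M}\right)^{t}
\left(\frac{M-S^{min}_c}{M}\right)^{U_c-t}$$

asks how often that would happen by chance if each sample drew its
contributing set at random ($U_c$ class size; $S^{max}_c$, $S^{min}_c$ the
largest and smallest per-sample contributing set in the class). Because the
success and failure probabilities come from different set sizes the terms
need not sum to one; the sum is computed in log space and clamped to
$[0,1]$. Species with $T_{ci}\ge 1$ are candidates; those with adjusted
$P_{ci} < 0.05$ (Benjamini-Hochberg within class by default; raw p-values
are always reported alongside) form the inferred community of class $c$.

### Choosing $z_\alpha$

The band statistics make the threshold nearly scale-free: for any
moderately spread attention distribution the interquartile band's standard
deviation is roughly a third of the overall spread, so a fixed
$z_\alpha \approx 2$ puts $thr_{kj}$ just above the third quartile and about
a quarter of a sample's non-zero species exceed it in *every* head,
whatever the data. On sparse profiles (tens of species present per sample
out of a thousand) that still yields a small calling rate relative to $M$
and the tail test retains power; on densely observed matrices it floods the
test. The default `z_alpha = "auto"` therefore calibrates the multiplier:
it picks the smallest value on a fixed grid whose average per-sample call
fraction (OR over heads) is at most 10%, using only the attention tensor —
labels play no role, so the calibration cannot peek at the outcome. Any
numeric value (e.g. the conventional 1.96) can be supplied instead.

## Evaluation machinery

* `subsample_experiment()` draws $K$ stratified subsamples of fraction $r$
  (per-class counts `round(r * U_c)`, at least 1), re-runs any
  identification method, and summarises the per-class pairwise Jaccard
  similarities into the reproducibility index $RJ$ (`reproducibility_index()`;
  two empty sets count as similarity 1, a documented convention). Defaults
  are $K = 50$ and $r \in \{0.80, 0.85, 0.90, 0.95\}$; tests and examples
  scale these down.
* `attention_rank_distribution()` ranks species per head within each class
  sample (rank 1 = highest attention, average ranks for ties, absent edges
  count as zero attention) and represents each (species, sample) pair by its
  best rank across heads — the head where the species matters most; an
  option flips to the worst rank.
* `wasserstein_1d()` computes the exact 1-D earth-mover distance between two
  rank collections via the quantile-function closed form; `rank_fit_r2()`
  scores a rank profile against the fixed identity line
  $1 - \sum(y_i-x_i)^2 / \sum(y_i-\bar y)^2$ (negative for fits worse than
  the constant predictor).

## The synthetic generator

`simulate_microbiome()` generates the controlled world every stage is
tested in: log-normal baseline abundances with a species-specific location
(`baseline = "dirichlet"` is available), a planted disjoint community per
class whose abundance is multiplied by `effect` in samples of its class,
independent zero-inflation with probability `sparsity`, column
renormalisation, consecutive genus blocks of `genus_size` species, and a
compound table linking planted within-class pairs with probability
`compound_link_prob` (coin-flip between competition and complementarity).
Defaults (M = 200, N = 120, C = 3, community size 15, effect 20, sparsity
0.3) are the package's reference study conditions; `genus_size = 5` and
`compound_link_prob = 0.5` are realistic fillers for quantities no source
states. `null_attention()` draws exchangeable attention for calibration
work.

What the generator does *not* emulate matters for interpreting green tests:
real intratumoral profiles are far sparser (most species absent from most
samples), compositional effects couple species, detection probability
depends on abundance, and class signatures overlap (an `overlap` option
plants shared species). Passing recovery tests here shows the machinery is
sound under its stated assumptions, not that any particular real dataset
will yield communities of the same quality.

## Numerical and procedural choices

* Attention softmax, the KL term and the classifier head all subtract
  per-group maxima before exponentiation; the tail probability is
  accumulated in log space with `lchoose`; probabilities at true labels are
  clamped at $10^{-12}$ inside the focal loss.
* Thresholds with fewer than one non-zero attention value are undefined and
  the sample/head pair is skipped with a warning; attention exactly equal to
  a threshold is *not* a call (strict inequality); `0^0 = 1` in the tail
  probability.
* A compound consumed by more than two species links every pair of its
  consumers; species absent from the knowledge tables simply get no
  relation edges.
* Reference problem sizes used by the test suite and the acceptance script:
  unit tests run toy studies (tens of species); the end-to-end recovery
  study runs the generator defaults with 400 training epochs and seeds
  1-3, sizes chosen so the whole suite completes on a single CPU in well
  under half an hour.

## Known limitations

* The model is transductive; there is no held-out prediction path.
* Relation edges are unweighted and undirected; temporal structure is not
  modelled.
* The binomial tail probability is approximate (its two branch
  probabilities come from the largest and smallest contributing sets);
  BH within class is a pragmatic multiplicity correction for it.
* Attention explains the trained classifier, not the biology directly: a
  species can be attended because it proxies for a correlated partner.
* On densely observed matrices the communities err on the side of
  inclusion: the tail probability scores within-class consistency only, so
  species that are consistently abundant (hence consistently attended) in
  *every* class cannot be excluded by it. In the reference synthetic study
  the inferred communities contain essentially all planted species plus a
  tail of such globally abundant ones; on sparse profiles, where per-sample
  contributing sets are small relative to $M$, the test is far more
  selective.
* At very high class counts or extremely sparse classes the focal weights
  $\alpha_c$ approach 1 and class imbalance handling degenerates to plain
  weighting.
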
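---
title: "pathvae: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pathvae: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pathvae` fits a variational autoencoder whose latent space and decoder
are wired to mirror a biological ontology, so that the activation of each
hidden neuron group can be read directly as the activity of a pathway or
phenotype term, and so that single-gene input perturbations (knockouts,
stimulations) can be propagated through the network to predict their
effect on every term.  This vignette is the package's own account of the
model, its assumptions, the parameters that matter, and the design
decisions taken where the design was genuinely open.

## The model

### Variational autoencoder

For an expression vector $x \in \mathbb{R}^G$ (non-negative, log-scale),
an encoder network produces the parameters $\mu(x), \log\sigma^2(x)$ of a
diagonal-Gaussian approximate posterior $q_\phi(z \mid x)$ over a latent
vector $z$, and a decoder produces a reconstruction from $z$.  Training
maximizes the evidence lower bound

$$
\mathcal{L}_{\phi,\theta}(x) =
  \mathbb{E}_{q_\phi(z\mid x)}\!\left[\log p_\theta(x \mid z)\right]
  - \beta \, D_{\mathrm{KL}}\!\left(q_\phi(z \mid x)\,\|\,p(z)\right),
$$

with a standard-normal prior $p(z)$, for which the KL term has the closed
form $\tfrac12\sum_i (\mu_i^2 + \sigma_i^2 - 1 - \log\sigma_i^2)$
(`kl_divergence()`).  Gradients flow through the sampling step via the
reparameterization $z = \mu + \sigma \odot \varepsilon$,
$\varepsilon \sim N(0, I)$.  The reconstruction likelihood is Gaussian
with identity variance, i.e. a mean-squared-error loss: the inputs are
continuous log-scale values, and MSE keeps the decoder's linear read-out
interpretable.  We report the loss as MSE summed over genes and averaged
over samples, and the ELBO objective under the sign convention
`objective = -reconstruction - beta * kl` (`elbo()`).

### Ontology-shaped decoder

The ontology (a DAG of terms under *is a* edges, with genes annotated to
terms) dictates the decoder's architecture:

* the **depth** of a term is the longest directed path from any parentless
  term down to it (not the shortest — `compute_depths()`);
* depth-0 terms live in the **latent space**; each deeper depth is one
  **decoder layer**;
* each term is represented by $k$ neurons ($k = 3$ by default; one neuron
  per term makes siblings that share all parents receive identical input,
  and extra neurons reduce such forced correlations);
* the decoder is **linear** (no activation functions) so that each term's
  value is an interpretable non-negative combination of its ancestors;
* connections exist only where the ontology has them.  Because a parent
  and child can sit several depths apart, every layer receives the
  **concatenation of all earlier layers' outputs** (skip concatenation),
  and a binary mask zeroes all weights that do not correspond to an edge.
  The reconstruction layer likewise connects each gene only to the $k$
  neurons of the terms it is **directly** annotated to.  Direct (rather
  than descendant-propagated) annotation keeps the mask faithful to the
  ontology: descendant information already reaches a term through the
  term–term edges, and propagating annotations would densify the mask far
  beyond "terms and their annotated genes";
* all decoder weights are constrained **non-negative**, so that a higher
  term activity can only raise the activities of its descendants and the
  expression of its genes — this is what keeps the sign of an activity
  meaningful across retrainings.

`build_masks()` compiles the masks: for decoder depth $d$, a
$(k\,n_d) \times (k\,n_{<d})$ matrix with a $k \times k$ block of ones per
edge, plus a genes $\times$ ($k\,$terms) reconstruction mask with $1
\times k$ blocks.  Within a depth, terms are ordered lexicographically by
ID, which makes the layout a pure function of the trimmed ontology:
rebuilding from the same inputs is bit-identical.

The encoder is deliberately unconstrained: one dense hidden layer (default
width 512) with ReLU and dropout, followed by linear $\mu$ and
$\log\sigma^2$ heads.  A single hidden layer suffices at the scales the
package targets and keeps the parameter count dominated by the
input-to-hidden map.

### Ontology trimming

A raw ontology has a single root, which would give a one-dimensional
latent space, and thousands of tiny leaves that would add layers with
almost no data support.  `trim_ontology(graph, bottom, top)` removes every
term whose **descendant-gene count** (genes annotated to the term or any
term reachable below it, `descendant_genes()`) lies outside
`[bottom, top]`, computed on the untrimmed graph in a single pass.  The
defaults 30 and 1000 are the thresholds used for a Gene Ontology
biological-process decoder; smaller ontologies need proportionally smaller
bounds.  Children of a removed term are rewired to its closest kept
ancestors (edge contraction), so that ancestry among kept terms — hence
reachability, hence the mask structure — is preserved; deleting without
rewiring would orphan entire subtrees whenever a mid-level term falls
outside the band.  Both properties (counts within the band, reachability
preservation) are enforced by oracle-backed tests.  Depths are recomputed
on the contracted graph, and the model's gene list is rebuilt from the
direct annotations of kept terms.  Descendant counts (rather than direct
counts) are used for the thresholds because the descendant gene set is
the notion of "genes of a term" used everywhere else (similarity,
over-representation).

## Training protocol

Defaults follow the protocol the architecture was published with: batch
size 128, AdamW with learning rate $10^{-4}$ (decoupled weight decay 0.01
on weight matrices only), dropout 0.2 on the encoder hidden layer,
dropout 0.5 on the sampled latent vector, KL weight $\beta = 10^{-4}$, up
to 300 epochs, 80/20 train/validation split.  Specific choices the
protocol leaves open:

* **Positivity by clamping.**  After *every* optimizer step, decoder
  weights are set to $\max(w, 0)$ and re-masked, rather than
  soft-reparameterized (e.g. $w = e^u$); this keeps the decoder map
  exactly linear in the stored weights and the constraint exactly true at
  all times (asserted per epoch in the training history:
  `min_decoder_weight`, `max_masked_abs`).
* **Biases** exist in every decoder layer and are unconstrained;
  positivity applies to weights only.
* **Initialization** of decoder weights takes the absolute value of
  fan-in-scaled uniform draws, then applies the mask — starting *at* zero
  would leave weights stuck there under clamping.
* **Latent dropout acts on the sampled $z$** (not on $\mu$), during
  training only; all dropout and sampling are disabled at inference.
* The **validation loss** is evaluated deterministically ($z = \mu$,
  dropout off) so that model selection does not depend on evaluation
  noise; the snapshot with the lowest validation loss is kept, the
  earliest epoch winning ties.
* The split is a seeded uniform partition of samples, unstratified.  All
  stochastic draws (split, initialization, shuffling, dropout,
  reparameterization noise) flow from the single `seed` argument, so a
  fit is bit-reproducible.

The optimizer, backpropagation and dropout machinery are implemented in
base R matrix code; the backward pass is validated against central finite
differences, and the skip-concatenation forward pass against an
independent dense formulation $(I - L)^{-1}(Ez + b)$ of the same linear
map, where $L$ is the masked block-lower-triangular weight matrix.

## Pathway activities

`activities()` runs samples through the encoder **deterministically at the
posterior mean** ($z = \mu$, no sampling, no dropout), decodes, and
averages the $k$ neurons of each term; depth-0 terms therefore report
averaged components of $\mu$.  Posterior-mean inference is a deliberate
choice: sampled-$z$ activities would change on every call, and the
perturbation machinery needs repeatable numbers.  Repeated calls are
bit-identical.

## In-silico perturbation

A perturbation sets one gene's input column to a constant: 0 for a
**knockout**, a high value for a **stimulation** (default: the maximum
training-data expression rounded up to the next integer — the published
analyses used 8 against an observed maximum of 6.8).  Only single-gene
perturbations are supported; combinatorial perturbations are out of
scope.

Effects are quantified by **one-tailed paired Wilcoxon signed-rank tests**
between the same samples pre- and post-perturbation, at any term node
(latent or decoder) or reconstruction gene (`compare_node()`), for whole
gene panels ranked by p-value (`screen_genes()`), or for all terms and
genes at once with a hypergeometric over-representation analysis of the
top-$k$ most affected genes (`term_and_gene_level_analysis()`).  Zero
paired differences are dropped before ranking; a perturbation with no
usable pairs is reported untestable (`p = NA`) rather than raised as an
error.  For stimulations, samples in which the gene was not expressed at
all can be excluded (`exclude_zero_cells`), since raising a silent gene
tests the model's extrapolation rather than the sample's response.

Two behaviors of this procedure are worth knowing before interpreting a
screen:

* **P-values saturate on sign-consistency.**  The inference pass is
  deterministic, so a gene whose removal shifts a node in the same
  direction for (nearly) every sample reaches the floor of the signed-rank
  distribution regardless of effect magnitude.  In compact models with few
  genes, strongly expressed bystander genes can reach the same floor as a
  true driver; the screen discriminates reliably within a panel of
  candidate genes at a node (e.g. the genes annotated under the branch of
  interest), and discrimination improves with training convergence and
  with larger gene panels diluting each single knockout.
* **Null p-values are not uniform.**  For the same reason, under a
  no-effect null the per-gene p-values pile up near 0 and 1 instead of
  being uniform; screen p-values order genes but should not be read as
  calibrated significance levels.  (The underlying rank tests themselves
  are calibrated — their type-I error at the 0.05 level is verified by
  simulation — the non-uniformity comes from the deterministic model, not
  from the tests.)

## Group comparison statistics

`rank_sum_test()` and `signed_rank_test()` wrap R's Wilcoxon machinery:
the exact small-sample null distribution when samples are small and
untied, and the tie-corrected normal approximation otherwise.  Both report
a centered, standardized statistic (a z-score) alongside the p-value; the
exact path is what lets the tests agree to machine precision with the
exhaustive enumeration oracles in the test suite.  `bh_fdr()` is
Benjamini–Hochberg step-up adjustment, `hypergeom_ora()` the upper-tail
hypergeometric probability, `jaccard_similarity()`
intersection-over-union of descendant gene sets (defined as 0 for an
empty union; the similarity classes used descriptively are low
$js \le 0.25$, medium $0.25 < js \le 0.75$, high $js > 0.75$).

`rank_terms_for_groups()` implements the pairwise-hit ranking used to
find a group's top terms: for every term and ordered group pair, a
one-sided rank-sum test asks whether the term is more active in the first
group, a win at $p \le 0.05$ (uncorrected, configurable) is a *hit*;
groups are ranked per term by hit count, and per group the terms are
sorted by (rank, hits, median pairwise statistic).  One-sided tests match
the asymmetric hit definition; groups with fewer than two samples are
excluded with a warning.

## The synthetic-data generator

`simulate_ontology()` / `simulate_expression()` generate the ground-truth
world used by the tests and the acceptance analysis: a single-root random
DAG in which every non-root term has one parent one depth above (pinning
its longest-path depth) and, with probability 0.4, a second parent at any
smaller depth; terms draw 4–8 genes (configurable) from a shared pool.
Latent activities are **half-normal** at the root, matching the decoder's
non-negativity semantics; every non-root term takes 0.6 times the mean of
its parents' activities **plus its own half-normal innovation** (sd 0.5).
The innovation term is essential: purely deterministic propagation from a
single root would make all term activities collinear and the stored
per-term ground truth vacuous.  A gene's value is the positively weighted
(U(0.5, 1.5)) sum of its annotated terms' activities plus Gaussian noise
(sd 0.5 by default), truncated at zero — truncation rather than
exponentiation keeps the generative map piecewise linear.  Group
structure, when requested, adds a shift to one depth-1 term before
propagation, so the effect cascades down that branch.

What the generator does **not** emulate: count noise, dropout and
overdispersion of real single-cell data, batch effects, and the
incompleteness and redundancy of curated annotations.  Passing tests on
this generator show that the machinery recovers structure it is able to
represent; they do not certify performance on any real dataset.

`simulate_driver_scenario()` builds the sharper ground truth used for
perturbation validation: a two-branch ontology in which one branch's
learnable signal is carried by a single near-noiseless driver gene while
the branch's other genes are noise, so the driver is the only input whose
knockout can move that branch.

## Validation scales and numerical choices

The oracle-backed checks run on random DAGs of 10–40 terms (50 graphs for
mask/depth equivalence, 25 for trimming, 20 for the dense-decoder
equivalence at tolerance $10^{-6}$); the KL closed form is checked against
$10^6$-draw Monte-Carlo estimates within three standard errors; the rank
tests against full enumeration for $n \le 8$ and against a 2000-replicate
null for calibration.  The perturbation-recovery experiment trains ten
150-sample driver-scenario models for the full 300-epoch protocol, and
the reproducibility experiment trains two 500-sample, ~45-term models
(hidden width 512, $k = 3$) and compares per-term activity vectors; these
sizes were chosen so the entire validation runs on a single CPU in
minutes while still exercising every code path at realistic depth.

Remaining numerical conventions: degenerate rank tests (all values
identical) return $p = 1$; an all-zero difference vector is untestable
rather than an error; screens break p-value ties by statistic magnitude
and then gene ID so rankings are reproducible; `top_k` larger than the
gene universe is capped with a warning; ORA on an empty term gene set is
`NA`.

## Known limitations

* Only *is a* relationships are modeled; other edge types are discarded
  at parsing.
* Expression input is delimited text (samples × genes); HDF5-based
  single-cell containers are not read directly.
* The model cannot distinguish causal from merely correlated gene–term
  influence, and for phenotype ontologies the sign of a gene's influence
  on a term is not defined a priori — screens should be run in both
  directions.
* Perturbation p-values saturate and are not calibrated under the null
  (see above); treat screen output as a ranking.
* The decoder prior is hard-coded by the ontology; annotation errors
  propagate into the model, although the encoder can partially compensate.
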
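---
title: "Recurrent autoencoders for molecular strings: models, metrics and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent autoencoders for molecular strings: models, metrics and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Molecules are routinely represented as strings: SMILES, a depth-first
traversal of the molecular graph with a grammar (parentheses for branches,
digits for ring closures, lowercase letters for aromatic atoms), and
SELFIES, a bracket-token format in which *every* token sequence decodes to
a chemically valid molecule. Both formats are discrete; downstream
machine-learning models prefer a fixed-size numeric vector per molecule.
Sequence autoencoders provide that vector: an encoder reads the token
sequence and summarizes it into a latent vector $z$, a decoder
reconstructs the sequence from $z$, and after training $z$ serves as a
molecular embedding.

`molae` implements a configurable family of such autoencoders entirely in
R, together with the string handling (tokenization, canonicalization,
enumeration, a SELFIES codec), the training protocol, the three
reconstruction metrics, and latent-space diagnostics. A synthetic molecule
generator makes every part of the pipeline testable without external data.

# The architecture family

Both encoder and decoder are recurrent networks over one-hot token
encodings, either GRUs or LSTMs, with 1–3 layers, hidden size $H$ and
latent size $L$. The *latent bridge* between them follows fixed wiring
rules:

* **GRU, one layer, $H = L$, no attention:** the latent is the final
  hidden state itself, $z = h_T$. No bridge parameters exist, and
  `encodeMolecules()` returns $h_T$ bitwise.
* **GRU otherwise:** the final hidden states of all layers are
  concatenated and passed through one linear map to size $L$.
* **LSTM:** the cell carries both a hidden state $h_T$ and a cell state
  $c_T$; all layers' $h_T$ and $c_T$ are concatenated (width $2mH$)
  before the linear map, avoiding a doubling of the latent size.
* **Decoder initialization:** the GRU decoder starts from $z$ directly
  when $m = 1$ and $H = L$, otherwise from one linear map of $z$ split
  across layers; the LSTM decoder always uses two separate linear maps,
  one reconstructing initial hidden states and one initial cell states.

Two options extend the family. *Additive attention* scores every encoder
step output $h_t$ with $v^\top \tanh(W h_t + b)$, softmax-normalizes the
scores across (non-padded) steps and concatenates the weighted sum with
the final states before the bridge; with attention on, the bridge
projection always exists. The mechanism itself is a design choice of this
package — a minimal encoder-side additive self-attention — since several
formulations would fit the description "an attention layer added to the
encoder"; results that depend on it should be read qualitatively. The
*variational* option replaces the bridge by two linear heads producing
$\mu$ and $\log\sigma^2$; training samples
$z = \mu + e^{\log\sigma^2/2}\varepsilon$ and adds
$\beta \cdot \mathrm{KL}(q \,\|\, \mathcal N(0, I))$ to the loss with
$\beta = 0.3$ by default. Encoding and diagnostics use the mean $\mu$
(deterministic); whether evaluation should sample instead is genuinely
open, and the mean is the choice that makes embeddings reproducible.

Decoder inputs are one-hot tokens, not learned embeddings, matching the
one-hot framing of the encoder input. Weights initialize uniformly in
$\pm 1/\sqrt{\text{fan}}$, seeded; there is no gradient clipping.

# Training protocol

Training uses teacher forcing on every step (the decoder consumes the
ground-truth previous token), a masked token-level cross-entropy averaged
over non-PAD positions, and Adam with learning rate 0.005. Sequences are
padded to the longest training sequence plus one EOS token; PAD, SOS and
EOS occupy vocabulary indices 0, 1, 2 ahead of the lexicographically
sorted chemistry tokens, so encodings are bit-reproducible. Whether SOS /
EOS framing and PAD masking were part of the original protocol is not
documented; they are this package's conventions.

Early stopping monitors a validation loss on a seeded 10 % split of the
corpus (the split is a package choice; a "validation loss" is specified
but its data is not): training never stops before 50 epochs, stops once
the loss has not improved on its running best by more than 0.01 for 5
consecutive epochs, and always stops at 500 epochs. A validation fraction
that rounds to zero molecules switches to "train on everything, monitor a
training sample" — the right semantics for memorization experiments. Every
experiment runs once per seed (three by default) and reports each metric
as mean with min and max across seeds.

Enumeration-based augmentation comes in three pairing modes: `can2can`
(canonical in, canonical out), `enum2can` (a sampled non-canonical SMILES
in, canonical out) and `can2enum` (canonical in, sampled non-canonical
out). Enumerations are resampled every epoch with an epoch-derived seed,
so the model sees different variants across epochs — the choice that
extracts the most augmentation value. Batch size defaults to 128.

# Reconstruction metrics

All metrics operate on *tokens* (so `Cl` is one unit), and both
normalized metrics divide by the input token count $n$:

* **Mean Similarity** $= \frac1n \sum_{i=1}^n
  f(s_i^{\text{input}}, s_i^{\text{recon}})$ with $f$ the indicator of
  positional equality. Positions beyond the reconstruction's length score
  0; reconstruction tokens beyond $n$ are ignored. How length mismatches
  should enter is undocumented; this rule is the package's documented
  choice.
* **Levenshtein similarity** $= \max(0,\, 1 - \mathrm{LD}/n)$ where LD is
  the token-level edit distance (substitutions, insertions, deletions).
  The clamp at 0 handles reconstructions with $\mathrm{LD} > n$.
* **Full Reconstruction rate** = percent of molecules reconstructed
  without a single token mismatch.

Evaluation always decodes free-running (greedy argmax from SOS, no
teacher), so these metrics measure what the embedding alone supports.

# Latent-space diagnostics

`classifyUtilization()` types a latent matrix as *posterior collapse*
(nearly identical encodings across molecules), *high utilization* (high
variance in all dimensions) or *selective utilization* (a blend of
heavily used and near-dead dimensions, indicating spare capacity). The
matrix is first rescaled to $[0,1]$ with a **single matrix-wide** min-max
transform — the heatmap's one color scale — and a dimension counts as
unused when its variance falls below $\tau_{\text{low}} = 0.01$; at least
90 % unused dimensions is collapse, at least 5 % is selective. The
thresholds make a typology that is otherwise judged by eye computable;
they are configurable and recorded in every report. The matrix-wide scale
is deliberate: scaling each dimension separately (what `minmaxScale()`
does, for display) would stretch the residual jitter of a dead dimension
to the full range and destroy the very signal — low variance *relative to
the space's overall spread* — that the typology rests on. The flip side
is that the classification is only invariant to affine transforms applied
to the latent space as a whole, not per dimension; full per-dimension
invariance is mathematically incompatible with detecting collapse at all.

`enumerationColocalization()` asks whether the latent space reflects
chemical identity: a few test molecules are enumerated (4 variants each,
5 strings per molecule), embedded together with a large random background
(10 000 by default), and a PCA fitted on all embeddings jointly — one
projection, matching how such maps are drawn — reports the first two
components and their explained-variance percentages, plus each group's
mean within-group Euclidean distance. For SELFIES models the enumerated
SMILES are translated through the codec first. `distanceSeparation()`
complements this with the pairwise-distance histogram of 1000 random
embeddings against the group means: the more the group means fall below
the background, the better same-molecule variants co-locate.

# Chemistry layer

Canonicalization and SMILES parsing are delegated to OpenBabel through
the Bioconductor package ChemmineOB; canonical dialects differ between
toolkits and versions, so all comparisons in this package go through one
toolkit and checkpoints record the package environment. One wrinkle is
handled explicitly: for borderline fused heteroaromatics the toolkit's
aromaticity perception depends on the input atom order, so a single
canonicalization pass is not always a fixed point.
`canonicalizeSmiles()` therefore runs a second pass on the toolkit's own
output, and `enumerateSmiles()` additionally verifies that every variant
canonicalizes back to its source, which makes the enumeration-closure
invariant hold by construction. Enumeration
generates non-canonical SMILES by randomly renumbering the atom order of
the kekulized connection table and writing the string back without
canonicalization (bounded rejection sampling guarantees `k` distinct
strings also distinct from the canonical form, with an explicit error for
molecules too small to support them).

The SELFIES codec is authored here for the neutral organic subset
(C, N, O, F, S, P, Cl, Br; bond orders 1–3; branches; rings): encoding is
a depth-first serialization of the kekulized graph with branch lengths
and ring distances carried by overloaded index tokens (base-16 over a
fixed 16-token table); decoding caps every requested bond order by the
remaining valence of both partners and skips structurally impossible
tokens, so *any* token string yields a valid molecule. Strings consisting
only of control tokens decode to the empty molecule — the same convention
as the reference SELFIES semantics — which the validity guarantee counts
as valid. Stereochemistry, charges, isotopes and multi-fragment species
are out of scope.

# The synthetic corpus generator

`generateMolecules()` samples random SELFIES token strings over a small
robust alphabet (`[C] [=C] [N] [=N] [O] [=O] [F] [Branch1] [Ring1]`),
decodes them — valid by construction — and keeps distinct molecules with
at least 5 heavy atoms, with 6–15 tokens by default. This emulates the
shape of a drug-like benchmark corpus: bounded token length, restricted
organic alphabet, guaranteed parseability. The heavy-atom floor exists
because 2–3-atom fragments support too few alternative atom orderings to
be enumerable (and no drug-like corpus contains them); with
`enumerate = k` the generator additionally rejects molecules that cannot
produce `k` distinct non-canonical forms and attaches the enumerations.

What the generator does *not* emulate: realistic functional-group and
property distributions (logP, QED), aromatic ring statistics, length
distributions of real screening libraries, or token frequencies of any
particular database. Passing tests on this corpus therefore demonstrate
that the machinery is correct and that architectural contrasts point the
documented way at small scale — not that any absolute performance number
transfers to a real corpus.

# Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately small
problems chosen as the smallest sizes at which each claim is meaningful:
memorization uses a 50-molecule corpus (6–14 tokens) with the GRU base
model for 350 epochs at batch size 8; the GRU-versus-LSTM contrast uses
500 molecules, three seeds and an equal 40-epoch budget at batch size 64,
with Full Reconstruction measured on the training corpus — at this scale
a held-out split yields zero for both cells and carries no signal, so the
contrast reads as learning efficiency at an equal budget; enumeration
closure uses 1000 molecules with 4 enumerations each; the SELFIES
validity check uses 1000 random strings of 1–30 tokens.

Numerics worth knowing: softmax and cross-entropy use the log-sum-exp
form; greedy decoding breaks ties towards the lowest token index;
gradients for every configuration (both cells, multi-layer, attention,
variational) are validated against central finite differences in the test
suite; Adam uses the standard bias-corrected form
($\beta_1 = 0.9, \beta_2 = 0.999, \epsilon = 10^{-8}$). All randomness
(initialization, batching, enumeration sampling, the variational noise)
derives from explicit seeds, so runs are reproducible on one machine with
single-threaded BLAS.

# Limitations

* The recurrent core is plain R with BLAS matrix products: fine for the
  corpus sizes above, not for millions of molecules.
* The attention formulation and the multi-layer bridge wiring (concatenate
  all layers' final states, one projection) are natural but not unique
  choices; trends involving them are qualitative.
* The SELFIES codec covers the neutral organic subset only.
* Greedy decoding is the only decoding mode; there is no beam search, and
  no KL annealing beyond a constant weight.

# A minimal session

```{r}
library(molae)

mset <- generateMolecules(50, seed = 11)
tc <- TrainConfig(seeds = 1, minEpochs = 350, maxEpochs = 350,
                  batchSize = 8, validationFraction = 0.005)
fit <- trainAutoencoder(ModelConfig("gru"), tc, mset)
fit$reports[[1]]

z <- encodeMolecules(fit$models[[1]], canonicalSmiles(mset))
classifyUtilization(z)
```
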
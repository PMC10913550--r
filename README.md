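# molae — recurrent autoencoders for molecular strings

`molae` is an R package for building, training and dissecting sequence
autoencoders over small-molecule string representations (SMILES and
SELFIES). It is aimed at cheminformatics practitioners who want molecular
embeddings from modest hardware and want to understand *how architecture
choices shape them* — rather than a black-box embedding service.

The package implements, from the ground up and fully in R:

* **A configurable architecture family.** GRU or LSTM encoder–decoder
  pairs over one-hot token sequences, 1–3 layers, hidden size H, latent
  size L, optional additive encoder attention, optional variational head.
  The latent bridge follows explicit wiring rules: a single-layer GRU with
  H = L uses its final hidden state directly as the latent (z = h_T, no
  extra parameters); any other GRU projects the concatenated final hidden
  states with one linear layer; an LSTM concatenates final hidden *and*
  cell states (width 2mH) before the projection, and its decoder receives
  initial hidden and cell states from two separate linear maps of z.
* **The training protocol.** Teacher forcing throughout, masked
  token-level cross-entropy (plus a β-weighted KL term for the
  variational models, β = 0.3 by default), Adam at learning rate 0.005,
  early stopping on validation loss (minimum 50 / maximum 500 epochs,
  min-delta 0.01, patience 5), multi-seed runs reported as mean with
  min/max. Enumeration-augmented pairing modes: `can2can`, `enum2can`,
  `can2enum`.
* **Reconstruction metrics** on token sequences: Mean Similarity
  (1/n) Σᵢ f(sᵢ_input, sᵢ_recon), Levenshtein similarity 1 − LD/n, and the
  Full Reconstruction rate (percent of molecules reconstructed without a
  single token mismatch), all evaluated under free-running greedy
  decoding.
* **Latent-space diagnostics**: utilization typing
  (posterior collapse / high / selective utilization) from per-dimension
  variances of the rescaled latent matrix, PCA co-localization of
  enumerated molecules against a random background, and Euclidean
  distance separation.
* **The chemistry layer**: a standard regex SMILES tokenizer, OpenBabel
  canonicalization (via Bioconductor's ChemmineOB), atom-order-shuffling
  SMILES enumeration, an organic-subset SELFIES codec with the "any token
  string is a valid molecule" guarantee, and a seeded synthetic molecule
  generator so everything is testable offline.

## A worked example

Train the GRU base model (one layer, H = L = 64, no attention) to
memorize a 50-molecule synthetic corpus, then inspect reconstruction and
latent utilization:

```r
library(molae)

mset <- generateMolecules(50, seed = 11)
mset
#> MoleculeSet with 50 molecules
#>   SMILES: ONN=C=CN=CF, FNCOCONC=O, NNCCC=N ...
#>   SELFIES present: 50 | enumerated: 0

tc <- TrainConfig(seeds = 1, minEpochs = 350, maxEpochs = 350,
                  batchSize = 8, validationFraction = 0.005)
fit <- trainAutoencoder(ModelConfig("gru"), tc, mset)

fit$models[[1]]
#> MolAutoencoder (smiles)
#> ModelConfig: GRU, H=64, L=64, layers=1, attention=FALSE
#>   vocab size 17 | maxLen 16 | parameters 32977

fit$reports[[1]]
#> ReconstructionReport on 50 molecules (0 skipped)
#>   Mean Similarity        1.0000
#>   Levenshtein similarity 1.0000
#>   Full Reconstruction    100.0%

z <- encodeMolecules(fit$models[[1]], canonicalSmiles(mset))
classifyUtilization(z)
#> UtilizationReport: selective
#>   50 molecules x 64 dims, fraction of low-variance dims 0.203
#>   (tauLow=0.01, collapse>=0.9, selective>=0.05)
```

Reading the output: after 350 teacher-forced epochs the model reproduces
every training molecule token-for-token under free-running greedy
decoding (Full Reconstruction 100 %, both similarities 1.0), and its
64-dimensional latent space shows *selective* utilization — about a fifth
of the dimensions carry almost no variance, i.e. the base model has more
latent capacity than this corpus needs.

A YAML-driven command-line interface covering corpus generation,
training, evaluation and diagnostics lives at
`inst/scripts/molae.R` (see `?cmdTrain`, `?cmdEvaluate`, `?cmdDiagnose`).

## The methods vignette

`vignettes/molecular-autoencoders.Rmd` documents the model family and its
wiring rules, the training protocol, the metric definitions, the latent
diagnostics (including why utilization typing uses a matrix-wide rather
than per-dimension rescaling), the SELFIES codec's constraint set, what
the synthetic corpus generator does and does not emulate, and the
package's numerical choices and limitations.
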
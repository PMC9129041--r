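---
title: "Detecting GC-biased gene conversion at stop codons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting GC-biased gene conversion at stop codons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopflux)
```

## The scientific problem

Mammalian stop codons show a puzzle: TGA is conserved at orthologous
termination sites even though mutation in mammals is GC→AT biased and
should favour TAA. `stopflux` implements a pipeline for asking whether
that conservation reflects purifying selection or GC-biased gene
conversion (gBGC) — the meiotic repair bias that favours G/C over A/T
alleles in heteroduplex DNA and therefore acts like directional drive on
AT↔GC changes, strongest in GC-rich, highly recombining isochores.

The pipeline has four largely independent measurement arms:

1. **Stop-codon flux from species trios.** For each gene we take the
   focal stop codons of two ingroup species and one outgroup, infer the
   ancestral state at the internal node between the ingroups by maximum
   likelihood, and count transitions from the ancestral stop to each
   derived tip state, per incidence of the ancestral stop.
2. **The pTGA statistic.** Treating TAA↔TGA as a two-state chain with
   the estimated per-incidence rates, the equilibrium TGA share is
   `pTGA = 1 / (1 + s)` with `s = rate(TGA→TAA) / rate(TAA→TGA)`.
   Fluxes involving TAG are excluded: TAG usage is low regardless of
   local GC and behaves differently from the other two stops.
   Differences in pTGA between gene partitions (GC-rich vs GC-poor,
   highly vs lowly recombining) are summarised as `(O − E) / E` and
   tested against a Monte-Carlo null (below).
3. **Mutational equilibria.** From a de novo mutation table we build
   4×4 (and 16×16 dinucleotide) per-incidence rate matrices, solve the
   stationary distribution (N\*, GC\*), and solve the three stop-codon
   balance equations with substitution controls (TAA→TGA and TAA→TAG
   take the A→G rate; TGA→TAA and TAG→TAA the G→A rate; TGA↔TAG the
   double-step product `2·A→G·G→A`). These say what stop usage mutation
   alone would produce.
4. **Markov nulls and the fixation boost.** Dinucleotide equilibria feed
   a first-order Markov model that simulates null sequences; their
   trinucleotide frequencies are the mutational expectation `E`. The
   deviation `(O − E)/E` in GC-rich sequence (`D1`) versus GC-poor
   sequence (`D2`) yields the GC-coupled fixation boost
   `(D1 − D2)/D2` per trinucleotide, stratified into the four
   trinucleotide GC classes (0/33/66/100% G+C; 8/24/24/8 members).

## The trio model and ancestral reconstruction

The only tree involved is the unrooted 3-taxon star: one internal node
with three pendant branches. We deliberately reduced the substitution
model to JC69/HKY85: the downstream statistic consumes only the ancestral
stop codon of that single node, which is insensitive to richer
parameterisations at these divergences, and `import_state_table()` accepts
externally computed ancestral-state tables (IQ-TREE `.state` dialect) for
exact replication with any model. Branch lengths and kappa are fitted by
cyclic bounded 1-D ascent of the pruning likelihood over ungapped columns;
the likelihood is non-decreasing by construction.

Per column the internal-node posterior is
`P(x) ∝ π(x)·P(x→tip1|t1)·P(x→tip2|t2)·P(x→tip3|t3)`; tips that are gap
or N at a column drop out of the product. MAP ties are broken by the fixed
order A<C<G<T so reconstructions are deterministic. An ancestral codon is
called `"unresolved"` when it is not TAA/TGA/TAG or when a stop column is
gapped in two or more sequences (our rule; alignments of orthologous stop
regions rarely trip it). Parallel or convergent substitutions on the two
ingroup lineages are not corrected; at the branch lengths involved their
rate is quadratic in an already small per-lineage switch probability.

Both ingroup lineages contribute to flux counting — each contributes one
incidence of the ancestral stop, and one transition if its tip codon
differs. The alternative (scoring a single lineage) discards half the
information; the choice is recorded in the output metadata and the
per-incidence rates are invariant to it in expectation. The outgroup
enters only the reconstruction, never the counts. Stop→sense tips are
tabulated but excluded from stop-to-stop rates, mirroring the equilibrium
model's assumption that stop→sense flux is rare and strongly deleterious.

## The Monte-Carlo null for pTGA deviations

Genome-wide per-incidence rates are estimated from all genes pooled. For
a gene group, one null replicate flips each ancestral-TAA incidence to
TGA with the genomic TAA→TGA probability (and conversely for TGA),
recomputes rates and pTGA; 1,000 replicates give the group's null pTGA
distribution (the desk-scale suites use fewer; sizes are listed below).
For a pair of groups we draw `m = 10,000` random pairs (with
replacement), form `(a − b)/b` per pair, and report `p = n/m` with `n`
the count of null deviations at least as large as observed — one-sided,
because the hypothesis (GC-rich exceeds GC-poor) is directional; a
two-sided flag exists. Ties count toward `n` (conservative). Replicates
with undefined pTGA (zero TAA→TGA events) are redrawn rather than
dropped so `reps` stays exact, and the redraw count is logged. When
`n = 0` the p-value is reported against its resolution bound `1/m`.

## Mutational equilibria: numerical choices

Stationary distributions are obtained by a linear solve of the
global-balance system with the sum-to-one constraint (null-space
approach), not by fixed-point iteration — exact to machine precision and
independent of mixing time. Power iteration of the embedded
per-generation chain is retained as the test oracle. Reducible chains
(an empty matrix cell can disconnect a state at desk scale) raise an
error naming the absorbing class; in binned analyses the affected bin is
flagged and its equilibrium reported absent rather than extrapolated.

The stop-codon system is solved the same way the balance equations are
written: one stop frequency is replaced by one minus the other two and
the remaining 2×2 system solved; the result is invariant to which stop
is eliminated (tested to 1e-12) and every balance residual is checked.

Exposure — the denominator of "changes per incidence of the nucleotide in
the reference" — defaults to the union of the mutations' centred 10 kb
windows, so rates and local composition are measured on the same
sequence; a `"genome"` mode uses the whole reference. Both are provided
because the field's descriptions are usually silent on this point; in
GC-binned analyses the windowed mode is what makes per-bin rates
meaningful. Each point mutation contributes both overlapping
dinucleotide transitions (left and right context) by default; a
single-side mode exists for sensitivity analysis. Mutations are counted
as reported, without collapsing to pyrimidine-strand classes, because the
matrices are full 4×4/16×16. Confidence intervals are exact Poisson
intervals on counts, scaled by exposure.

## Markov nulls

`markov_from_dinuc()` turns a 16-simplex of dinucleotide equilibrium
frequencies `F` into a first-order chain: the initial dinucleotide is
drawn from `F`, and `P(next = b | prev = a) = F(ab) / Σ_b' F(ab')`.
The closed-form stationary trinucleotide probability
`p(abc) = F(ab)·P(c|b)` is exposed (`trinuc_expected()`) so users can
skip simulation; simulation is retained because it reproduces the
sampling error of the simulate-then-count procedure. Note the closed
form (and the stationarity of the simulants) presumes `F` is
marginal-consistent — row and column marginals agree — which genuine
dinucleotide equilibria satisfy; an arbitrary 16-simplex does not.

Simulated sequence length defaults to the rounded mean CDS length of the
gene set under study, with 10,000 simulants the reference configuration.
Each simulant consumes a private random stream derived from the root
seed, so enlarging `n` never reshuffles earlier sequences. Stop-codon
equilibrium shares are `TGA* = F(TGA)/(F(TAA)+F(TGA)+F(TAG))` over
frame-free trinucleotide frequencies, consistent with the UTR analyses
which are frame-agnostic; 3′ UTR counting starts strictly after the
focal stop so the response variable never leaks into the expectation.

## The boost metric and its sign pathology

`boost = (D1 − D2)/D2` is computed literally. The literal form flips
orientation whenever `D2 < 0` — for a trinucleotide under-represented
relative to its mutational null in GC-poor sequence, a further deficit in
GC-rich sequence produces a *positive* literal boost. For this reason
`boost_table()` always co-reports the plain difference `D1 − D2` and the
`|D2|`-denominator variant (`boost_abs`), whose sign always equals
`sign(D1 − D2)`; nothing is ever silently substituted. The validation
experiments use the sign-stable variant when testing orderings across GC
classes, precisely because their synthetic GC-poor stratum sits close to
its mutational equilibrium, where `D2` crosses zero and the literal
formula's sign is that of the noise in `D2`. Coding sequence is excluded
from rank-correlation analyses by default — selection on the encoded
protein confounds the fixation signal there.

Downstream "usage" in the stop-enrichment statistic is conditional: at
downstream in-frame position +k, usage is computed only over genes that
carry one of the three stop trinucleotides at that position, which is
what makes the three usages sum to one per position. Positions with no
stop trinucleotide in any gene are skipped rather than zero-filled.

## The synthetic-data generator

The generator emulates every input the pipeline consumes, with recorded
ground truth: an isochore-structured reference (i.i.d. bases per block at
target GC, defaults 0.35/0.45/0.55/0.65, matching the span of mammalian
isochores), genes with 5′UTR, two CDS exons, an intron and 3′UTR on
alternating strands, trio alignments evolved from each gene's CDS,
mutation tables sampled from the ground-truth matrix, a log-normal
recombination map whose log-rate mixes standardised window GC with noise
in proportion to a coupling knob, and log-normal protein abundances
(meanlog 3, sdlog 1.5 ppm — a heavy-tailed proteome).

The gBGC knob `B` acts at fixation, not mutation: every proposed change
is accepted with a base probability of one half, scaled by `B` for
AT→GC changes and by `1/B` for GC→AT changes, so `B = 1` is neutral and
the up/down fixation ratio is `B²`. This deliberately separates the two
forces the pipeline is designed to distinguish — a GC→AT-biased mutation
process and an AT→GC-biased fixation process. Long noncoding blocks are
evolved by sampling each site's final state from the exact finite-time
transition matrix of this process (sites are independent under a
mononucleotide model, so this is distribution-identical to event-by-event
simulation and orders of magnitude faster). Trio alignments are generated
ungapped, isolating flux inference from aligner error. Focal stop codons
switch as a unit with per-lineage probabilities (`TAA→TGA = r·B`,
`TGA→TAA = r/B`, TAG exchanges at `r²`), or with an explicit user matrix.

What the generator does **not** emulate: indels and alignment error,
CpG hypermutability (unless planted through a context-weighted table),
selection on coding sequence, demography, and recombination hotspot fine
structure. Passing the recovery suite therefore shows the estimators are
correct under the stated model, not that real-genome complications are
handled; the importers exist so that real IQ-TREE/MAFFT outputs can be
substituted where that matters.

## Validation experiments and problem sizes

The package's acceptance suite re-derives every stage from scratch:

- stationary solves against long-run power iteration (4×4 and 16×16,
  agreement to 1e-10) and marginal ASR against brute-force enumeration
  over the four internal states (1e-10);
- stop-equilibrium balance residuals below 1e-12 and invariance to the
  eliminated stop;
- null-simulator calibration: 500 replicate experiments with both groups
  of 1,000+1,000 ancestral stops generated at genomic rates 0.02/0.02
  (200 null replicates, 2,000 pairs each) must give 3–7% of p-values
  below 0.05;
- flux recovery: 5,000-gene trios across a per-lineage rate grid
  (0.005–0.05), estimates within 3 binomial SE and pTGA within 3
  bootstrap SD of the generator's event log;
- matrix recovery from 50,000 sampled mutations (≥90% of cells inside
  their 95% Poisson intervals; GC\* within 3 bootstrap SE of the
  analytic value);
- Markov-null consistency at 10⁷ simulated bases, with the Monte-Carlo
  SE taken from the between-simulant spread (overlapping windows within
  a simulant are dependent, so the naive multinomial SE would be wrong);
  and flat per-GC-bin equilibria under a homogeneous mutation process,
  "flat" meaning the extreme-bin difference is within three times its
  own (bootstrap) standard error;
- boost sign recovery: with `B = 2` planted in half the blocks the
  100%-GC class out-boosts the 0%-GC class in ≥95% of 50 seeds; with
  `B = 1` everywhere the per-seed correlation signs are symmetric
  (binomial sign test p > 0.01). The strata in these experiments are the
  generator's block labels (under `B = 2` the biased blocks *are* the
  GC-rich blocks). Ranking exchangeable windows by their realised GC and
  comparing each stratum to a (then common) mutational null is not a
  valid neutral control: conditioning on compositional noise mechanically
  enriches GC-rich trinucleotides in the high stratum and manufactures a
  boost gradient with no bias present. The same regression-to-the-mean
  caveat applies to real data whenever the GC strata and the mutational
  nulls are not genuinely matched;
- the mutational-null regression on low-GC synthetic sequence explains
  ≥90% of trinucleotide-frequency variance.

These sizes were chosen as the smallest at which the binomial/bootstrap
error bands are informative; all are fixed in the test code.

## Known limitations

- The HKY85 reduction cannot represent context-dependent substitution;
  the `.state` importer is the escape hatch.
- The pTGA statistic conditions on observed flux and ignores
  stop→sense→stop paths entirely.
- The literal boost is undefined where `D2 = 0` and unstable nearby; use
  the co-reported variants when `D2` straddles zero.
- Dinucleotide "equilibria" from sparse bins can be reducible; such bins
  are flagged, not imputed.
- The generator's fixation bias is memoryless per site; linkage and
  conversion-tract structure of real gBGC are not modelled.
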
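---
title: "Models and methods behind phyloseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phyloseed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloseed)
```

phyloseed reconstructs how a metastatic cancer spread through a patient
from two complementary data layers collected on multiple lesions of the
same tumour: ultra-deep targeted read counts of somatic point mutations
(SNVs) and allele-specific integer copy-number profiles. This vignette
describes the models, the parameters that matter, the design decisions
taken where the methodology was genuinely open, and what the synthetic
data used in the test suite does and does not establish.

## Tiered filtering of SNV calls

Formalin-fixed material produces low-level artefactual reads of all four
bases. The filtering ladder therefore works on evidence tiers: externally
indexed and validated mutations enter as tier-2 provenance flags, and the
package recomputes the sequencing-driven levels.

* **Background noise.** Positions flanking validated SNVs estimate the
  per-substitution-class background. Positions with more than 10%
  non-reference reads are removed as probable germline variants, and the
  remaining non-reference fractions are pooled into six classes
  (`AT>CG`, `AT>GC`, `AT>TA`, `CG>AT`, `CG>GC`, `CG>TA`). The presence
  cutoff is a configuration value, default 3% of reads — a deliberately
  conservative margin above the background such assays show in practice
  (well under 2%).
* **Tier 3.** Cells sequenced to 1,500x or less are treated as missing
  (the depth rule is exclusive: a cell at exactly 1,500x is missing,
  matching the "more than 1,500-fold" convention); samples below 75%
  non-missing are dropped; SNVs with more than one missing cell across
  the retained samples are dropped; SNVs absent everywhere are dropped;
  finally samples with 20% or fewer of the remaining SNVs present are
  dropped as likely low-purity material. The presence and CCF cutoffs
  are inclusive (3% calls present, 30% promotes); the filters are applied
  once, in this order, and re-applying them to their own output changes
  nothing.
* **Tier 4.** Samples with an array-confirmed cancer cell fraction of at
  least 30% are promoted; samples without a CCF estimate stay tier-3
  with a warning rather than being silently promoted or dropped.

## Cancer cell fractions from read counts

For an SNV carried on $s_q \in \{1, \dots, q_2\}$ copies at a locus with
total copy number $q_t$ (major allele $q_2$, minor $q_1$) in a sample
with cancer cell fraction $\alpha$, the expected variant allele
frequency is

$$f_{s_q} = \frac{s_q\,\alpha}{q_t\,\alpha + 2\,(1-\alpha)},$$

and a sequencing error rate $e$ (misreads hitting the specific alternate
base with probability $e/3$) shifts the binomial success probability to
$f(1-e) + (1-f)\,e/3$. Three estimators build on this relation:

* **Pointwise.** A uniform prior over $s_q$ times the binomial
  likelihood gives a posterior over the multiplicity; inverting the
  relation at the posterior mode yields
  $\hat\alpha = 2\hat f / (s_q - \hat f q_t + 2 \hat f)$. Observed
  frequencies too large for any multiplicity pin the estimate at 1 with
  a saturation flag; zero-count observations flag a near-zero estimate
  instead of failing.
* **Global.** The per-sample CCF maximizes the mixture likelihood over
  all usable SNVs, with mixture weights over $s_q$ shared across SNVs of
  the same copy state and adjusted by expectation-maximization at each
  grid value of $\alpha$ (grid 0.02–1.00, step 0.01 — finer than the
  recovery tolerance of the estimator; at most 100 iterations or a
  log-likelihood change below 1e-6). The EM runs on the log scale with a
  per-observation floor at the smallest representable log density, which
  keeps the iteration monotone even where far-off grid values underflow.
  The likelihood is binomial on counts; this is the counts-level
  equivalent of a Beta observation model on frequencies with the same
  error-substituted mean, and is exactly testable against planted
  parameters. SNVs at masked loci, or at loci where the sample retains
  no major-allele copy, are excluded from the fit.
* **Clonal frequency.** The ratio of the pointwise to the global CCF,
  capped at 1. This deliberately replaces Dirichlet-process clustering
  of mutation frequencies with a direct per-SNV quantity: downstream
  classification only needs "fully clonal vs subclonal vs absent", and
  the ratio form is transparent and testable.

One caveat is inherent to the model: a sample whose usable SNVs all sit
at loci with $q_2 \ge 2$ admits equivalent $(s_q, \alpha)$ explanations
(for example $s_q{=}1$ at $\alpha{=}0.8$ and $s_q{=}2$ at
$\alpha{=}0.4$ produce identical expected frequencies at $q_t{=}3$).
Real panels always contain SNVs at heterozygous diploid loci, which
anchor the estimate; the parameter-recovery tests reflect that mix.

**Detection power** is the binomial tail probability of reaching the
presence cutoff given the local depth and the expected frequency if the
mutation were present; it certifies that an absence call is informative
before any reversion is asserted.

## Array QC and profile cleanup

Two track-level metrics guard against wavy FFPE profiles: MAPD, the
median absolute difference of adjacent log2 probe values pooled
genome-wide, and MAC, the median across chromosomes of the per-chromosome
lag-1 Pearson autocorrelation (the metric is named without a lag in the
field; lag 1 is the convention for waviness detection). Samples with
MAPD above 0.7 or MAC above 0.3 fail; the boundary values pass.

Neighbouring segments whose means differ by less than three standard
deviations are merged leftmost-first until a fixed point. The reference
deviation is the pooled *within-segment* probe standard deviation — using
the total variance would let the very mean gap under test inflate its own
acceptance band. Merging is a partition coarsening: it never changes the
spanned genome.

Because the integer caller truncates at eight copies, any segment
reaching total copy 8, or a major allele above 4, in any sample is
removed from all samples of the patient before tree building, and SNVs
at such loci are excluded from CCF estimation. High-ploidy patients are
exempt — there the rule would erase most of the genome.

## Dollo phylogenies of SNVs

Binary presence/absence characters evolve under Dollo parsimony: each
mutation arises exactly once and can only be lost afterwards. On a fixed
rooted topology the single gain sits at the most recent common ancestor
of the carrying samples, and the score is the minimum number of loss
events explaining the absent leaves; the all-absent germline outgroup
roots every tree. Missing cells contribute no cost in either direction —
they are not imputed, and the upstream missingness filters keep this
from mattering in practice.

The search is exhaustive: leaves are added stepwise and a partial
topology is pruned as soon as its score exceeds the best complete score,
which is valid because restricting a tree to a leaf subset can only
lower its Dollo score. All co-optimal trees are returned (up to 9
leaves; beyond that a neighbour-joining start is offered with an
explicit heuristic flag). Ties are broken against the patient's
copy-number tree by minimum unrooted Robinson–Foulds distance, then by
lexicographic Newick order so results are deterministic.

Ancestral states follow accelerated transformation: the gain on the
branch into the carriers' MRCA, losses as high in the tree as the
minimum allows; missing leaves inherit the state of their surroundings
(an all-missing subtree below a gain is treated as carrying, which
postulates no event). Branch lengths are the event counts this
reconstruction assigns.

A predicted loss becomes a **reversion call** only after two checks:
the detection power of the absent call must reach 0.95 (otherwise the
call is flagged a possible false negative), and the affected samples'
copy-number state at the mutated segment is compared with every sample
still carrying the SNV — a drop in total, major or minor copies
annotates the reversion with its physical cause; an unchanged state is
reported as unexplained rather than silently accepted.

## Minimum-event phylogenies of copy-number profiles

The elementary event adds or removes one copy over a contiguous run of
segments of one allele. Counts stay non-negative and an event can never
raise an allele from zero — a deleted allele is unrecoverable, which is
what makes LOH phylogenetically informative. The directed distance
between two allele vectors has a closed form: the sum of positive
ascents of the required gain and loss profiles, with permanently-zero
loci splitting the vector into independent blocks (this equals
breadth-first search in the state graph; the test suite verifies the
equivalence on hundreds of random pairs). One consequence worth noting:
moving one locus from 2 to 0 costs two events — each unit step is an
event.

The symmetric dissimilarity between two profiles minimizes
$d(c \to p) + d(c \to q)$ over unobserved ancestors $c$. Because the
ascent formula decomposes over adjacent loci, this minimization is
solved exactly by dynamic programming over the ancestor state at each
locus, rather than delegated to a transducer composition whose
internals would be opaque to testing.

Tree building searches all rooted topologies (up to 7 leaves) for the
minimum total event count, with internal profiles optimized per locus
and per allele by a Sankoff-style dynamic programme over integer states
under the unit-step cost and the no-0-to-1 rule. The per-locus
decomposition is an approximation relative to full multi-segment
alignment, but at the segment granularity used here independently
optimized loci never interact. Near-diploid patients root at a uniform
diploid 2/1 outgroup.

**WGD rooting.** Tetraploid patients are rooted by scoring the four
candidate tetraploid ancestral states 6/4, 4/2, 4/4 and 2/2
(total/major) at the root of an intermediate topology. Internal nodes
may take any integer between the observed extremes at that locus:
restricting them to exactly the observed values would exclude
intermediates that the event model can pass through, so the range
reading is the strictly more parsimonious convention and is the one
implemented. A locus no candidate can reach is excluded with a
warning; a candidate that cannot reach a retained locus scores infinity
rather than silently dropping the locus. Ties are broken by adding the
cost of the events that must precede the duplication — the event
distance from diploid 2/1 to the halved states 3/2, 2/1, 2/2 and 1/1,
i.e. 1, 0, 2 and 1 — and the final tree is re-rooted at the winner.

**Support values** resample the pairwise dissimilarity matrix (default
100 times) with i.i.d. Gaussian noise (default standard deviation 1
event, configurable; there is no canonical choice for the magnitude —
one event is the smallest meaningful perturbation of an event-count
matrix), rebuild a tree from each resample (neighbour joining by
default; the builder is injectable) and report the fraction of
resamples containing each original bipartition.

## Progression metrics

* **Normalized branch lengths.** Per lesion, the event-path length from
  the cancer clade's MRCA to the leaf divided by the trunk (root to
  MRCA). The trunk is defined *excluding* the zero-length outgroup
  stem; either convention is defensible, and the choice only rescales
  all patients identically. The ratio is invariant
  under uniform rescaling of branch lengths; a tree without truncal
  events has no defined ratio and errors explicitly.
* **Survival correlation.** Spearman rank correlation of per-patient
  mean ratios against overall survival, requiring at least four
  patients and flagging all-tied input as degenerate.
* **Substitution spectra.** Pyrimidine-strand-normalized six-class
  counts split into early (trunk) versus late (below the MRCA) phases,
  with the fraction of C>T events at NpCpG trinucleotides reported per
  phase as an APOBEC-style indicator. No signature deconvolution is
  attempted — the fraction is the claim.
* **Pairwise configurations.** Each SNV and ordered sample pair falls
  into one of seven configurations of the two-sample clonal-frequency
  plane. Fully clonal means a clonal frequency of at least 0.8 — "full
  clonality" has no canonical numeric cutoff; 0.8 is configurable and
  sits well clear of both 1 (sampling noise) and the planted subclonal
  fraction 0.3. Configurations vi and vii (clonal in
  one sample, subclonal in the other) are tree-incompatible and ground
  the **cross-seeding call**: an ordered donor–recipient pair is called
  when at least $k = 5$ SNVs private-clonal to the donor's clade appear
  subclonal in the recipient; $k = 5$ separates the dozen-mutation
  signal seen in real cross-seeding from the one-to-three stray
  mutations that sampling noise produces.

## What the synthetic data emulates — and what it does not

The generator (`sim_config()` / `simulate_patient()`) plants a random
rooted binary clone tree over the sampled lesions, truncal SNVs (fixed
count, default 30) and per-branch SNVs (Poisson, default mean 8),
segmental copy-number events (Poisson; default 4 truncal, 2 per branch,
with an optional per-branch floor for regimes defined by a minimum
event count), per-sample CCFs (uniform in 0.5–1), optional trunk WGD,
optional LOH events that delete a mutated allele, and optional
cross-seeding (donor-private SNVs at clonal fraction 0.3 in the
recipient, mirroring the dozen-mutation pattern the method is built to
detect). Read depth is Poisson around 9,000x — the ultra-deep targeted
regime — floored at 100; errors hit the specific alternate base with
probability $e/3$, default $e = 0.01$.

Deliberate simplifications, each chosen to make planted truth
unambiguous rather than to flatter the method:

* Profiles are emitted phased (major = one fixed parental allele, kept
  at or above the other during generation), as a multi-sample-aware
  integer caller would phase them.
* Background copy-number losses keep at least one copy of each allele;
  allele-deleting LOH enters only through the dedicated reversion
  planting and the pre-WGD states. The reversions in the data are
  therefore exactly the planted ones.
* Reversion LOH is planted on terminal branches whose leaf is not a
  direct child of the cancer MRCA, so the remaining carriers still pin
  the gain at the trunk and the reversion is identifiable in principle.
  A reversion that deletes an entire clade's worth of evidence is
  undetectable by any method and would only measure the generator.
* Mutation multiplicity follows a deterministic convention (gains after
  the SNV on a branch duplicate it only when every copy is mutated;
  losses remove unmutated copies first unless planted as reversions).
* Cross-seeded mutations appear in the recipient at one fixed
  subclonal fraction rather than a distribution of fractions.

Consequently, passing tests show that the pipeline recovers planted
truth under its own statistical assumptions at realistic depths and
event counts. They do not establish robustness to unphased or wrongly
segmented profiles, subclonal copy number, multiple independent LOH of
the same segment, or mutation multiplicities that violate the
convention above.

Problem sizes used by the test suite — chosen to exercise each claim at
desk scale: Dollo search equivalence on 500 random 4–6-leaf matrices
against full enumeration; event-distance equivalence on 500 random
vector pairs (length ≤ 5, values ≤ 4) against breadth-first search; CCF
recovery at 50 SNVs and depth 2,000 over 20 seeds per planted value;
reversion recovery over 25 simulated patients at depth 3,000; seeding
detection and false-positive rate over 50 simulations each at depth
5,000; copy-number topology recovery over 30 simulations with at least
5 events per branch on a 60-segment grid (collision-driven homoplasy,
not algorithmic failure, dominates on much coarser grids).

## Known limitations

Exhaustive tree search is deliberate (the cohorts this targets have
3–7 usable lesions per patient) and refuses silently degrading: larger
patients get a flagged heuristic. The clonal-frequency replacement for
mixture clustering ignores correlations between SNVs of one subclone.
The WGD rooting assumes a single duplication on the trunk. Segmentation
and integer copy-number calling are upstream of this package: profiles
enter as integers with shared breakpoints, and errors made there
propagate.
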
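---
title: "Threading-based PWM prediction: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threading-based PWM prediction: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the science behind **pwmthread**: the statistical
potential, the threading procedure, every tunable parameter with its
default and rationale, what the synthetic-data generator does and does not
emulate, and the numerical decisions taken where the design was genuinely
open.

## The problem

Transcription factors and other DNA-binding proteins recognize short,
variable sequence families that are conventionally summarized as a
position weight matrix (PWM): an L x 4 column-stochastic matrix of base
probabilities, 5'->3' on a reference strand.  When a co-crystal of the
protein on DNA exists, atomic contacts can be scored directly.  When only
an *unbound* structure exists, a synthetic complex must be built first:
the query protein is rigidly superimposed onto a homologue's protein-DNA
co-crystal (the *template*), the template's protein chains are removed,
and the transformed query is appended to the untouched template DNA.  The
package implements that construction plus everything downstream.

## The knowledge-based potential

### Contact statistics

`build_knowledgebase()` accumulates `N_obs(i, j, r)`, the number of
(protein atom type i, DNA atom type j) heavy-atom pairs at separation in
bin r, over a set of complexes passing the selection filters.  The type
vocabulary is exhaustive over standard residues: 167 protein types (every
heavy atom of the 20 amino acids; terminal OXT excluded) and 82 DNA types
(every heavy atom of DA/DC/DG/DT including the sugar-phosphate backbone;
the 5'-terminal OP3 excluded).  Atoms outside the vocabulary - water,
ions, modified residues - are skipped and tallied.  Distances are binned
at r = 3, 4, ..., 10 Angstrom with widths 3, 1, ..., 1 and the half-open
convention (r - dr, r]: a pair at exactly 3.0 A falls in the first bin, at
exactly 10.0 A in the last, and beyond 10 A contributes nothing.

Selection filters (the `knowledgebase` profile): X-ray method with
resolution strictly better than 3.0 A; exactly one double-stranded DNA;
at least 6 Watson-Crick paired bases with fewer than 30 % of DNA residues
unpaired; at least one protein chain with >= 5 contact residues (any heavy
atom within 4.5 A of DNA); at least one protein chain of >= 40 residues.
The `template` profile drops the single-duplex requirement.  "Exactly one
dsDNA" is operationalized as exactly one chain pair carrying >= 2 detected
base pairs, since the phrase has no unique structural definition.

Watson-Crick pairing itself is detected by complementarity plus a single
distance test - purine N1 to pyrimidine N3 at most 3.5 A - with greedy
one-to-one matching by increasing distance.  No angle criterion is
applied; for near-ideal duplexes the distance test is unambiguous, and it
is trivially reproducible.  Positions are ordered by author residue
number on the reference strand, assumed to ascend 5'->3'.

### From counts to energies

The potential is the standard inverse-Boltzmann log-ratio to an r^alpha
reference state:

$$u(i,j,r) = -\ln\frac{P(i,j,r)}{P_{\mathrm{ref}}(r)},\qquad
P_{\mathrm{ref}}(r) = \frac{r^{\alpha}\,\Delta r}{\sum_{r'} r'^{\alpha}\,\Delta r'},$$

with P(i,j,r) the pair's normalized bin distribution.  Negative u means
the contact is enriched over the reference geometry - the sign convention
is fixed so that *lower energy = favored*, and every downstream rule
(argmin = preferred base) follows from it.

Parameters (`potential_params()`):

| parameter | default | meaning and rationale |
|---|---|---|
| `alpha` | 1.61 | exponent of the reference state; the established calibration for this family of atomic protein-DNA potentials |
| `r_cut` | 10 A | upper edge of the last bin; pairs beyond it score 0 |
| `pseudocount` | 0.1 | per-bin additive count before normalization, so sparse pairs stay finite; 0 restores the bare log-ratio, in which case pairs with no counts at all are "uninformative" and score 0, and empty bins of observed pairs are clamped to the table's strongest finite repulsion rather than +Inf |
| `weighting` | `"none"` | optional distance weighting w(r) of the counts; `"power"` with `gamma` gives w(r) = (r/r_cut)^gamma.  The weighting variant of this potential family emphasizes long-range contacts, but its functional form is not standardized, so it is exposed as configuration and the documented default is the plain log-ratio.  When enabled, weighted counts are renormalized so P still sums to 1 over bins |
| `beta` | 15 | temperature-like divisor of the PWM emission (below) |

### Threading

`position_energies()` substitutes position i through the four Watson-Crick
pairs - base alpha on the reference strand, its complement on the partner
- and sums u over all protein heavy atoms against all heavy atoms of the
two substituted nucleotides within r_cut.  Two deliberate choices:

* **Complementary substitution.**  A PWM describes a duplex motif;
  threading a mismatched pair has no meaning here, so the partner base
  always tracks the complement.
* **Backbone included.**  The per-position sum covers the nucleotides'
  backbone atoms too (their 82-scheme types change with residue identity),
  which keeps the per-position decomposition exactly consistent with the
  whole-complex energy restricted to that position.  `base_only = TRUE`
  restricts the sum to the base moieties for sensitivity analyses.

Base substitution splices idealized base geometry (shipped as a
plain-text table of one conformer per nucleotide) onto the untouched
backbone by superposing the glycosidic frame - C1' plus the glycosidic
nitrogen and its ring anchor (N9/C4 for purines, N1/C2 for pyrimidines),
the classical isosteric triple.  This preserves the native glycosidic
orientation of the position being threaded.  One numerical consequence is
documented rather than hidden: because C1' belongs to the immutable
backbone while N and the anchor move with the base, substituting *across*
base identities is a least-squares fit with a small residual (under
0.05 A in the fixtures), so repeated substitution converges to, rather
than lands exactly on, a fixed point; substituting a base *for itself* is
idempotent to machine precision.

PWM columns follow the Boltzmann rule
$p_i(b) \propto \exp(-\Delta G_i(b)/\beta)$ with a max-shift for
numerical stability.  beta = 15 smooths energies into probabilities; as
beta grows columns tend to uniform, as beta shrinks they concentrate on
the argmin.  Positions with no protein atom within r_cut of any variant
get four equal (zero) energies, hence uniform columns, and are flagged
`contacted = FALSE`: the method is only informative about positions the
protein physically touches.

## Superposition

`build_superimposed_complex()` keeps template DNA (and any non-protein
chains) bitwise untouched, applies one rigid transform `x' = t + U x` to
the whole query, removes all template protein chains, and renames query
chains on id collision.  The transform comes from a structure-alignment
tool's rotation-matrix file (`parse_matrix_file()`, three rows of
`i t(i) u(i,1) u(i,2) u(i,3)`), or from a user-supplied residue
correspondence via the Kabsch least-squares fit (`kabsch()`, proper
rotation enforced, >= 3 non-collinear points).  Structure alignment and
homology search themselves are external: published template-qualification
thresholds (sequence e-value < 0.001, TM-score > 0.5, highest TM-score
wins) apply to scores those external tools report, so the package treats
them as user-checked annotations, not computations.  When an alignment
covers only part of the query, the whole query is still transformed
rigidly - nothing is trimmed.

## Evaluation

The Psi-score is the mean per-position Kullback-Leibler divergence
between annotated (q) and predicted (p) columns, natural log, after
flooring every probability at epsilon = 1e-3 and renormalizing:

$$\Psi = \frac{1}{L}\sum_{j=1}^{L}\sum_{b} q_{jb}\,\ln\frac{q_{jb}}{p_{jb}}.$$

The direction D(annotated || predicted) treats the annotation as truth
and punishes predictions that starve truly favored bases of mass; the
reverse and symmetrized directions are available as options since the
field uses all three.  `align_pwms()` slides the shorter matrix across
every offset fully inside the longer, on both orientations of the
prediction, and keeps the minimal Psi (ties: smaller offset, then forward
strand).  Empirical p-values draw n random PWMs (default 100,000) with
columns uniform on the probability simplex - the maximum-entropy choice
for an unspecified "random PWM" - align each exactly as the prediction
was aligned, and report the add-one estimate (1 + #{Psi_null <= Psi}) /
(n + 1), which can never be zero.  Feeding null draws back through the
procedure yields p-values indistinguishable from uniform (Kolmogorov-
Smirnov, alpha = 0.01, 200 replicates of 2,000 dummies in the shipped
checks).

## The synthetic-data generator

All tests and the acceptance script run on synthetic structures from the
`fixtures` functions; nothing is downloaded.

* `make_bdna()` stacks rigid Watson-Crick pair templates with uniform
  rise 3.38 A and twist 36 deg about a straight axis.  Pair templates are
  built from the idealized nucleotide library by fitting the pyrimidine
  against the purine along a common hydrogen-bond direction (N1-N3 about
  2.86 A); every strand-1 C1' sits at the same pair-frame position, so
  consecutive C1'-C1' distances are exactly regular, and each backbone is
  spun about its glycosidic axis by a fixed angle (200 deg) chosen once,
  by grid search, to keep stacked nucleotides clash-free.
* `make_toy_complex()` adds a poly-alanine chain placed on a distant arc
  and relocates designated CB atoms to planted distances from designated
  DNA atoms (choosing, among a fixed fan of outward directions, the one
  with the best clearance), with a 1.5 A clash guard.  Resolution 2.0 A
  and an X-ray method string are stamped on so the selection filters can
  be exercised both ways.
* `make_planted_kb_corpus()` plants a base preference: the probe CB sits
  3.4 A off the preferred base's major-groove edge (N7 for purines, C5
  for pyrimidines) at a fixed duplex position, five further CBs touch
  backbone phosphates at sequence-neutral positions (so the complex
  passes the knowledgebase filters), and the rest of the sequence is
  random.  A knowledgebase built from such a corpus concentrates
  short-range counts on the preferred base's atom types, and threading a
  held-out complex recovers the preference - the package's end-to-end
  self-check, run at 50 complexes per corpus over 20 seeds.

What the fixtures deliberately do **not** emulate: sequence-dependent
helical geometry, sugar repuckering, protein folds, solvent, crystal
packing, or chemically bonded backbones (nucleotides are placed as rigid
bodies; chain connectivity is cosmetic).  Passing the shipped checks
therefore demonstrates the correctness of the counting, potential,
threading and scoring machinery - not predictive accuracy on real
co-crystals, which additionally depends on the quality of the structure
database, the template choice, and above all the conformational change
between unbound and bound forms.

## Numerical choices and degenerate inputs

* Bin lookup is `max(3, ceiling(d))` with d > 10 excluded - exactly the
  half-open convention; cross-distance matrices are computed coordinate-
  wise so constructed boundary distances bin exactly.
* Multi-model files: model 1 by default; alternate locations resolve to
  the highest occupancy, ties to file order; hydrogens are dropped
  everywhere (the typing scheme is heavy-atom based and most X-ray
  entries lack H).
* Empty intersections are values, not errors: no pairs in range gives
  ΔG = 0, an empty contact set is allowed, and a superimposed complex
  whose protein never approaches the DNA warns (the prediction will be
  uninformative) instead of failing.
* Refusals: an empty knowledgebase (zero surviving complexes), reflective
  "rotations" (det U = -1), degenerate Kabsch inputs, unpaired positions
  in `substitute_base_pair()`, and PWM length mismatches in `psi_score()`
  (align first).
* Serialized artifacts (knowledgebase TSV, potential TSV, PWM files,
  JSON reports) embed their parameters and a checksum where integrity
  matters; loading a truncated or out-of-vocabulary file is an error that
  names the offender.

## Problem sizes

The shipped test-suite and acceptance script use 8-bp duplexes,
45-residue synthetic proteins, corpora of 50 complexes x 20 seeds for
recovery, 100 random atom clouds for exhaustive pair-count
cross-checks, 50 random rigid motions for invariance, and null ensembles
of 2,000-100,000 random PWMs - sizes chosen so every property is
exercised at meaningful scale on a single CPU.

## Known limitations

* Rigid-body superposition cannot model the unbound-to-bound
  conformational change, which is the dominant error source for unbound
  queries; ensemble or flexible variants are out of scope.
* The position-independence assumption excludes dinucleotide and higher-
  order dependencies by construction.
* Modified nucleotides and non-standard residues are skipped, not
  modeled; mmCIF input is not yet supported.
* Predictions are only informative at contacted positions; columns
  flagged `contacted = FALSE` are uniform by design.
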
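# pwmthread

Predicts the DNA sequences a DNA-binding protein recognizes — as a
position weight matrix (PWM) — from structure alone.  Transcription
factors read the double helix through atomic contacts; given a protein–DNA
complex (a native co-crystal, or a synthetic complex built by
superimposing an unbound query protein onto a homologue's co-crystal), the
package threads every Watson–Crick position of the duplex through all four
base identities, scores each variant with an atomic knowledge-based
potential, and converts the per-position binding free energies into PWM
columns.  It is aimed at structural bioinformaticians studying
protein–DNA recognition, in particular the hard case where the query
protein has **no** co-crystallized structure of its own.

## The model

**Contact statistics.**  From a curated set of protein–DNA co-crystals
(X-ray, resolution better than 3.0 Å, one duplex with ≥ 6 paired bases and
< 30 % unpaired, ≥ 5 contact residues within 4.5 Å, a protein chain of
≥ 40 residues) the package counts `N_obs(i, j, r)` — pairs of protein atom
type `i` (167 types, every heavy atom of the 20 amino acids) and DNA atom
type `j` (82 types, every heavy atom of DA/DC/DG/DT including backbone) at
separations in bins `r = 3, 4, …, 10` Å (`Δr = 3` for the first bin, 1
after, interval `(r−Δr, r]`).

**Potential.**  The pair potential is the inverse-Boltzmann log-ratio to
an `r^α` reference state,

    u(i, j, r) = −ln [ P(i, j, r) / P_ref(r) ],
    P(i, j, r) = N_obs(i, j, r) / Σ_r N_obs(i, j, r),
    P_ref(r)   = r^α Δr / Σ_r r^α Δr,       α = 1.61,  r_cut = 10 Å,

with zero contribution beyond the cutoff and for type pairs never
observed.  The binding free energy of a complex, ΔG, is the sum of `u`
over all protein–DNA heavy-atom pairs in range.

**Threading and emission.**  Assuming positions contribute independently,
each paired position `i` is substituted in silico through the four
Watson–Crick pairs (idealized base geometry spliced onto the untouched
sugar–phosphate backbone), giving energies `ΔG_i(b)` for `b ∈ {A,C,G,T}`
and columns

    p_i(b) = exp(−ΔG_i(b) / β) / Σ_b' exp(−ΔG_i(b') / β),   β = 15.

Positions with no protein atom within the cutoff are reported uniform and
flagged: the method can only speak about bases the protein physically
touches.

**Evaluation.**  Predicted and annotated PWMs are compared by the mean
per-position Kullback–Leibler divergence (Ψ-score; 0 = identical, smaller
is better), minimized over all offsets and both strands, with empirical
p-values from 100,000 random PWMs drawn column-wise from the flat
Dirichlet.

## Worked example

The package ships a synthetic-fixture generator (idealized B-DNA plus toy
poly-alanine proteins with planted contacts) so the full pipeline runs
without downloading a single structure:

```r
library(pwmthread)

# 50 synthetic complexes whose probe atom reads guanine in the major groove
corpus <- make_planted_kb_corpus(n = 50, preference = "G", seed = 1)
kb  <- build_knowledgebase(corpus, filter_profile("knowledgebase"))
pot <- derive_potential(kb, potential_params(alpha = 1.61, beta = 15))

# thread a held-out complex built the same way
held <- make_planted_complex("G", seed = 99)
pw   <- predict_pwm(held, detect_duplex(held), pot)
print(pw)
```

```
<pwm> 8 positions, consensus TATGCATC
       A     C     G     T
1* 0.133 0.252 0.240 0.376
2* 0.380 0.216 0.266 0.138
3* 0.056 0.234 0.071 0.639
4* 0.049 0.030 0.903 0.019
5* 0.136 0.517 0.296 0.051
6* 0.378 0.155 0.330 0.137
7* 0.165 0.212 0.282 0.341
8* 0.254 0.301 0.202 0.244
  (* = position contacted by protein)
```

Position 4 — the planted contact — is read as G with probability 0.90;
the flanking columns stay close to uniform because nothing specific
touches them.  Scoring against the planted motif:

```r
truth <- pwm(rbind(matrix(0.25, 3, 4),
                   c(0.01, 0.01, 0.97, 0.01),
                   matrix(0.25, 4, 4)))
evaluate_pwm(pw, truth, n = 10000, seed = 7)
#> <psi_result> psi = 0.1383 at offset 0 (forward), L = 8, p = 0.0002
```

For real structures the same pipeline is driven by `cmd_build_kb()` (a
directory of PDB files), `cmd_predict()` (query PDB + template complex +
rotation-matrix file from a structure-alignment tool, e.g. TM-align) and
`cmd_evaluate()`, or from the shell via `inst/cli/pwmthread`.

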
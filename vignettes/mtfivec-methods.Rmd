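---
title: "Methods: calling m5C and f5C in mitochondrial tRNA with mtfivec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling m5C and f5C in mitochondrial tRNA with mtfivec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtfivec)
```

## The biological problem

The wobble base C34 of the mitochondrially encoded methionine tRNA
(mt-tRNA^Met^, gene *MT-TM*, mtDNA position 4432 on the rCRS) carries a
cytosine-5 modification cascade: an m^5^C writer methylates unmodified C34,
and oxidation then produces 5-formylcytosine (f^5^C). Three sequencing
chemistries probe this cascade, but none resolves it alone:

* **BS RNA-Seq.** Bisulfite deaminates unmodified C *and* f^5^C to U (read
  as T); m^5^C and hm^5^C are protected and read as C. The non-conversion
  level at a cytosine therefore estimates the combined m^5^C + hm^5^C
  fraction and is blind to f^5^C.
* **RedBS-Seq.** NaBH~4~ reduces f^5^C to hm^5^C before bisulfite, so
  f^5^C becomes protected; the level estimates m^5^C + hm^5^C + f^5^C.
* **fCAB-Seq.** *O*-ethylhydroxylamine adducts protect f^5^C directly,
  with the same read-out.

The per-site difference (RedBS or fCAB minus BS), clamped to [0, 1], is
the package's f^5^C estimator. m^5^C and hm^5^C are never separated — the
chemistry cannot do it, so the package reports them as one bundle.

Orthogonally, **miCLIP** localises the writer's target cytosines: a
catalytically trapped methyltransferase mutant stays covalently bound to
the cytosine it attacks, reverse transcription stalls at the
peptide-bearing adduct, and cDNA 5′ ends pile up adjacent to the
methylated C. **HITS-CLIP** footprints (~30–60 nt) give independent,
coarser evidence of binding, tested per gene against a control
immunoprecipitation.

## Module overview and model assumptions

`refmodel` holds the coordinate authority: contigs, BED6(+biotype) gene
annotations, and tRNA layouts giving the sequential index of the first
anticodon base (the wobble position). Internally all intervals are 0-based
half-open (BED convention); every user-facing position is 1-based, so that
*MT-TM*'s wobble base reports as 4432. Sequential indices are used
throughout: universal tRNA numbering with its insertions/deletions is not
modelled, layouts carry the sequential index of the wobble base directly.
`U` is mapped to `T` at load time; all downstream logic is DNA-alphabet.

`simulate` draws ground-truthed molecule populations (per-position
modification states, multinomial per site) and renders them into FASTQ
libraries. `miclip` and `bsdeconv` must then recover the truth; every
headline check in the test suite is a parameter-recovery experiment of
this form.

`miclip` re-implements, at toy scale, the documented behaviour of the
standard read-processing chain:

1. split-UMI parsing (UMI at read positions 1–3 and 8–10, sample barcode
   at 4–7, insert from 11);
2. exact barcode demultiplexing and PCR deduplication — the cDNA count of
   a unique insert is its number of distinct UMIs;
3. 3′ adapter trimming with minimum overlap 4 and error rate 0.06,
   substitutions only (see *Numerical choices*);
4. length filter at 18 nt;
5. unique best-stratum alignment allowing one mismatch: a read is kept
   only if its best non-empty mismatch stratum holds exactly one hit
   across all contigs and strands;
6. truncation-to-cytosine assignment within a ±2 nt window;
7. per-replicate RPM normalisation (counts per million uniquely mapped
   cDNA counts) and the high-confidence rule: RPM strictly above 50 in at
   least 2 of 3 replicates.

`bsdeconv` aligns directional bisulfite reads with three-letter collapsed
matching (read and forward reference C→T; reverse-complemented read and
reference G→A for minus-strand placement), counts per-cytosine conversion
states, applies a ≥ 5× coverage floor, and forms the difference
estimators with binomial standard errors.

`hitsclip` counts uniquely aligned reads (> 20 nt) per gene by maximal
overlap and applies a conditional negative-binomial exact test with fixed
dispersion 0.1: conditioned on the pair sum *s*, the two-sided p-value
accumulates all splits (*x*, *s − x*) whose joint NB probability does not
exceed the observed one.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `threshold_rpm` | 50 | high-confidence site floor, strict `>` (literal reading of the protocol's "> 50 RPM") |
| `min_replicates` | 2 of 3 | replicate support rule |
| adapter overlap / error | 4 / 0.06 | trimming emulation of the cited trimmer settings |
| `min_len` | 18 nt | insert length floor |
| truncation `window` | ±2 nt | search window around the RT stall |
| `min_coverage` | 5× | bisulfite level floor; the protocol wording ("> 5 reads (5×)") is self-contradictory and we resolve it as ≥ 5, exposed as a flag |
| `gamma` | 0.005 | bisulfite non-conversion of unmodified C; typical libraries report ~0.2–1% |
| `rho`, `pi_protect` | 0.9 | NaBH~4~ reduction and *O*-ethylhydroxylamine protection efficiencies; unquantified in the protocols, configurable, and only used when explicit efficiency correction is requested |
| `dispersion` | 0.1 | fixed NB dispersion of the exact test; no dispersion estimation is attempted (single-replicate design) |

## The synthetic-data generator

The generator is first-class, tested code: its defaults define the study
conditions under which recovery is demonstrated.

* **Molecule populations.** Per-site state mixtures over {C, m^5^C,
  hm^5^C, f^5^C}. The default wild-type wobble mixture is 30% m^5^C(+
  hm^5^C), 37% f^5^C, 33% unmodified (`wt_wobble_composition()`). The two
  orthogonal formyl-chemistries report 36% and 38% for the same
  underlying f^5^C fraction; a single simulated truth cannot centre both
  read-outs at once, so the generator fixes the midpoint, 37%, and the
  recovery checks compare each chemistry's estimate against its own
  published value at 3 binomial standard errors. The null
  (methyltransferase-deficient) condition is 100% unmodified C.
* **Chemistry.** Per-position independent Bernoulli conversion by state;
  in the ideal limit (γ = 0, ρ = π = 1) the truth table is exact and is
  asserted exhaustively over all states × chemistries.
* **miCLIP reads.** Crosslink sites drawn proportionally to per-cytosine
  weights; the RT stall leaves the insert starting one base 3′ of the
  adduct, jittered by an offset δ ∈ ±2 (default mass 0.55 at 0, decaying
  outwards — the empirical stall distribution is unreported, so this is a
  free simulation parameter). Insert 3′ ends are drawn uniformly over
  18–45 nt (clipped at the transcript end), emulating the variable
  fragment boundaries of partial RNA digestion; besides realism this
  keeps distinct cDNAs distinguishable, so 6-nt UMI collisions remain the
  small perturbation the counting model assumes. Raw reads carry the
  3 + 4 + 3 nt UMI/barcode prefix, adapter read-through on short inserts,
  geometric PCR duplication (mean 2) and a 10^-3^ per-base substitution
  error rate. Quality is constant Q40: quality trimming is not simulated.
* **Toy references.** `toy_mt_bundle()` is a synthetic ~1.1 kb contig
  with six loci (four tRNAs — one on the minus strand — and two mRNA
  loci) whose default crosslink weights reproduce the published
  mitochondrial miCLIP composition: *MT-TM* 26% of mitochondrial cDNAs
  and 60% of tRNA-locus cDNAs, *MT-ND1* 15%, *MT-TL1* 5%, *MT-TS2* 4.5%,
  the remainder split between the fourth tRNA (to close the 60% tRNA
  share) and the large mRNA locus. Designated sites are planted with a
  C-free ±4 nt context so that truncation assignment is unambiguous for
  every offset. `toy_trna_catalogue_bundle()` carries the eight
  catalogued mitochondrial tRNA m^5^C positions across six tRNAs.
  `rcrs_mttm_bundle()` places *MT-TM* at its true rCRS boundaries
  (4402–4469) on an otherwise synthetic contig; every coordinate
  computation on it depends only on the annotation.

What the generator does **not** emulate: quality-score error models,
indels, RNA secondary structure (and hence structure-induced false
priming or truncation), precursor-versus-mature tRNA pools (a knob left
unexplored), non-directional bisulfite libraries, and genome-scale
references. Passing recovery tests therefore demonstrate correctness of
the inference chain under the stated sampling model — not robustness to
artefacts real libraries may contain.

## Numerical choices

* **Truncation geometry.** Whether the read's first base is the
  crosslinked C or its neighbour is undocumented; simulator and caller
  share one convention — the stall sits one base 5′ (transcript sense) of
  the first aligned base — and the assignment window of ±2 nt absorbs the
  jitter. Equidistant candidate cytosines resolve to the 5′ side, the
  side the adduct biases.
* **Trimming dialect.** Substitution-only suffix/prefix matching with
  error budget `floor(0.06 × overlap)`; order-independent and
  reproducible, but not byte-identical to the cited trimmer (no indels).
* **Alignment.** Best-stratum uniqueness approximates the cited aligner's
  `-m 1 -v 1 --best --strata`; it is checked against an exhaustive scan
  oracle on 10^4^ reads. Bisulfite alignment is directional only.
* **RPM denominator.** The protocol text ("pooled read counts … were
  normalized") is ambiguous against the 2-of-3 replicate rule; we
  normalise per replicate and then apply the replicate rule.
* **Exact test ties.** The two-sided rule sums all splits with
  probability ≤ the observed one; a 10^-12^ relative tolerance guards
  floating-point ties. At dispersion 1 every split is exactly
  equiprobable (the NB with size 1 is geometric) and the test correctly
  returns p = 1. Unequal library sizes are handled by rescaling both
  counts to the geometric-mean effective size — an approximation to
  quantile adjustment, stated in the documentation.
* **Level denominator.** Read bases other than C/T at a reference C are
  excluded from the level denominator and logged as `n_other`.
* **Zero-coverage and clamping.** Levels need ≥ 5× coverage; difference
  estimators clamp at 0, so "no f^5^C detected" is read statistically:
  an estimate within 3 standard errors of zero.

## Problem sizes

The bundled checks use 10^4^ molecules per chemistry for the wobble-base
deconvolution, 5 × 10^4^ cDNAs for composition recovery, 200× coverage
for the site-catalogue recovery, and 10^4^ reads for the alignment
oracle — sizes at which binomial/multinomial standard errors are a few
per mille to a few per cent, chosen so every comparison is made at 3
standard errors of its own sampling noise.

## Known limitations

* m^5^C and hm^5^C are inseparable by design; f^5^C estimates are lower
  bounds when reduction/protection is incomplete (the optional ρ/π
  correction divides the difference, it does not model joint
  likelihoods).
* The difference estimator ignores covariance between chemistries
  (separate libraries, so independence holds in the simulation and
  approximately in practice).
* No differential-methylation hypothesis test is attached to condition
  comparisons — none is defined for this design; deltas carry pooled
  binomial errors only.
* The alignment engine is for toy/mitochondrial-scale references, not
  nuclear genomes.
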
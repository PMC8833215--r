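---
title: "Decoding a DEL-versus-RNA-library screen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding a DEL-versus-RNA-library screen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnadel)
```

## The screening problem

`rnadel` implements the computational side of a library-versus-library
screen: a DNA-encoded library (DEL) of small molecules on beads is incubated
simultaneously with a fluorescently labeled RNA *fold* library and a
base-paired counter-screen RNA, selective beads are sorted, and both sides
of every interaction are read out by sequencing. Three statistical problems
arise, and the package treats each as a module:

1. **Barcode deconvolution** — turn sequencing reads from sorted beads back
   into compounds, with replicate counting and two-channel selectivity
   filtering (`decode_beads()`, `selectivity_filter()`, `cluster_hits()`).
2. **Fold enrichment** — decide which of the 4,096 RNA internal-loop folds a
   compound prefers, by comparing selected-pool frequencies against the
   starting library (`z_obs()`, `call_privileged()`, `position_profile()`).
3. **Target nomination** — locate those privileged folds in microRNA
   hairpins, asking specifically whether they fall in Drosha or Dicer
   processing sites, where a bound ligand can block biogenesis
   (`mine_motifs()`, `rank_targets()`, `mining_summary()`).

A fourth module generates synthetic inputs with planted ground truth for
every stage, so the full pipeline is testable without any external data.

## The combinatorial library and its DNA encoding

The DEL is a split-pool library: one of 96 amino acids (cycle 1), a central
proline-derived hub used as a stoichiometric mixture of two diastereomers,
and one of 192 carboxylic acids (cycle 2) installed at either of two
positions — the pendant secondary amine (R2) or, after azide reduction, the
primary amine (R3). That yields

$$ 96 \times 192 \times 2_{\text{acylation}} \times 2_{\text{stereo}} = 73{,}728 $$

compounds. Hub stereochemistry is a property of the synthesis mixture, not
of any split, so it is *not encoded*: the tag space holds
$96 \times 192 \times 2 = 36{,}864$ distinct barcodes and every tag-level
"hit" denotes a diastereomer pair. All decoding, filtering and clustering
operate at tag level; stereochemistry is resolved downstream when hits are
resynthesized as pure diastereomers.

Each tag is positional: `primer5 | codon(R1) | codon(acid) |
codon(acylation) | primer3`. The published barcode sequences are not
bundled, so the scheme is contract-driven instead: `assign_codons()` draws
codons in a seeded deterministic order from the full 4^L space and accepts
greedily under a pairwise Hamming-distance floor. Defaults are 8-nt codons
with minimum distance 3, which accommodates the 290 codons needed with a
large margin and guarantees that any read with at most one substitution per
codon (`max_mismatch_per_codon = 1`, i.e. errors strictly below half the
design distance) decodes uniquely. Primers are matched exactly — they are
the anchors that define the reading frame — and codons are forbidden from
occurring inside the primers.

Beads are called by majority vote over their decoded reads; ties and
decode-free beads are dropped and logged rather than guessed. The replicate
class *k* (distinct beads per compound per channel) is the screen's internal
confidence measure, and the selectivity filter is a hard set difference:
a compound observed on any counter-channel bead is removed. Hit triage uses
deterministic leader clustering at Tanimoto 0.8 on block-one-hot
fingerprints (one bit per synthetic choice); seeds are processed in
decreasing *k* with lexicographic tie-breaks, which makes the partition
independent of input order. Structure-based fingerprints are a pluggable
hook (`fingerprint(..., mode = "STRUCTURE", structure_fp = )`) so a
cheminformatics toolkit can be substituted without changing the clustering
contract.

## The RNA fold library

The RNA library displays six randomized nucleotides as a potential 3×3
internal loop inside a hairpin cassette: a top 3-mer written 5'→3' over a
bottom 3-mer written 3'→5', i.e. 4^6 = 4,096 folds. The canonical notation
`5'XXX/3'YYY` allows base pairs *inside* the window — `5'GAG/3'CCC` is
really a 1×1 A·C loop closed by two G:C pairs. Two consequences drive the
implementation:

* `extract_internal_loops()` reports loops as they exist in a structure
  (sizes `a × b` with closing pairs, GU accepted as a closing pair), and
* `window_3x3()` reconciles sub-3×3 loops with the library's 6-nt window by
  padding with aligned closing base pairs, split as evenly as possible:
  a 3×3 loop is its own window, a 1×1 loop has the unique
  pad-one-pair-each-side window, a 2×2 loop the two one-sided choices.
  Because a pad is a base *pair* (one nucleotide on each strand),
  asymmetric loops (`a != b`) cannot be written as an aligned 3×3 window
  and return an empty window set; bulges (`a = 0` or `b = 0`) are reported
  but excluded from matching, since the library is an internal-loop
  pattern. A loop "matches" a motif if *any* of its windows does.

The default cassette (12-nt tails, 6-bp GC-rich stems, UUCG tetraloop) is
config, not biology: the true selection cassette can be dropped into
`build_hairpin()` via the `scaffold` argument. The build→extract→window
round trip is the identity on all 4,096 members, verified exhaustively in
the test suite (it runs in seconds).

A deterministic Nussinov base-pair-maximization fold (`nussinov_fold()`,
Watson–Crick + GU, minimum hairpin loop 3, leftmost-partner traceback) is
included strictly as a convenience for synthetic constructs. It is not a
thermodynamic model, and mining treats secondary structures as *inputs*:
real hairpin structures come from upstream prediction, and structureless
hairpins are only folded on explicit request (with a warning).

## The enrichment statistic

For each fold the selection yields a 2×2 table: `x_sel` of `n_sel` selected
reads versus `x_lib` of `n_lib` starting-library reads. The package scores
it with the pooled two-proportion z statistic

$$ Z_{obs} = \frac{\hat p_{sel} - \hat p_{lib}}
  {\sqrt{\hat p (1-\hat p)\left(\tfrac{1}{n_{sel}} + \tfrac{1}{n_{lib}}\right)}},
  \qquad \hat p = \frac{x_{sel} + x_{lib}}{n_{sel} + n_{lib}}, $$

whose square is the 1-df chi-square statistic of the table without
continuity correction — an identity the tests verify against
`chisq.test()` to 1e-9 on random tables. The pooled-variance form is the
natural reading of a "pooled population comparison"; an unpooled variant is
available behind `pooled = FALSE` for sensitivity analysis. Degenerate
tables (pooled proportion 0 or 1) return 0. Folds with
$Z_{obs} > 4$ are called *privileged*; the cutoff is a fixed,
empirically motivated operating point, and no further multiple-testing
correction is applied — the calibration question is instead answered
directly: under null multinomial simulations at depth 10^5 the privileged
fraction sits within Monte-Carlo error of the standard normal upper tail at
z = 4 (≈3.2e-5), and the z distribution itself passes a KS comparison
against N(0,1) at distance < 0.05.

When a compound is selected at several doses, per-dose results are always
emitted and the compound's privileged set is the union over doses. (An
alternative convention — scoring only the most stringent dose — is easy to
apply downstream from the per-dose rows; the union is the more conservative
default for target nomination, since a fold bound at any stringency is a
candidate liability or opportunity.)

Sequence preferences are summarized as position profiles: 4×6 frequency
matrices with per-position information content $2 - H_i$ bits, optionally
$Z_{obs}$-weighted. The small-sample correction $3/(2\ln 2\, n)$ is off by
default and flag-controlled. Profile pairs (e.g. the two hub diastereomers
of one compound) are compared by per-position Jensen–Shannon divergence in
base 2, which is symmetric, bounded by 1 bit, and zero only for identical
columns.

## Processing-site mining

Mature-arm annotations imply the nuclease geometry of a hairpin: Drosha
cuts at the 5' end of the 5p arm and the 3' end of the 3p arm, Dicer at the
other two arm boundaries. Coordinates are 1-based inclusive in all file
formats (the miRBase/GFF convention) and 0-based inter-nucleotide *bond*
indices for cuts, stated once and enforced by round-trip tests.

A privileged loop is "in" a processing site when one of its unpaired runs
spans a cleavage bond or lies within `K` nucleotides of it. The membership
window is genuinely a free parameter — there is no standard definition of
"in the processing site" — so it is config with default `K = 2` nt, chosen
so that a loop abutting the scissile bond or separated from it by at most
one closing base pair still counts, while loops a full helical turn away do
not. Every loop occurrence is reported (site `NONE` otherwise), so tandem
copies of a motif near one site are visible individually.

Candidate targets are ranked by mature-miRNA expression (reads per
million): at a fixed ligand dose, the more abundant of two RNAs sharing a
binding site is proportionally more occupied, so expression is the main
prioritization axis between otherwise equivalent sites. Fold differences
are reported to two significant figures, with zero-rpm competitors flagged
as infinite rather than silently dropped. Disease association is an input
flag per hairpin; curating it is out of scope.

## What the synthetic data does and does not emulate

The generators produce every pipeline input with machine-readable truth:

* `simulate_bead_reads()` — per planted bead, a fixed number of tag reads
  with i.i.d. per-base substitutions. Substitution-only by design: the
  positional barcode layout makes indel tolerance a decoder extension, not
  part of the screen's claims. No PCR duplication or amplification-bias
  model.
* `simulate_2dcs_counts()` — paired multinomials at equal depth: uniform
  over the 4,096 folds for the starting library, proportional to planted
  enrichment factors for the selection. Real starting libraries are
  sequenced, not theoretical, which is why library counts are an input
  table in the analysis path and the uniform model lives only here.
* `simulate_mirnome()` — stem-loop hairpins with a fixed geometry (10-nt
  flanks, 11-bp lower stem, 22-nt arms, 9-bp upper stem, UUCG tetraloop;
  ~108 nt total, in the pri-miRNA size range), exact dot-bracket
  annotation, and motif windows planted at requested distances from the
  Drosha/Dicer bonds. All non-planted duplex columns are Watson–Crick
  pairs, so planted loops are the only internal loops and recovery can be
  asserted exactly. Expression is log-normal (median 500 rpm,
  $\sigma_{\log} = 2$): the model is a choice, not a fit, made because
  real small-RNA expression spans orders of magnitude with a heavy right
  tail.

Passing recovery tests on these inputs demonstrates the *pipeline logic* —
decoding, statistics, coordinate conventions — under known truth. It does
not demonstrate performance on real screens, where reads carry indels and
quality structure, starting libraries are non-uniform, hairpin structures
are predictions with their own error, and the miRnome's loop content is far
denser than a planted toy.

## Numerical and policy choices

* Degenerate inputs: empty motif sets error; empty counter channels are the
  identity filter; zero-rpm ratios are `Inf`; z on degenerate tables is 0.
* Tie-breaks are total and documented: clustering seeds by (k desc, tag id
  asc); cluster representative likewise; Nussinov traceback prefers pairing
  and the leftmost partner. Reruns are byte-identical for a seed, asserted
  in the CLI tests.
* All randomness flows through private seeded RNG streams that restore the
  caller's `.Random.seed`.
* Test and calibration problem sizes: selection depth 10^5 per pool, 50
  null replicates (≈205k null statistics), the exhaustive 4,096-member
  structural round trip, and 100-bead noisy-decode Monte Carlo; the full
  suite runs in well under a minute.

## Known limitations

* The barcode scheme is contract-compatible with the published screen, not
  sequence-identical; decode results on real reads require loading the true
  codon tables (`read_building_blocks()`, `read_scheme()`).
* Asymmetric internal loops are never matched to the 3×3 library (see
  above); they are still extracted and visible to callers.
* `nussinov_fold()` maximizes pair count only — do not use it as a
  structure predictor for real hairpins.
* Affinity is not modeled: the z statistic ranks enrichment, and any
  mapping to dissociation constants is experimental work outside this
  package.
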
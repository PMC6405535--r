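---
title: "Methods: PCR-RFLP diagnostics and mitogenome quality control for Helicoverpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PCR-RFLP diagnostics and mitogenome quality control for Helicoverpa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitokey)
```

# The problem

Five noctuid moths — *Helicoverpa armigera*, *H. punctigera*, *H. assulta*,
*H. zea* and *H. gelotopoeon* — are major crop pests with overlapping ranges
and near-identical adult morphology. Two practical needs drive this package:

1. **Field diagnostics.** PCR-RFLP is the cheapest molecular identification:
   amplify a short mitochondrial COI fragment, digest it with a restriction
   enzyme, and read the band pattern on a gel. Historically two incompatible
   assays existed (different amplicons, partial species coverage). The
   consolidated key implemented here covers all five species from either of
   two COI amplicons — a 698 bp 5' fragment or a 511 bp 3' fragment — each
   with a panel of four enzymes.
2. **Database hygiene.** Public mitogenomes are sometimes wrong: a genome can
   be deposited under the wrong species (a misidentified specimen) or be a
   *chimeric assembly* stitched from two species when PCR amplicons were
   cross-contaminated. Both failure modes are detectable from sequence alone,
   and both occurred among deposited "*H. assulta*" mitogenomes. The QC half
   of the package automates the detection logic: nucleotide-identity
   screening for misidentification and diagnostic-SNP donor tracking for
   chimera breakpoints.

# In-silico digestion

An enzyme is a (possibly degenerate) IUPAC recognition motif plus two cut
offsets, `cut_top` and `cut_bottom`, measured from the motif's first base;
offsets may exceed the motif length for downstream cutters (`GGTCTC(1/5)`
means the top strand is cut one base past the site). Site scanning matches
the motif on both strands (bottom-strand cut coordinates transformed to
top-strand space); palindromic motifs are scanned once so sites are never
double-counted.

Two conventions matter and are deliberate:

* **Top-strand cut arithmetic.** Fragment lengths are consecutive
  differences of sorted top-strand cut coordinates. This is the
  single-number arithmetic gel tables use, and it makes fragment lengths sum
  exactly to the amplicon length. A consequence worth knowing: digesting the
  reverse complement mirrors the fragment list exactly only for blunt
  cutters. A sticky-end cutter shifts every cut by the constant overhang
  `cut_top − cut_bottom`, so internal fragments are preserved but the two
  terminal fragments move by that amount. The property tests encode exactly
  this.
* **Strict ambiguity semantics.** Degenerate letters in the *motif* match
  their IUPAC expansion; any non-ACGT letter in the *subject* never matches.
  Assembled mitogenomes carry a low-complexity 5N spacer at the origin of
  replication, and strict mode guarantees such regions can never produce
  phantom cuts.

The scanner is a hand-written bitmask matcher. Its correctness is pinned two
independent ways: against `Biostrings::matchPattern` (with an explicit
N-window filter) on 10^4 random kilobase sequences, and against a naive
per-position loop at smaller scale.

# The diagnostic key

The key is a species × region × enzyme table of expected fragment multisets
(uncut = one full-length fragment), validated on load: every pattern must
sum to its region length and every species must cover every enzyme.
Classification compares observed fragment multisets per enzyme and ranks
species by the number of mismatching enzymes; fragments are matched
one-to-one after sorting, with a per-fragment length tolerance (0 bp for
in-silico patterns; ~20 bp is a sensible starting point for gel estimates).

`minimal_panel()` enumerates all enzyme subsets in increasing cardinality —
at most 2^8 for a packaged region, so exhaustive search is exact — under two
scoring modes. Presence/absence scoring uses only cut/uncut states (a quick
gel read-out): the 511 bp region then needs all four enzymes, and no
three-enzyme subset works. Size-aware scoring compares full fragment
multisets: three enzymes suffice, because the one enzyme that cuts both
*H. assulta* (267+244) and *H. gelotopoeon* (458+53) separates them by
fragment size alone. Ties among equally minimal panels are all reported.

Two packaging decisions resolve ambiguities in the published 698 bp table,
whose column headers are garbled in print:

* BseJI and BsaBI are isoschizomers (both `GATNN^NNATC`). The only reading
  of the 698 bp table in which every row is simultaneously realizable by an
  actual sequence places the two identical *H. assulta* cut columns under
  the isoschizomer pair and *H. zea*'s 584+114 pattern under BsaI. That is
  the packaged default; the alternate mapping ships alongside
  (`key_coi_rflp_altmap.tsv`) for classifying externally supplied patterns,
  with a header explaining why no sequence can realize its *H. zea* row.
* Recognition sequences for the trade names Bco5I and AquVI are not public
  alongside the key. The packaged enzyme table defines them with clearly
  commented synthetic placeholder motifs, chosen non-degenerate,
  non-palindromic and non-interacting with the rest of the panel. All
  internal arithmetic is consistent (fixtures plant these motifs), but these
  two entries must not be used to predict digests of empirical DNA.

On the 698 bp region *H. armigera* and *H. gelotopoeon* are both uncut by
every enzyme, so that region alone cannot separate them; the classifier
reports the ambiguity and the CLI points users at the 511 bp region. This
is a property of the published key, not of the implementation.

# Nucleotide identity and the misidentification screen

Percent identity is computed from a global affine alignment (match +1,
mismatch −1, gap open −2, gap extend −0.5): matched columns over aligned
columns, excluding columns where both sequences gap and columns where either
has an undetermined base (so the 5N spacer cannot depress identity);
gap-versus-base columns count as mismatches. Values are reported to two
decimals. Short sequences (genes) use full dynamic programming via
Biostrings; whole mitogenomes use a banded affine aligner written in C++
(band 200, widened automatically by the length difference), which is exact
for near-collinear molecules at these divergences and is score-checked
against full dynamic programming at ≤ 2 kb. Sequences whose lengths differ
by more than 2× are compared over their best local core, with a warning.

The identity structure of these moths is strongly bimodal: conspecific
mitogenomes sit near 99.5% while even the closest species pair
(*H. armigera*–*H. zea*) averages ~97.2%. The screen exploits that gap. A
query labelled species X is compared to at least one reference per candidate
species; the verdict is

* `misidentified` when the best species beats the label by ≥ 2 percentage
  points (`margin`) and the best identity clears a conspecific floor of 98%
  — both thresholds sit inside the empirical gap between conspecific
  (≥ ~98.9%) and interspecific (≤ ~97.4%) values, and both are configurable;
* `chimeric_suspect` when the per-gene best-species assignments are bimodal
  (at least `min_genes = 2` genes best-matching each of two species) — the
  hand-off trigger to the chimera scanner;
* `consistent` / `inconclusive` otherwise.

# Chimera localization

The scanner formalizes how one reads a published SNP alignment table by eye.
Given a query and two candidate donor panels:

1. align everything onto query coordinates (banded alignment);
2. keep the columns where at least one individual differs from the query
   (`build_snp_matrix`; the packaged tables use the same structure with `.`
   meaning "same as the reference row");
3. at each column where the two donor consensuses differ (a *diagnostic
   site*), call the query `A_donor`, `B_donor`, or `neither` (private
   allele). Donor consensus requires unanimity — sites with intra-donor
   variation are demoted to uninformative rather than risking false
   diagnostic sites from within-species polymorphism;
4. report maximal runs of at least `min_run` consecutive same-donor calls.
   `neither` and uninformative sites are skipped without breaking a run; an
   opposite-donor call breaks it. The breakpoint interval before a segment
   spans from the previous segment's last site to this segment's first site
   — the resolution limit imposed by diagnostic-site spacing.

Run-length segmentation was chosen over an HMM deliberately: the underlying
published analysis is a visual run inspection, an HMM would add parameters
nothing in the data can calibrate, and at these divergences (diagnostic site
every ~20–50 bp) runs of three are already far beyond what homoplasy
produces. `min_run = 3` is the default for the same reason: one or two
matching sites are within reach of private variation; three consecutive
ones are not.

On the packaged Cytb table the suspect genome tracks the *H. assulta* donors
at every diagnostic site up to 332 and the *H. armigera* reference from 355
onward (the table's highlighted changeover column), giving breakpoint
interval (332, 355); on the rrnS table its armigera-matching run ends at
site 425 before reverting. The other suspect genome matches armigera at all
34 diagnostic Cytb sites — a clean relabelling, not a chimera.

# Distance phylogeny

As a sanity check of species clustering (not a substitute for
maximum-likelihood inference, which is out of scope), the 13 protein-coding
genes are extracted in coding orientation, aligned per gene (center-star
progressive alignment around the modal-length copy; flush concatenation when
all copies are equal length), concatenated in the shared gene order with a
recorded partition map, and fed through Kimura two-parameter distances into
a canonical neighbor-joining implementation. Saturated pairs (non-positive
log argument) are set to a documented ceiling and flagged; negative NJ
branch lengths are clamped to zero and flagged; ties in the Q criterion are
broken lexicographically by descendant tip labels, making the tree invariant
to input order. NJ is exact on additive matrices — the property suite
verifies exact topology and length recovery on 100 random additive trees,
and cross-checks topology against the independent implementation in `ape`.
Column-resampling bootstrap support is available for reporting; support
values are never an acceptance surface.

# The synthetic-fixture generator

Every module is testable without downloads because the generator produces
inputs with known ground truth:

* **Amplicons** (`make_amplicon`): a seeded AT-rich background (A+T = 80%,
  matching lepidopteran mtDNA composition) is rejection-sampled until no
  panel enzyme has a spurious site, then each recognition site the key
  expects is planted so the cut coordinates equal the key's exactly
  (degenerate bases resolved by seeded choice; either orientation used when
  placements collide; isoschizomer sites planted once). The result is
  re-verified by digestion before being returned, so generator
  self-consistency is structural, not statistical.
* **Mitogenome panels** (`make_genome_panel`): a ~15.3 kb base genome on the
  shared gene layout (13 PCGs + 2 rRNAs in synteny order, minority strand
  carrying ND5/ND4/ND4L/ND1 and the rRNAs, 5N origin spacer in the control
  region) is mutated along a species tree whose branch lengths encode the
  observed identity structure: armigera–zea 97.24%, assulta vs armigera/zea
  ~94.8%, punctigera most divergent (~93.5%), conspecifics 99.5%. Branch
  substitutions are drawn from a globally disjoint position pool, so
  realized pairwise divergence equals the tree path length up to rounding
  and the planted mismatch counts are exact ground truth (the counting
  oracle used in tests). An optional deep outgroup supports rooted topology
  checks.
* **Chimeras** (`make_chimera`): a backbone genome with a donor block
  spliced in at known 1-based coordinates, carried as truth metadata. Splice
  recovery is tested over 200 seeded replicates: every true splice point
  must fall inside its reported breakpoint interval, and median interval
  width must stay within twice the diagnostic-site spacing.

What the generator does *not* emulate — and hence what passing tests do not
establish about field data: sequencing error, heteroplasmy, indel evolution
(beyond a single planted-insertion test case), codon structure, selection,
and real intraspecific haplotype diversity (novel COI haplotypes are exactly
why earlier single-enzyme assays broke). Empirical gel work should use the
documented fragment-length tolerance and real REBASE definitions for the two
placeholder enzymes.

# Numerical choices and problem sizes

* Identity reported to 2 decimals; banded aligner band 200 bp; full dynamic
  programming used up to 3 kb.
* Misidentification thresholds: floor 98.0%, margin 2.0 points, `min_genes`
  2 — all configurable.
* Digest scanner oracle equivalence at 10^4 random 1 kb sequences; NJ
  additive recovery at 100 random 5–12-taxon trees; splice recovery at 200
  chimeras (60 in the acceptance script, which repeats a subset of the same
  computations for reporting); panels of 12 genomes for identity and
  topology checks. These sizes keep the full suite around five minutes on
  one CPU while leaving each property's failure modes plenty of room to
  show.
* All generator randomness flows through a seed-scoped RNG helper that
  restores the caller's RNG state, so fixtures are reproducible and tests
  cannot interfere with each other through the global stream.

# Known limitations

* The exact trim coordinates of the two COI amplicons relative to the CDS
  are not public; region extraction therefore locates amplicons by local
  alignment against packaged per-species reference sequences (synthetic
  here; swap in empirical references via `regions.conf` for real use).
* Bco5I/AquVI placeholder motifs, as above.
* Whole-genome alignment assumes collinearity (true for these mitogenomes,
  which share perfect synteny); rearranged genomes would need anchoring.
* Mitochondrial markers identify the matriline only: hybrids are invisible
  to any mtDNA assay, PCR-RFLP included.
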
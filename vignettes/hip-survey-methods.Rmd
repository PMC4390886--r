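---
title: "Surveying highly iterated palindromes and simulating a methylation-directed ratchet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying highly iterated palindromes and simulating a methylation-directed ratchet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipscan)
```

## The problem

Many cyanobacterial genomes carry the octamer `GCGATCGC` — the Highly
Iterated Palindrome, HIP1 — at densities of hundreds to thousands of copies
per million nucleotides, orders of magnitude beyond composition-based
expectation. A minority of genomes instead carry a *different* GC-rich
palindrome at comparable density (alternate HIPs such as `GGCGCC`,
`rCCGGy`, `GCsGC`, `GGGATCCC`, `TCGATCGA`), and genomes with abundant HIP
sequences essentially always encode DNA methyltransferases (MTases) whose
recognition sites lie within the repeat (`GATC`, `CGATCG`). hipscan
implements the quantitative survey machinery behind these observations —
oligomer overrepresentation statistics, palindrome-class scans, flanking
extension detection, one-off deviation profiles — together with a
stochastic simulator of the mechanistic proposal that ties them together:
a G^meC-directed mismatch-repair (MMR) ratchet that preferentially fixes
mutations creating new methylatable sites.

Everything is testable on synthetic genomes with known ground truth; no
external downloads are needed.

## Counting conventions

All statistics rest on a small set of conventions applied uniformly:

* **Overlapping matches count.** HIP1 overlap analysis requires it
  (staggered 8-mers sharing 7 bases with a repeat occurrence must
  register).
* **Matches never span contig boundaries**; each contig is linear unless
  flagged circular, in which case the `k-1` wrap-around windows are
  included. Coordinates are 0-based half-open in the genome container.
* **`N` matches nothing**, conservatively, so degenerate-pattern counts
  cannot be inflated by ambiguous residues.
* **Strand collapsing.** A palindromic oligomer represents both strands
  already and keeps its forward count; a non-palindromic oligomer is
  merged with its reverse complement and the two forward counts are
  averaged. This puts palindromes and non-palindromes on a common scale,
  and is used for counts per million, O/E ratios, ranked k-mer lists,
  extension ratios and deviation profiles alike.

Degenerate IUPAC patterns (e.g. `RCCGGY`) are counted as the sum over
their concrete expansions; `is_palindromic()` compares a pattern with its
IUPAC reverse complement, so `RCCGGY` is correctly palindromic.

## Null models and the deviation scale

The baseline expectation of an oligomer with `s` strong (G/C) and `w`
weak (A/T) bases in a genome of length `L` and GC fraction `gc` is

    E = L * (gc/2)^s * ((1-gc)/2)^w

summed over expansions for degenerate patterns. Markov models of order
`m` (1 or 2) use the standard sub-word count-ratio estimator,

    E(w) = prod_j N(w[j..j+m]) / prod_j N(w[j..j+m-1]),

with numerators over all `(m+1)`-mer sub-words and denominators over the
interior `m`-mers. The `N` tables are strand-collapsed counts (mean of a
word and its reverse complement); feeding the both-strand *sum* instead
would double every expectation relative to collapsed observed counts and
destroy the O/E ≈ 1 calibration on random genomes, which the test suite
checks directly.

Deviation from expectation is scored with a binomial model: with
`n = L` trials and success probability `p = E/L`, the score is

    D = log10 P(E) - log10 P(C_obs)

where `P` is the binomial pmf evaluated at real-valued counts by
log-gamma interpolation (expected counts are rarely integers). `D` is 0
at the expectation and grows in either direction; the direction (enriched
vs depleted) is carried as a sign by `shade_category()`, which maps `D`
linearly from 0 at `D = 100` to ±1 at `D = 8000` (saturating above).
`filtered_count()` passes a count per million only when the oligomer is
*enriched* with `D ≥ 1000`; the filter uses the order-0 model. All three
anchors are overridable through `shade_scale()`. Base-10 logarithms are
used throughout, matching the printed notation of the scale. Note that
these scores are genome-size dependent: 500 planted copies per Mnt pass
the filter comfortably on a multi-Mnt genome but not on a 1 Mnt one —
absolute counts, not densities, drive the binomial.

## The survey

`top_oligomers()` tabulates all `4^k` k-mers (a rolling base-4 encoding
plus `tabulate()`, so a 5 Mnt genome takes seconds), collapses
reverse-complement pairs, ranks by O/E or count per million (ties broken
lexicographically on the alphabetically smaller pair member), and annotates each entry with whether it overlaps or
is contained in a reference oligomer (HIP1 by default; an overlap is an
offset alignment agreeing on at least 4 positions). `hip_summary()`
reports the HIP1 count per million and O/E under all three models, plus
the top 8-mer when it differs from HIP1.

`best_in_class()` scans three enumerated palindrome classes: the 64
concrete palindromic 6-mers, the 32 palindromic 5-mer patterns with a
`W`/`S` center, and the 720 degenerate palindromic 6-mers carrying one or
two two-fold degenerate base *pairs*. (An even-length self-complementary
pattern cannot hold an odd number of degenerate positions — they come in
complementary pairs — so "one or two degenerate positions" is read as
pairs; the class's exemplar `RCCGGY` has exactly one degenerate pair.
Unbounded degeneracy would make `N`-heavy patterns trivially "best".)

`oe_excluding_hip()` removes an enclosing repeat's contribution from an
inner oligomer's *observed* count (count of the repeat times the inner
oligomer's multiplicity within it, floored at zero) while leaving the
expectation untouched: the operation asks how the inner site behaves
outside the repeat, not what its expectation would be in a repeat-free
genome. The subtracted O/E is therefore never above the plain O/E.

## Extension detection

`find_extensions()` grows a core oligomer outward one symmetric base pair
per round, testing only the four palindrome-preserving flank pairs
`x...comp(x)` (every conserved extension observed in real genomes
preserves the palindrome, and asymmetric extension is out of scope). The
selected pair is the one maximizing the extension ratio
`C(x.S.comp(x)) / C(S)`; ties select nothing. Tiers follow the survey's
published criteria: *strong* at ratio ≥ 50%, *weak* at ratio ≥ 25% with
the extended sequence's order-0 O/E above 4. Outer rounds divide by the
*inner-extended* count, reproducing the two-number style of nested
extension reports. The encoded string renders strong extensions in upper
case and weak in lower case around the core. A degenerate core is
analysed per reverse-complement class of its expansions and merged only
when all classes agree — mirroring how only two of four `rCCGGy`
expansions carry a conserved extension in the one genome showing it.
Cores with fewer than 20 occurrences are reported as having insufficient
occurrences rather than analysed.

## Deviation profiles

The one-off profile of a consensus `S` substitutes `N` at each position
`i` and reports

    f_i = (C(S with N at i) - C(S)) / C(S with N at i),

so a multi-position deviant is counted at no position (every other
position must match). With strand-collapsed counting (the default) the
N-substituted pattern of a palindromic consensus pairs with the pattern
for position `m+1-i`, so the profile is symmetric across the palindrome
axis; this is deliberate — a deviant site read on the other strand *is* a
deviant at the mirrored position. `collapse = FALSE` gives the plain
forward-strand profile when asymmetric bookkeeping is wanted. Flanking
context rules (required/forbidden bases immediately left/right) restrict
the statistic, e.g. to `CGATCG` occurrences not embedded in
`G`...`C` context; the mirrored rule is applied to the reverse strand.
Fractions are reported as numbers; no shading is applied to them.

## The ratchet simulator

The simulator formalizes the proposed G^meC-directed MMR ratchet. Each
generation the genome replicates; errors appear on the daughter strand at
rate `mu` per site and each mismatch is resolved in precedence order:

1. **Parental repair** — if a methylated site lies within the repair
   radius `R` of the mismatch, repair is directed toward the parental
   strand and the mutation is lost. (MMR efficiency falls off when the
   methylation signal is ~1000 nt away, hence the default `R = 1000`.)
2. **Nascent-strand methylation** — otherwise, if the daughter strand
   (with the mutation) contains the MTase recognition site (`CGATCG` by
   default) whose methylatable C sits in a G^meC context — a `G`
   immediately 5' of it, or equivalently a `C` immediately 3' of the site
   on the other strand — overlapping or adjacent to the mutated position,
   then with probability `p_meth` the MTase wins the race against mismatch
   resolution, the new site is methylated and the mutation is fixed.
3. **Random resolution** — otherwise the mismatch resolves to either
   strand with probability 1/2.

Giving parental signals priority over nascent methylation is a modeling
choice: the proposal describes a race, and parental priority is what
produces the saturating set point — once most of the genome lies within
`R` of a methylated site, new sites can no longer be ratcheted in.
Methylation is binary and persistent; only planted initial sites and
sites created by rule 2 are methylated. Background recognition sites that
arise by chance in the random starting genome are *unmethylated* (they
can still be captured by rule 2 when a mismatch lands on or adjacent to
them), and with `p_meth = 0` the whole machine collapses to neutral
drift with a 1:1 fixed:lost ratio, which the tests verify. Only the
daughter strand acquires errors; full duplex bookkeeping would add
nothing observable. The genome is circular by default so spacing
statistics have no edge effects.

Because mutations within `R` of a methylated site are always lost, sites
are effectively immortal and new sites arise only in uncovered territory
more than `R` from every existing site. Equilibrium gaps therefore fall
in roughly `(R, 2R]`, i.e. a mean spacing of ~1.4–1.5 `R` — about 1500 nt
at `R = 1000`, within a factor of two of one site per 1000 nt, and
halving `R` roughly halves the spacing. Approach to this plateau is
coverage-limited and slows as gaps close: at the default parameters
(`L = 200` knt, `mu = 1e-4`, 20 initial sites) the site count is still
growing at 20,000 generations, so the reference runs in the tests and the
acceptance script use 40,000 generations and average the recorded mean
spacing over the final quarter of the run (`equilibrium_spacing()`).

`trajectory_deviation_spectrum()` closes the loop with the survey: on an
evolved genome, one-off deviation from `GCGATCGC` is concentrated at the
first and last positions — the ratchet builds `G.CGATCG` / `CGATCG.C`
sites whose eighth base is unconstrained — while interior positions are
protected, reproducing the end-biased deviation pattern seen in real
HIP1-rich genomes.

## Synthetic data: what it emulates and what it does not

The generators produce i.i.d. background at a target GC fraction with
planted structure written on top at spaced random positions, and always
return exact bookkeeping (positions, planted counts, implied fractions)
for use as test oracles. `plant_pattern()` emulates HIP-like densities
(hundreds to thousands per Mnt); `plant_extension_mixture()` emulates
conserved-flank fractions; `plant_deviants()` emulates one-off spectra,
solving `n_i = E f_i / (1 - f_i)` so the *collapsed* profile recovers the
requested fractions (requested spectra should be palindrome-symmetric;
asymmetric requests are recovered symmetrized). Background occurrences of
planted patterns are counted and reported, not masked — tolerances in the
tests account for them analytically.

What the synthetic genomes do **not** emulate: coding structure and codon
bias (the triplet-repeat 8-mers that surface in real top lists), skewed
dinucleotide composition, real MTase/REase gene content, and
assembly artifacts. Passing tests therefore demonstrate the statistics
and the simulator's internal consistency, not biological conclusions
about any particular genome; runs on real FASTA files are supported
(`load_fasta()`) but optional.

## Numerical choices and degenerate inputs

* Binomial log-pmfs are computed via `lgamma`, accurate far into the
  tails where naive products underflow.
* Markov expectations with a zero denominator sub-word count are
  reported `NA` and propagate to `NA` O/E (reported missing, never
  Inf).
* `gc` of 0 or 1 with a pattern requiring the absent base class yields
  expectation 0 (not an error); O/E on a zero expectation is `NA`.
* Empty genomes and patterns longer than every contig are errors;
  contigs shorter than the pattern simply contribute no windows.
* Tie-breaks: ranked lists break O/E ties lexicographically; extension
  rounds with tied flank ratios select nothing.
* Generator placement uses a sorted-slack scheme (uniform gaps given
  the minimum spacing), so planted blocks never overlap and the same
  seed is byte-reproducible.

## Problem sizes

The test suite and acceptance script run entirely on synthetic data at
desk scale, chosen so each check has clear signal: oracle equivalence on
200 genomes up to 10 knt; null calibration on one 5 Mnt genome; planted
recovery on 1 Mnt (survey) and 150 knt (extensions, deviation spectra);
ratchet reference runs on 200 knt circular genomes for 40,000
generations (about a minute each).

## Known limitations

* The ratchet tracks a single parental sequence plus mismatch events;
  polyploidy, selection, and REase-driven site loss are out of scope.
* The equilibrium spacing is measured on a finite, still slowly
  coarsening configuration; the reported value is the plateau of a
  40,000-generation run, not an analytic fixed point.
* `best_in_class()` on the degenerate 6-mer class restricts degeneracy
  to two-fold codes by design; broader IUPAC classes would need a
  different normalization to stay comparable.
* Deviation profiles report fractions only; which base replaced which
  is not tabulated.
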
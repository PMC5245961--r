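---
title: "Methods: origin mapping from nascent-strand sequencing and DNA combing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: origin mapping from nascent-strand sequencing and DNA combing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriseq)
```

# Scope and model

oriseq implements the computational chain used to characterise human
replication-origin landscapes from two complementary assays and to
convert quantitative-western measurements into genome-wide origin
numbers. Three measurement models underlie the package:

* **BrIP-seq.** Nascent strands — 0.5–3.0 kb of newly synthesised,
  BrdU-substituted DNA spanning an origin — are enriched by anti-BrdU
  immunoprecipitation and sequenced as single-end 75 bp reads. Read
  density therefore peaks at initiation sites. A genomic control library
  (same labelling chemistry, no size selection) measures the
  position-specific background.
* **Molecular combing.** DNA fibers stretched on silanised glass at a
  constant extension carry alternating immunostained tracks from two
  sequential pulses (CldU then IdU, 30 min each). An origin that fired
  during the first pulse appears as a central CldU track flanked by two
  IdU tracks; track lengths measure fork progression and distances
  between pattern centres measure single-molecule inter-origin
  distances (IODs).
* **Quantitative westerns.** A dilution series of a recombinant standard
  converts a lysate band into a molecule count; combined with the cell
  number loaded this yields molecules per cell, and with a stated
  detection floor an upper bound on an undetectable protein.

# The peak caller

`call_peaks()` operates on fixed windows (default 1 kb) in four steps:
an enrichment filter (sample ≥ fold × scaled control, fold = 2), a
threshold computed as mean + 3 × population SD of the *sample* counts
over the enriched set, an inclusive (≥) significance cut, and merging of
adjacent significant windows into peaks with midpoint ⌊(start+end)/2⌋.
Reads are assigned to exactly one window by their 5′ position
(strand-aware), so totals are conserved.

Several aspects of this recipe are genuinely underdetermined, and each is
an explicit switch in `peak_call_config()`:

* **Library scaling** (`library_scale`, default on). Whether counts are
  depth-normalised before the fold comparison is not dictated by the
  recipe itself; scaling the control by total-sample/total-control makes
  the fold filter a statement about densities rather than raw counts.
  Both readings run.
* **Zero-control windows** (`control_pseudocount`, default 1). A fold
  ratio against a zero control is undefined; the pseudocount applies only
  to windows with a raw control count of zero, leaving measured windows
  untouched.
* **Threshold domain** (`threshold_domain`, default `enriched_only`).
  The two filters can be chained (a peak must pass both) or the
  mean + 3σ cut can be applied to all windows. The default chains them,
  which is the stricter reading; the alternative is selectable.
* **SD convention** (`sd_type`, default `population`). Dividing by n
  versus n − 1 is immaterial at genomic window counts but is documented
  and switchable because the recipe does not specify it.
* **Merging** (`merge`, default on). A 0.5–3 kb nascent-strand signal
  spans more than one 1 kb window; without merging, peak counts and
  downstream IODs are inflated by multi-window origins. Unmerged mode
  exists for sensitivity analysis.

## Operating regimes of the mean + 3σ rule

The threshold is a property of the *enriched set*. Two regimes follow:

* When the enriched set is dominated by a large, homogeneous background
  population — the situation at genome scale, where millions of windows
  at a few reads each pass the 2× filter by chance against a fluctuating
  control — μ and σ describe that background, and origin windows stand
  clear of μ + 3σ. This is the regime in which the rule behaves as a
  background-model peak caller.
* When the enriched set is dominated by the signal windows themselves —
  the situation on a small dense test genome, where background windows
  at ~0.5 reads rarely pass any fold filter while every origin window
  does — μ + 3σ is computed over the signal distribution and lands
  *above* the typical origin window. Writing f for the signal fraction
  of the enriched set and a two-point mixture for its counts, the
  threshold falls below the signal level only when
  3·sqrt(f(1−f)) < 1 − f, i.e. f < 0.1. The caller then returns only the
  extreme tail of the origins: high precision, very low recall.

The package implements the rule faithfully and reports μ, σ, the
threshold and the enriched-set size in every `peak_report()`, so users
can see which regime they are in. The planted-origin acceptance check in
the test suite runs at desk scale (10 Mb, 400 origins, 30 reads/origin
over 0.5 reads/kb background) and measures this second regime directly:
recovery there is a fraction of a percent at precision 1.0. This is a
property of the calling rule at that scale, not of the
implementation, which matches an independent naive re-computation of the
three steps window for window on randomised grids.

# Combing estimators

`fiber_iods()` defines an origin event as a CldU segment flanked by IdU
on both sides within `max_gap_um` (default 1 µm, joining tracks split by
staining gaps) and measures centre-to-centre distances, converted at
`kb_per_um` (default 2 kb/µm — the conventional stretching constant for
silanised-coverslip combing; the constant is configurable because
combing set-ups differ).

`fork_rates()` supports two conventions:

* **CldU-based (default).** A complete origin pattern's CldU track was
  laid by two forks over pulse 1, so rate = CldU length × kb_per_um /
  (2 × pulse1). Converging forks from neighbouring origins typically
  meet *after* the label switch (meeting time d/(v₁+v₂) with d ≈ 96 kb
  and fork speeds ~1.2 kb/min gives ~40 min, past the 30 min switch), so
  complete CldU tracks are rarely shortened and the estimate is nearly
  free of censoring bias. Simulated recovery at the defaults is within
  ~1% of the generating rate.
* **IdU-based.** Each IdU segment contiguous with exactly one CldU
  segment measures a single fork: rate = IdU length × kb_per_um /
  pulse2. Segments touching a fiber end are censored, and segments
  flanked by CldU on both sides are excluded (`exclude_converged`) as
  converged-fork pairs whose length reflects origin spacing. At
  realistic origin densities the full pattern spans ~144 kb against a
  ~96 kb median spacing, so most second-pulse tracks are destroyed by
  convergence or fiber ends; the survivors preferentially carry *slow*
  forks, and the IdU-based median under-reads the true rate by ~7–11%
  in simulation. The convention is kept because it is the natural
  single-fork measurement when origins are sparse, but it is not the
  default.

Both estimators are invariant under fiber orientation reversal, and all
outputs are strictly positive.

# Statistics

Inter-origin distances from peaks are successive midpoint differences
per chromosome (centre-to-centre; the pattern schematics of combing
measure centres, and midpoints are the only well-defined point of a
merged peak); the global summary pools distances across chromosomes
rather than averaging per-chromosome medians. Overlap between peak sets
counts any shared base pair on half-open intervals, reported in both
directions because the denominators differ. TSS distances are signed by
TSS strand (positive downstream), with equidistant ties resolved to the
lower-coordinate TSS and peaks on TSS-less chromosomes excluded and
counted.

Location comparisons use a two-sided Wilcoxon rank-sum test
(`wilcoxon_rank_sum()`, a front end over `stats::wilcox.test`): exact by
enumeration for tie-free samples with n₁ + n₂ ≤ 12, otherwise the
tie-corrected normal approximation with continuity correction. Two
conventions are pinned down explicitly: a statistic at the exact centre
of the null distribution reports p = 1 (the continuity correction would
otherwise report slightly less for identical samples), and degenerate
input in which every value of both samples is identical returns p = 1
with a warning instead of NaN.

# The synthetic-data generator

The generator exists so that every stage has inputs with known ground
truth. What it emulates, and what it deliberately does not:

* **Origins** are planted uniformly (optionally biased to within ±1 kb
  of a TSS with a stated probability, emulating the enrichment of
  origins near transcription start sites) with a minimum spacing
  (default 5 kb) so planted origins remain resolvable on a 1 kb grid.
  Placement is by rejection sampling; over-full chromosomes raise an
  error naming the chromosome. Note that at minimum spacing s each TSS
  window supports at most one biased origin, so the TSS set must
  outnumber the biased origins.
* **BrIP-seq reads** are origin-centred: fragment length uniform in
  0.5–3 kb, read start uniform within the fragment, Poisson read counts
  per origin scaled by firing efficiency, over a uniform Poisson
  background (default 0.5 reads/kb). The control is uniform; its depth
  either stated or matched to the sample library (the default, matching
  the comparable library sizes of the assay). No sequencing errors, PCR
  duplicates, mappability structure or diploid haplotypes are modelled —
  recovery results therefore say nothing about mappability artefacts in
  real data.
* **FASTQ mode** draws random base sequences (there is no reference
  genome) and appends 3′ poly-T tails of uniform length, which is
  exactly what the trimmer removes; round-tripping is exact whenever the
  template read does not itself end in T.
* **Fibers** carry origins spaced by truncated-normal IOD draws; all
  origins fire at the start of pulse 1 with per-fork truncated-normal
  rates; converging forks terminate where they meet; tracks are clipped
  at fiber ends and flagged truncated. Fiber length is normal
  (default mean 150 µm ≈ 300 kb, a realistic combed-fragment length).
  Asynchronous firing and fork stalling are not modelled; the
  synchronous model is what makes the deterministic limit tests exact
  (rate SD 0 ⇒ every complete IdU track is exactly 18 µm).

All randomness flows through explicit integer seeds via scoped RNG
state; identical spec + seed reproduces outputs bit for bit, and the
pipeline writes no timestamps so whole run directories are
byte-reproducible.

# The pipeline and its demo conditions

`run_pipeline()` / `oriseq_demo()` execute simulate → trim → call peaks
(per condition) → statistics → combing → quantification, writing every
output under one directory and finishing with a JSON manifest of the
configuration, seed, package version and per-file MD5 checksums.
`validate_config()` fills defaults, rejects unknown keys and reports all
range errors at once, before any stage runs.

The demo simulates a wild-type-like condition (400 origins on a 10 Mb
two-chromosome genome, 30 reads/origin, fork rate 1.2 kb/min, IOD
96 kb) and a knockout-like condition (260 origins of which 40% are
shared with the wild-type set, emulating partial origin-usage overlap;
fork rate 1.4 kb/min, IOD 115.5 kb — the slightly-faster, wider-spaced
phenotype of an origin-licensing mutant). Problem sizes throughout the
tests and the acceptance script — 10 Mb genomes, 400 planted origins,
500 fibers, 5,000 distances per condition — were chosen as the smallest
sizes at which medians and rank-sum comparisons are stable to a few
percent.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open in all data frames and BED files (no
  shift on BED I/O); conversions to 1-based closed ranges happen only
  internally at the GenomicRanges boundary.
* Window assignment uses the strand-aware 5′ position; a read starting
  exactly on a window boundary belongs to the right-hand window.
* The significance comparison is inclusive (≥) at both the fold filter
  and the threshold.
* An empty enriched set is a warning plus an empty peak list, not an
  error; a zero-total control is an error (scaling undefined).
* Poly-T trimming removes the maximal trailing T-run (an N stops the
  run), is idempotent, never lengthens a read, and flags — rather than
  drops — reads falling below `min_len_after` (default 20 bp).
* Fiber segments shorter than 1 nm are dropped as numerical noise;
  segment contiguity uses `max_gap_um` with a 1e-6 µm end-tolerance.
* Reported counts follow the quoting precision of the source
  measurements: molecule counts to 3 significant figures, origin counts
  ≥ 10⁴ to the nearest thousand with halves away from zero; raw values
  are always retained alongside.

# Known limitations

* The caller implements exactly one calling rule; it has no local
  background model, FDR control or replicate handling, and at dense
  desk-scale simulations it operates in the low-recall regime described
  above.
* The generator's uniform background and uniform control understate the
  structured background of real chromatin.
* The combing simulator's synchronous firing overstates how often
  complete bidirectional patterns occur on real fibers, where origins
  fire throughout S phase; absolute track counts per fiber should not be
  compared to experimental ones.
* The licensing arithmetic propagates no uncertainty; it is exact
  division and multiplication on point estimates.
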
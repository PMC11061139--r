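---
title: "Methods: fly social networks, betweenness centrality and its null model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fly social networks, betweenness centrality and its null model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis in one paragraph

`flynetbc` turns per-frame trajectories of a small group of flies (12 males
in a 60 mm circular arena, 30 minutes of recording) into directed social
networks and asks whether the group's *betweenness centrality* (BC) deviates
from what its degree sequence alone would predict.  Interactions are
detected with a three-part geometric criterion; the time-ordered stream of
*first-occurrence* directed interactions is scanned with a 33-edge boxcar
window (25% of the 132 possible directed edges among 12 flies); each window
graph's mean node BC is standardized against an ensemble of degree-preserving
random digraphs; and the per-window z-scores are averaged into one number
per recording.  Recordings are the statistical unit: groups of recordings
are compared by IQR outlier trimming, one-way ANOVA and a Tukey–Kramer post
hoc test with a compact letter display.

# Interaction criterion

A directed pair (interactor → interactee) is interacting on a frame when

1. the angle between the interactor's long axis and the segment joining the
   two body centres is ≤ 90° (boundary inclusive),
2. that segment is ≤ 2 body lengths of the *interactor* (boundary
   inclusive), and
3. both conditions persist for ≥ 1.5 s.

The interactor's body length is scalarized as the **median** of its
per-frame body-length track — robust to tracking jitter; the choice of
scalarization is a package decision since per-frame lengths fluctuate.
Events are directional: only the interactor's heading enters the angle
condition, so A→B can hold while B→A does not.  A `max_gap` option can
bridge short criterion-violating interruptions inside a bout; it defaults
to 0 (conditions must hold on every frame) because the criterion is stated
as *maintained*.  All criteria are configurable per genotype via
`load_criteria()`; automatic data-driven criteria selection is out of scope.

# Network construction and metrics

An interaction is *unique* if that ordered pair has not interacted before.
Uniqueness is per **ordered** pair: 12 flies give 12 × 11 = 132 possible
directed edges, and a 33-edge window is exactly 25% density — the stated
window size only makes sense under directed-pair counting.  The i-th boxcar
iteration drops the first i − 1 unique interactions and appends the next
one, giving U − 32 window graphs for U unique interactions; a recording
with U < 33 yields no networks and a warning.

Betweenness centrality of node v is the unnormalized sum over ordered pairs
(s, t), s ≠ v ≠ t, of the fraction of shortest directed s→t paths passing
through v; pairs with no path contribute 0.  It is computed with Brandes'
algorithm in C++ and is checked in the test suite against an independent
matrix-power path-counting oracle (exhaustively for every digraph on ≤ 4
nodes, by fixed-seed sampling on 5 nodes).  Normalization is omitted
deliberately: it cancels in the z-score.

Auxiliary metrics: out–in degree assortativity (Pearson correlation over
edges of source out-degree with target in-degree), Fagiolo's all-triangle
directed clustering coefficient, global efficiency (mean reciprocal
geodesic length over ordered pairs, 0 for unreachable pairs), group
movement (mm/s) and interaction rate (events per fly per minute).  The
directed variants of assortativity and clustering are not pinned down by
the original description beyond a toolbox citation; the chosen variants are
documented here and isolated behind `degree_assortativity()` /
`clustering_coefficient()` so they can be swapped.

# Null model and z-score

Each window graph is standardized against `n_random` (default 10,000)
random digraphs with **exactly** the same in- and out-degree sequences,
generated by directed double-edge swaps: edges (a,b), (c,d) are rewired to
(a,d), (c,b) unless a self-loop or duplicate would result.  Each sample
restarts from the observed graph and performs 10 swap attempts per edge —
standard practice in connectivity toolboxes; exact degree preservation (not
mixing speed) is the tested contract, asserted per sample in the acceptance
suite.  The z-score is (observed − mean(null)) / sd(null).  A graph with no
valid swap (e.g. a complete digraph) yields a degenerate null with zero
spread: z is 0 when the observed value equals the null mean and an
undefined-value sentinel (`NA`) otherwise; undefined iterations are dropped
from the per-recording mean with a logged count.  Graph-level metrics are
z-scored identically.

# The synthetic arena: what it emulates, and what a green test means

Real recordings come from video tracking; this package ships an agent-based
generator instead, so every downstream stage is testable offline.  Flies
move by a correlated random walk (heading diffusion `turn_sd`,
multiplicative speed noise around `speed_mean` = 4 mm/s) inside a
reflective 60 mm arena at 30 Hz — a frame rate typical of the camera class
used for such assays; duration-denominated criteria make results robust to
it.  Two behavioural features of real fly groups are built in:

* **Contact bouts.** Flies alternate between a *social* state (steer toward
  the most attractive neighbour within 10 mm, decelerate within 3 mm of
  it — real interacting flies are nearly stationary) and a *roaming* state
  (ignore neighbours).  Mean bout and roam durations default to 4 s and 6 s,
  which reproduce realistic interaction rates (≈ 5 events/fly/min) and
  bout durations comfortably above the 1.5 s detection threshold.
* **Local aggregation.** Every fly carries a home range (8 mm radius)
  centred on one of two aggregation sites, chosen from the fly's own seed
  substream.  This spatially assorts interactions into two resident
  communities, a caricature of the local clustering seen in real arenas.

`hub_bias` is the single structural dial.  With `hub_bias = 0` the hub
designation is inert: all flies follow identical rules and are exchangeable
(verified bit-exactly under joint permutation of labels and per-fly seeds).
With `hub_bias > 0` the designated hub flies become highly attractive,
home-less rovers: residents engage them whenever they visit, so the rovers
become the *gatekeepers* that bridge the two communities.  This is the
textbook high-betweenness topology — dense communities connected through
few shared nodes — and it measurably raises the mean BC z-score.

A design finding worth recording: the naive mechanism ("make one fly a
magnet that everyone approaches") does **not** raise standardized BC.  A
star's centrality is fully explained by its degree sequence, which the null
model preserves, and a magnet additionally mixes the group and shortens
paths, so z stays flat or falls as the magnet strengthens.  Several such
kernels (single magnet, anchored magnets, attractiveness-scaled sensing
range or bout duration, resident migration between sites) were evaluated
and rejected because they produce no contrast or the inverse one; resident
migration in particular bridges the communities in *both* presets and
erases the hub-specific effect.  The preset magnitudes (`hub_bias` 30 vs 0)
are tuning choices validated only by the **direction** of the BC
difference, as is the generator's whole purpose: under the defaults, ten
seeded recordings per preset give mean BC z ≈ −3.3 (high_bc) vs ≈ −11.5
(low_bc).  Both absolute levels are below null expectation — segregated
communities have fewer, shorter completed paths than degree-matched random
graphs — and no claim is made that they match the magnitudes of real
recordings.  A green parameter-recovery test therefore establishes that the
pipeline can detect a known gatekeeper manipulation in the stated
direction; it does not validate absolute centrality levels, locomotor
realism (no wing/leg kinematics, no thigmotaxis), or genotype-specific
interaction criteria.

# Group statistics

Outliers ≥ Q3 + 1.5·IQR or ≤ Q1 − 1.5·IQR are removed before testing, with
quartiles computed once on the input by linear interpolation (quantile
type 7 — the boundary cases of the rule depend on the quartile convention,
so it is pinned explicitly).  A zero IQR would, under the
boundary-inclusive reading, delete every observation; the implementation
returns the input unchanged in that degenerate case because the rule's
intent is tail trimming.  Outlier removal is applied per genotype (whether
the original analysis pooled groups first is unknowable from the text; a
flag switches the behaviour).  The one-way ANOVA is the classical
fixed-effects F; Tukey–Kramer uses the studentized-range distribution with
unequal-n standard errors; letters are assigned by greedy clique cover over
the non-significance graph, smallest mean first, with a repair pass so two
groups share a letter iff they are not significantly different.  The
two-sample t-test defaults to the classical pooled-variance form, with
Welch as an option, since the original text does not specify.  Alpha
contexts: 0.05 by default, 0.008 for the allele-swap experiment (several
measurements on one data set, Bonferroni), 0.01 for the hydrocarbon
experiment.

# Variant survey and mapping

`tally_position()` counts A/C/G/T at one 1-based position (default 1049,
the site distinguishing the two strain alleles) per locality parsed from
the FASTA headers; any other character — IUPAC ambiguity codes, N, gaps —
counts as ambiguity and removes the sequence, since the original filter is
stated only as "nucleotide ambiguity".  The index base is switchable
because off-by-one conventions are the classic failure mode here.  The
chi-square homogeneity test is the textbook Pearson statistic on the
locality × nucleotide table with all-zero rows/columns dropped; N is
reported as the retained-sequence count (the published "N = 49" alongside
df = 28 is not reconstructible from the stated 966 − 215 = 751 retained
sequences; the package reports what it computes and leaves the discrepancy
noted, not reconciled).

Recombinant mapping intersects, across phenotyped recombinant lines, the
chromosome-3 segments whose strain of origin matches the line's phenotype.
Unsequenced segments are treated as compatible with either origin and are
included in a line's implicated region — excluding them could wrongly empty
the intersection.  Lines with intermediate phenotypes are skipped, not
modelled.  Coordinates are 1-based inclusive at the interface (marker
convention), half-open internally, and BED output is 0-based half-open.

# Numerical and reproducibility choices

* One master seed drives everything: per-fly simulator substreams, per-file
  recording seeds, and per-iteration null-ensemble seeds are all derived
  from it (kept below 2^31), so a pipeline run is bit-reproducible.
* The double-edge-swap sampler consumes R's RNG, so `set.seed()` governs it.
* Thresholds are compared boundary-inclusively, matching the criterion's
  wording; angle comparisons go through `acos` of a clamped cosine.
* Tests scale the null ensemble down to 50–500 samples (the default for
  analysis remains 10,000) and the parameter-recovery check uses
  `n_random = 200` over 10 recordings per preset; these are runtime
  scalings, not changes to the stated world.

# Known limitations

The simulator is a stand-in, not a locomotion model: no thigmotaxis, no
body-size interaction, no collision handling, and exactly two aggregation
sites.  Genotype-specific criteria selection, weighted or time-respecting
networks, and community detection are out of scope.  Assortativity returns
`NA` on windows whose edge-endpoint degrees have zero variance; such
iterations are dropped from the z average with a logged count.
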
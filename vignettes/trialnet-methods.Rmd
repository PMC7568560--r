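---
title: "Methods: impact scoring, co-authorship networks, and the synthetic corpus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: impact scoring, co-authorship networks, and the synthetic corpus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`trialnet` studies the collaboration network of clinical-trial authorship.
This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical conventions it fixes, and the
limits of what its synthetic data can show.

## The impact score

Each author earns, per manuscript, the product of four coefficients.

| coefficient | values | default | meaning |
|---|---|---|---|
| role | `role_first_last`, `role_middle` | 3, 1 | first/last/equal-contribution vs middle authorship |
| trial | `trial_randomized`, `trial_other` | 2, 1 | any randomized design on the manuscript (mixed designs count as randomized) |
| citation | `[0, 1+]` | — | citations normalized to the corpus maximum |
| update | `0.5^k` | half-life 0.5 | k-th update of a trial; primary is k = 0 |

Assumptions worth making explicit:

- **Citation normalization is corpus-wide and static.** The divisor is the
  single most-cited manuscript in the corpus, computed once — not per
  year. Citation counts are a snapshot field of the record; the package
  performs no retrieval.
- **The blend window.** Recent manuscripts are still accruing citations,
  so for years inside `blend_window` (2009–2018 by default) the journal
  tier's historical median citation count is phased in:
  `(citations + w(year) * tier_median) / max_citations` with
  `w(year) = (year - (start - 1)) / width`, i.e. 1/10 at 2009 rising to 1
  at 2018. The linear ramp is a package choice; it is exposed through
  `impact_config()` so any other phase-in can be substituted. Blended
  scores may exceed 1; the package permits this and keeps the raw
  corpus maximum separately as a ledger attribute.
- **Pooled updates** (one manuscript updating several trials) use the
  pooled index that yields the maximum coefficient, i.e. the smallest
  index.
- **Subspecialty splitting.** A manuscript's weights over the 13 disease
  subspecialties must sum to 1; each author's score is split by exactly
  those weights, so the ledger's per-record contributions always total
  the undivided score. One author's score never depends on co-authors'
  scores.

## The co-authorship network

One manuscript contributes one edge per unordered author pair, weighted
`s_i * s_j / n_authors`. Dividing by team size damps any single link on a
large multi-institutional paper while the paper's total neighborhood
weight still grows linearly with team size. Networks are discretized by
calendar year and strictly cumulative: nodes, edges and scores never
leave.

Two views coexist. The **multigraph** keeps every (record, pair) edge and
is used for provenance and for concentration's endpoint counts. All
**metrics** run on the weight-summed **simple-graph view**, because the
modularity and assortativity definitions the analysis relies on are
simple-graph formulations:

- *Density* counts distinct co-author pairs over `n(n-1)/2`. This is
  validated by the corpus arithmetic the method was designed around
  (30 links among 12 authors gives 45.5%).
- *Modularity* is weighted Newman modularity under the subspecialty
  partition; authors without an assignment form a single `"None"`
  community.
- *Assortativity* is the weighted categorical coefficient computed from
  the mixing matrix `e` as `(tr e - sum a^2) / (1 - sum a^2)`. It is
  hand-implemented because the installed igraph's nominal assortativity
  does not accept edge weights; tests check it against a brute-force
  evaluation of the same definition.
- *Betweenness* uses distance = 1/(summed edge weight): stronger
  collaboration is a shorter path. This reading is a package choice,
  exposed via `weighted = FALSE` for hop-count distances.
- *PageRank* treats summed weights as transition propensities on the
  undirected graph (damping 0.85) and returns the standard sum-to-one
  probability vector; "median PageRank" in reports is the median of that
  vector.
- *Homophily* is per-author: the share of distinct co-authors
  (`"neighbors"`) or of incident link weight (`"outlinks"`) whose far end
  matches the author's subspecialty or gender. Authors without a defined
  attribute (subspecialty `"None"`, gender outside woman/man) are
  excluded both as egos and from denominators, and authors with no
  remaining co-author are dropped — homophily is only reported where it
  is calculable.

Numerical conventions: links whose two endpoint scores are both zero
(possible with zero-citation manuscripts) would give infinite
reciprocal-weight distances; such weights are floored at `1e-9` times the
smallest positive weight for the distance-based metrics only. Impact ties
in concentration rankings break deterministically by author key.

## Identity and gender

Raw names are MEDLINE-style `Surname_Given`. Canonicalization applies an
explicit alias table transitively (cycles are an error), then one
automatic rule: an initials-only form merges into a full form only when
exactly one full form shares its surname with a prefix-compatible initial
sequence. Anything subtler — misspellings, surname changes over a career,
country-dependent given names — is left to the alias and override
tables, because those cases cannot be resolved mechanically from the
corpus alone.

Gender assignment is a total function onto
`{woman, man, unknown_initials, ambiguous}`: initials-only names are
always `unknown_initials`; otherwise an override table wins, then a
name-frequency table assigns the majority gender only when its ratio is
strictly above 0.9, then a dictionary table, else `ambiguous`. The strict
inequality means a name at exactly 0.9 falls through to the next source.

## Careers

Primary-subspecialty eligibility requires first/last authorship in the
subspecialty or cumulative impact there of at least `mean - 1 SD` of all
authors with positive impact in that subspecialty that year. Three
package choices deserve note:

- the phrase "one standard deviation below the mean" is read as an
  inclusion *floor* (`impact >= mean - SD`) — the only reading that makes
  it a meaningful criterion — with the SD taken as the population SD over
  authors with positive impact in the subspecialty;
- assignments are recomputed only in years the author publishes, and an
  incumbent is displaced only by an eligible subspecialty with strictly
  higher impact (exact ties become an equal split across the tied set);
- the change flag considers only single-label years and ignores `"None"`
  and equal-split transitions, so oscillation through ties does not count
  as a subspecialty change.

Longevity is `last - first` publication year, with final years 2016–2017
adjusted to 2018 for authors already active before 2016, reflecting the
lag between trial completion and publication at the database horizon.

## Statistics

- The Wilcoxon rank-sum test enumerates all group assignments exactly for
  groups of up to 10 (midranks make this exact under ties; the two-sided
  p-value is the probability of a rank sum at least as far from its
  expectation as observed). Larger groups use the tie-corrected normal
  approximation without continuity correction. Quartiles use linear
  interpolation (R type 7) so reported IQRs are reproducible.
- The gender trend is LOESS with degree 2 and span 0.75. The parity year
  comes from an OLS line through the most recent 30 years of the
  new-author woman share — the window is a package default chosen to
  match the span of the modern, nearly linear rise, and is configurable
  (`parity_window`); the first calendar year at which the line reaches
  0.5 is reported, with `NA` and a warning when the slope never crosses.
- The sensitivity analysis varies the role coefficient by ±67% and the
  trial coefficient by ±50%, one at a time (five variants including
  baseline), recomputes the full ledger, per-year career assignments and
  yearly metric series per variant, and reports Pearson correlations of
  each variant's assortativity and modularity series against baseline.
  Baseline correlates with itself at exactly 1; series with fewer than
  three usable points are flagged degenerate and reported `NA`.

## The synthetic corpus

`simulate_corpus()` generates the study conditions the analysis assumes,
at roughly 1/50 of the scale of a seven-decade curated trial
bibliography (about 112 papers and several hundred authors, 1946–2018),
so the complete pipeline and its tests run in seconds:

- papers per year grow exponentially (rate 0.064/yr, about 100-fold over
  the period);
- team sizes are lognormal with a median interpolating 6 (1946) to 20
  (2018) and `sdlog = 0.33`, putting the end-of-period IQR near 16–25;
- 13 subspecialties; returning co-authors are drawn from the paper's
  subspecialty with probability 0.88, and otherwise preferentially by
  accumulated collaboration weight (`strength^attachment + 1`), which
  produces the heavy-tailed degree distributions of repeat collaboration;
- 40% of author slots go to new entrants, calibrated so that most authors
  appear in a single year (median longevity below one year);
- new entrants are women with probability 0.15 before 1980, rising
  linearly to 0.40 by 2018; by default gender affects nothing else, so
  disparity statistics are testable under the null;
- citations are lognormal (`sdlog = 1.3`) around journal-tier medians,
  damped in 2009–2018 to mimic incomplete accrual; 78% of papers are
  randomized; 22% are updates of earlier primaries (3% pooled);
- names are synthetic surname tokens with a controlled gendered
  given-name vocabulary; 12% of authors always appear as initials and 8%
  alternate forms, exercising the disambiguation rules.

What the generator deliberately does **not** emulate: real name
misspellings and surname changes, citation dependence on gender or
seniority, non-random journal placement, subspecialty birth and death,
and multi-trial manuscripts beyond simple pooled updates. Passing
recovery tests therefore show that the pipeline measures what the
generator encodes — configured homophily, the gender schedule, tail
heaviness — not that it would be unbiased on any real bibliography.
At this scale the new-author gender series is noisy: single simulated
corpora can yield parity extrapolations far from the schedule's nominal
crossing, which is itself a caution against over-reading a single
extrapolated year.

## Problem sizes and determinism

The test suite exercises brute-force oracle equivalence on hundreds of
random graphs of up to 8 nodes (exhaustive simple-path betweenness,
power-iteration PageRank, direct modularity and mixing-matrix sums),
exact rank-sum enumeration up to 8 per group, and 20 replicate
simulations at the default 1/50 scale; these sizes keep the whole suite
in a few minutes while leaving every assertion exact. All randomness
flows through explicit seeds: a fixed `sim_config(seed)` reproduces a
corpus byte for byte, and `run_simulation()` / `run_analysis()` /
`run_sensitivity()` write byte-identical bundles on re-runs, which the
tests assert.

## Limitations

Co-authorship is one lens on collaboration; published trials
under-represent negative and early-phase work; the impact score's
coefficients are judgment calls (hence the sensitivity analysis); name
disambiguation without external lookups cannot resolve every ambiguity,
and given-name gender assignment misses nonbinary identities and
name–identity mismatches entirely. The package treats these as explicit
interfaces — alias, override and frequency tables — rather than hidden
heuristics.
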
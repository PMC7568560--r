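# trialnet

Temporal co-authorship network analysis of clinical-trial publications.

Clinical trials establish the standard of cancer care, yet the social
structure of the people who run them — who collaborates with whom, how
subspecialties cluster, how influence concentrates, and how gender
disparities play out — is rarely quantified. `trialnet` implements a
complete, reproducible pipeline for that question: it scores each author's
impact on each manuscript, grows a cumulative weighted co-authorship
network year by year, assigns authors to disease subspecialties, and
measures disparity, homophily and concentration over seven decades of
publication records. Because real curated trial bibliographies are not
generally redistributable, the package ships a seeded synthetic corpus
generator that reproduces the statistical structure such corpora exhibit,
so every analysis in the package runs end to end with no external data.

## The model

**Author impact.** An author's impact on one manuscript is a product of
four coefficients:

```
impact = role x trial x citation x update
```

- `role` — 3 for first, last, or equal-contribution authors; 1 for middle
  authors.
- `trial` — 2 if the manuscript reports at least one randomized trial
  (mixed designs count as randomized); 1 otherwise.
- `citation` — the manuscript's citation count normalized to the
  corpus-wide maximum, so the maximum citation score is 1. For recent
  years still accruing citations (2009–2018 by default) the journal
  tier's historical median citation count is phased in linearly with
  weight `w(year) = (year − 2008)/10`.
- `update` — half-life decay `0.5^k` for the k-th update of a trial
  (primary publication is k = 0); pooled updates use the index giving the
  maximum coefficient.

A manuscript's impact is divided across its disease subspecialties by the
record's subspecialty weights, and an author's cumulative impact is the
sum over all their manuscripts.

**Co-authorship network.** Every author pair on a manuscript contributes
one edge weighted `s_i * s_j / n_authors` (manuscript-specific scores
divided by team size). Networks are discretized by calendar year and
cumulative; metrics — density, weighted Newman modularity and categorical
assortativity by subspecialty, reciprocal-weight betweenness, weighted
PageRank, per-author homophily, and link/impact concentration — run on
the weight-summed simple-graph view, while the multigraph keeps
edge-level provenance.

**Careers and disparity.** Authors gain a primary subspecialty once they
are first/last author there or their impact clears a `mean − 1 SD` floor;
the assignment is recomputed each publishing year and only moves to a
strictly better subspecialty. Longevity is the first-to-last publication
interval (with a truncation adjustment near the database horizon). Group
contrasts use the two-sided Wilcoxon rank-sum test (exact by enumeration
for small groups), gender trends use LOESS (degree 2, span 0.75), and a
30-year linear extrapolation estimates the year of gender parity among
new authors. A sensitivity analysis rescales the role (±67%) and trial
(±50%) coefficients and correlates the resulting assortativity and
modularity series with baseline.

## Worked example

```r
library(trialnet)

sim <- simulate_corpus(sim_config(seed = 7))          # ~108 papers, 1946-2018
ids <- author_identities(sim$corpus,
                         freq_table = sim$tables$freq_table,
                         dictionary_table = sim$tables$dictionary_table)
led <- impact_ledger(sim$corpus, mapping = ids$mapping,
                     config = sim_impact_config(sim$ground_truth$config))

attrs <- history_node_attrs(career_history(led))
final_attrs <- dplyr::slice_max(dplyr::group_by(attrs, canonical_key), year, n = 1)
net <- build_network(led, 2018, node_attrs = final_attrs)
net
#> <yearly_network 2018: 771 authors, 14727 links (19062 co-authorship edges)>

net_density(net); net_modularity(net); net_assortativity(net)
#> density 4.961%, modularity 0.513, assortativity 0.739

hom <- net_homophily(net, "subspecialty", "neighbors")
median(hom$homophily)
#> 0.87   # co-authors overwhelmingly share a subspecialty

cars <- careers(led, identities = ids$identities)
compare_groups(cars$impact[cars$gender == "man"],
               cars$impact[cars$gender == "woman"], c("man", "woman"))
#> man   n=399 median 0.121; woman n=222 median 0.094; p = 0.026

glance(new_author_trend(led, ids$identities))$parity_year
#> 2030   # linear extrapolation of the new-author woman share

concentration(net, 0.1)
#> top 10% of authors hold 27.8% of links and 63.4% of impact
```

The numbers above are what the code prints for that seed: a sparse,
single-component network that is strongly modular and assortative by
subspecialty, with high within-subspecialty homophily, heavy
concentration of impact in a small elite, and a measurable gender gap in
impact and longevity. `run_analysis()` wraps the whole chain and writes a
report bundle (per-year metrics, career and comparison tables, GraphML
export, manifest); `run_sensitivity()` writes the coefficient-variation
correlation table; `autoplot()` and `plot_*()` functions draw the series.

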
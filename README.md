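# townnet

Building and analysing the **complete discussion network of a township's
older population** from ego-centric, name-generator survey data.

Sociocentric studies of aging villages survey every resident aged 60+ and
their spouses, asking each respondent (*ego*) to name the people with whom
they discuss important matters: a spouse plus up to five discussion
partners (up to six members in total), each described by name, gender,
age, administrative district (*Ri*), relationship, cohabitation, a 4-level
closeness code, an 8-level contact-frequency code, and a member-by-member
acquaintance matrix. `townnet` turns such records into the community's
complete directed network and the standard descriptive analyses, for
social epidemiologists and network researchers who want the whole chain —
simulation, resolution, measurement, reporting — reproducible and tested.

## What it computes

* **Ego-centric measures** — network size (0–6), proportions female / kin /
  cohabiting, average closeness, contact volume in days/year
  (categories coded 365, 182, …, 0.5 days), density
  (acquainted pairs / C(m,2)) and bridging potential
  (1 if some member knows no other member). Undefined cases (size < 2)
  stay missing, never zero.
* **Entity resolution** — two mentions are the same person iff all four
  criteria hold: ≥ 2 of 3 name tokens match position-wise, same gender,
  age gap < 5 years, same district. Reports are matched to the respondent
  roster first, the rest merged by union–find transitive closure;
  accuracy is scored against planted ground truth as pairwise
  precision/recall.
* **Node retention** — a merged person is dropped only if *both* not a
  respondent's spouse *and* living outside the township.
* **Complete-network measures** — in/out-degree; normalized closeness on
  the undirected projection with the Wasserman–Faust reachable-set
  correction `|R|² / ((N−1) Σd)` (within-component and harmonic variants
  selectable); normalized betweenness (fractional credit, pairs excluding
  the focal node); Gould–Fernandez brokerage over districts — coordinator,
  gatekeeper, representative, itinerant, liaison — in both classic
  counting and a mode that requires the bridged endpoints to be
  disconnected otherwise.
* **Components** — weak/strong components, a five-class typology
  (largest, second largest, 3–7, dyads, isolates) and per-class summaries.
* **Tables** — grouped means by age band, gender, marital status,
  education and 3-group self-rated health, with one-way ANOVA (computed
  from the sum-of-squares decomposition), and overall mean / SD /
  adjusted Fisher–Pearson skewness.
* **Synthetic townships** — `generate_township()` simulates the whole
  survey with planted ground truth (identity map, segregated district,
  size–health link), so every stage is testable without confidential data.

## Worked example

```r
library(townnet)

cfg  <- township_config(n_population = 860, seed = 1)
town <- generate_township(cfg)
town
#> Synthetic township
#>   roster: 860 persons in 10 districts
#>   respondents: 813
#>   alter reports: 2515

m <- ego_metrics(town)
round(colMeans(m[, c("size", "density", "bridging_potential",
                     "avg_closeness", "contact_volume")], na.rm = TRUE), 3)
#>            size           density bridging_potential     avg_closeness
#>           3.093             0.982              0.001             3.274
#>  contact_volume
#>         679.758

res <- resolve_duplicates(town$surveys, town$roster)
net <- build_complete_network(res)
net
#> Complete network: 860 nodes, 1962 directed ties
#>   exclusion filter removed 553 of 1413 merged persons

find_components(net, "weak")
#> 85 weak components over 860 nodes
#>   largest sizes: 727, 4, 2, 2, 2

tabs <- build_table(m, "srh_group", town$roster, measure_cols = "size")
tabs[["size.srh_group"]]
#> size by srh_group
#>             category   n proportion  mean
#>                 good 373      0.459 3.113
#>   poor_somewhat_poor 371      0.456 2.984
#>  very_good_excellent 69       0.085 3.580
#>   ANOVA p = 0.0125 | overall mean 3.093, SD 1.55, skewness 0.108
```

Respondents report about 3.1 network members on average in almost fully
dense ego networks (density 0.98, so bridging potential is nearly absent),
the duplicate-resolution step collapses 2,515 mentions onto 1,413
canonical persons of whom the non-spouse outsiders are excluded, and
respondents with better self-rated health hold larger networks (ANOVA
p ≈ 0.01). `run_pipeline(output_dir, generator = cfg)` executes the whole
chain and writes every stage output (roster/egonet/acquaint CSVs, metrics,
node/edge lists, GraphML, centralities, brokerage, components, class
summaries, grouped tables) plus a manifest; identical config and seed
reproduce every file byte for byte.

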
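# careshed

Walking-time access to childbirth care over rugged rural terrain.

## What this is for

In many rural districts, delivery services are spread across dozens of
small dispensaries that are individually too under-staffed and
low-caseload to provide safe care around the clock. Health planners face a
trade-off: concentrating deliveries in fewer, stronger sites improves
quality, but may push women beyond the two-hour travel window conventional
for reaching basic emergency obstetric care. `careshed` quantifies that
trade-off. It is aimed at health-systems researchers and district planners
who have (or can synthesize) an elevation model, a land-use map, a road
network, a gridded population and a facility list.

## The model in brief

Pedestrian speed follows the Naismith–Langmuir rule: a basal 4 km/h
(15 min per horizontal km), +0.1 min per metre climbed, −0.03 min per
metre descended for slope angles in (−5°, −12°], and +0.03 min per metre
descended beyond −12°. Crossing times are multiplied by slope-class and
seasonal land-use friction coefficients; lakes and swamps are impassable.
Travel time to the nearest facility is computed with two independent
engines:

* **raster** — exact anisotropic least-cost accumulation (multi-source
  Dijkstra) over 16-neighbour moves on the 90 m elevation grid;
* **network** — shortest paths on a virtual triangular mesh (223 m sides)
  merged with the classed road network, with direction-dependent edge
  times; an optional multimodal mode rides motorable roads at 20–75 km/h.

Population coverage is tallied in 20-minute bands (cumulative % within
≤ 1 h, ≤ 2 h, > 2 h), facility tables are summarised by staffing (0/1/≥2
skilled birth attendants) and caseload classes (0–49/50–99/100–199/≥200),
and a greedy maximal-coverage planner evaluates reduced-delivery-site
scenarios with hospitals locked in.

## Worked example

Everything below runs on the packaged synthetic reference district — a
27 × 27 km seeded landscape with 90 villages, 120 000 people and 20
delivery facilities — so no proprietary geodata is needed.

```r
library(careshed)

d <- reference_district(42)
ctx <- cost_context(d$terrain, d$landuse)
surface <- accumulate(ctx, d$facilities)
surface
#> <travel_time_surface> 300 x 300 cells, 20 sources, mode pedestrian
#>   reachable: 87300 cells, median 46.5 min, max 174.6 min

coverage(surface, d$pop)
#> <coverage_table> scenario 'baseline', 120000 people
#>   bound cum_pct
#> 1    20    35.1
#> 2    40    66.3
#> 3    60    80.4
#> 4    80    92.1
#> 5   100    99.1
#> 6   120    99.6
#> le_60: 80.4%  le_120: 99.6%  gt_120: 0.4%
```

80.4% of the synthetic population lives within one hour's walk of a
delivery site and 99.6% within two hours (the reference district is
deliberately facility-dense; see the methods vignette). Facility
statistics and a ~40% site-reduction scenario:

```r
facility_summary(d$facilities)
#> <facility_summary> 19 first-line facilities
#>   SBA counts      : 0=3  1=9  >=2=7
#>   caseload classes: 0-49=11  50-99=3  100-199=2  >=200=0  missing=3
#>   caseload median 42.5 (range 5-168); <100 in 14; hospital share 40.0%

tt <- facility_travel_times(d$facilities, ctx, d$pop, "raster")
locked <- d$facilities$id[d$facilities$level == "hospital"]
scn <- reduce_sites(tt, target_count = 13, locked = locked)
sprintf("baseline 2-h coverage %.1f%%, reduced %.1f%%",
        scn$baseline_pct, tail(scn$coverage_pct, 1))
#> [1] "baseline 2-h coverage 99.6%, reduced 99.6%"
```

Dropping 7 of 20 sites costs essentially no 2-hour coverage here: the
greedy planner keeps the sites whose catchments do not overlap. The
statistics of the two real worked-example districts (staffing and caseload
class counts, medians 65 and 22, hospital shares 28.0% and 68.7%) are
reproduced exactly by `facility_summary(reference_facility_table("iringa"))`
and `...("ludewa")` on synthetic stand-in tables that match every
published aggregate.

The full pipeline (synth → both engines → coverage → stats → scenario →
JSON manifest) is one call, or a CLI:

```r
run_pipeline(run_config(seed = 42), "out/")
```

```sh
inst/cli/careshed run-all --seed 42 --out out/
```

## Layout

* `R/`, `src/` — implementation (geodata IO, speed model, raster and
  network engines, coverage statistics, scenario planner, synthetic
  districts, pipeline CLI)
* `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles
* `vignettes/methods.Rmd` — the full model description, design decisions
  and limitations
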
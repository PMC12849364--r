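---
title: "Optimizing hospital service allocation by population-weighted travel time"
author: "pmedAccess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing hospital service allocation by population-weighted travel time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmedAccess)
```

## The planning problem

When a health system reorganizes which hospitals provide a specialized
service — pediatric emergency and inpatient care is the motivating case —
the geographic question is: given a fixed stock of hospital sites, which
subset of p sites should carry the service so that the population's car
travel time to the nearest service site is as small as possible? The
package frames this as a **p-median problem**. Patient homes are
represented by the centroids c of a hexagonal grid laid over the country;
each centroid carries the population of its cell (cell area times the
local population density `p_c`). For every centroid–hospital pair the
travel time `t_ch` in minutes is computed, and the population-weighted
travel time

    w_ch = p_c * t_ch

forms the objective coefficients. With binary assignment variables `x_ch`
(patient c treated at hospital h) and site indicators `y_h` (hospital h
carries the service), the program is

    min  z = sum_c sum_h x_ch * w_ch
    s.t. sum_h x_ch = 1            for every c      (every patient served)
         x_ch <= y_h               for every c, h   (only open sites serve)
         sum_h y_h = p                              (exactly p sites)

The linking family `x_ch <= y_h` can be swapped for the aggregated Big-M
form `sum_c x_ch <= M y_h` (one constraint per site; weaker relaxation,
smaller model). The default Big-M constant is `M = m`, the number of
demand points — the tightest universally valid choice, since at most all
m points can be assigned to one site.

Two policy scenarios wrap this core:

* **liberal** — any candidate hospital may receive the service;
* **prioritized** — existing service sites are protected: for p above the
  current count they are all retained and only the additions are
  optimized; for p below it, selection is restricted to the current
  sites; at p equal to it the current configuration is returned unchanged
  (the model is fully pinned, so no optimization is run).

## How the model is solved, exactly

The integer program is assembled in R (`buildPMedianModel()`) and handed
to the HiGHS branch-and-cut solver. Two numerical choices matter:

* **Assignment variables are declared continuous in [0, 1].** For any
  fixed binary `y`, an optimal `x` assigns each demand point wholly to
  its cheapest open site, so an integral optimum always exists and the
  reformulation is exact while shrinking the branch-and-bound tree to the
  site variables only. At the package's default scale this is the
  difference between seconds and minutes per solve.
* **Assignments are always re-derived from the open set** by the
  nearest-open rule in `w` (ties broken by column order). The solver's
  `x` may be degenerate at tolerance; the nearest-open rule is
  well-defined, deterministic, and is also the convention under which all
  travel-time statistics are reported. The reported objective is likewise
  recomputed as `sum_c min_{h open} w_ch`, independent of the solver's
  objective value (they must agree to 1e-6 relative; the solver is run at
  an integrality gap of 1e-6).

An exhaustive-enumeration oracle (`bruteForcePMedian()`) scores every
feasible open set directly and breaks ties lexicographically. It refuses
instances beyond a subset cap (default 2e6) rather than sampling
silently. The test suite requires objective equality between the solver
and the oracle across random instances in all scenario modes and both
linking formulations; because optimal site sets need not be unique,
tests compare objectives, never site identities (except through the
oracle's deterministic tie rule).

Solver infeasibility (p exceeding the openable sites after pinning) is a
reported status, not an exception, so quantity sweeps can record and
continue.

## The k-means heuristic

The alternative allocator clusters demand points with k-means and opens
one hospital per cluster. Demand points are observations in an
n-dimensional feature space: the columns of `W`, i.e. each point's
weighted travel times to the n hospitals. Lloyd's algorithm with
k-means++ seeding runs `n_restarts = 10` times (a common default; the
method is seeding-sensitive) and the best inertia wins; all restarts are
seeded deterministically.

Mapping a feature-space center to a concrete hospital is genuinely
underdetermined — a center is not a location. The default
`center_argmin` rule opens, for each cluster, the hospital whose center
coordinate is minimal, i.e. the hospital with the smallest mean weighted
travel time from the cluster's members. This rule is adopted because it
provably recovers the exact 1-median at k = 1, giving the heuristic a
verifiable anchor. A `geographic` variant (population-weighted clustering
of coordinates, centers matched to the travel-time-nearest hospital via
their closest demand point) is provided behind the `matching` flag, since
both procedures are plausible readings of "match each cluster center to
its nearest hospital". When two clusters prefer the same hospital,
clusters are processed in descending member-population order and each
takes its best not-yet-taken site (with a warning), so exactly k distinct
sites always come back. On the shared objective the heuristic can never
beat the exact optimum, and the suite asserts that inequality on every
instance — the formal version of the observation that clustering-based
allocation improves travel burden less than exact optimization.

## Accessibility statistics

For a set of open sites, each demand point's travel time is its
nearest-open minutes. The package reports, overall and per urbanization
stratum (urban / intermediate / rural):

* **weighted** mean, median and IQR — *population-frequency-weighted*
  statistics of the minutes, i.e. each point contributes its cell
  population as a frequency weight. Results stay in minutes. (Taking
  statistics of `w = p_c * t` literally would produce person-minutes,
  two orders of magnitude off any reported travel time; the frequency
  reading is the one consistent with minute-scale results.)
* unweighted mean, median and IQR across centroids;
* the share of population whose travel time **strictly exceeds** the
  threshold (default 40 minutes, the German regulatory benchmark for
  pediatric emergency access), plus the absolute population above it.

Weighted quantiles use the *lower weighted quantile*: sort by value and
return the smallest value whose cumulative weight reaches `q` of the
total. No interpolation — the estimate is an observed travel time,
reproducible and insensitive to convention drift; users comparing against
interpolating estimators should expect small discrepancies on coarse
grids, where travel times are quantized by the lattice geometry.

Distribution comparisons use the two-sided Mann-Whitney U test with
tie-corrected normal approximation on the unweighted per-centroid
samples, after Shapiro-Wilk normality checks (samples above 5000 are
thinned to 5000 evenly spaced order statistics — deterministic and
shape-preserving; travel-time distributions are never close to the
borderline where thinning could flip the verdict). The U statistic
follows the first-sample convention (pairs where the first sample
exceeds the second, plus half the ties). Change reports give absolute
and percent deltas for every metric; proportions additionally in
percentage points; zero baselines yield `NA`, never infinity.

## The synthetic country

The real analysis this package supports runs on curated national
hospital registries, administrative density tables and road routing —
data that cannot be redistributed. The generator replaces them with a
synthetic geography carrying the same statistical structure:

* a rectangular country tiled into Voronoi regions of uniformly sampled
  seeds (irregular, convex, administrative-looking cells with exact
  shoelace areas);
* each region drawn into one of three urbanization classes and given a
  uniform density from its class range;
* a pointy-top hexagonal centroid grid (spacing `s` km, cell area
  `sqrt(3)/2 * s^2`), each centroid inheriting the containing region's
  density and class, ties at region borders to the lowest region id;
* candidate hospitals sampled without replacement at centroid locations
  with probability proportional to `density^site_density_bias`, and a
  subset flagged as current service sites by the same biased draw —
  hospitals concentrate where people are, and placing them on centroids
  makes zero travel time attainable, exercising the degenerate case;
* straight-line travel at 70 km/h inflated by a circuity factor of 1.3,
  a standard approximation of road-network detour.

Defaults mirror the motivating countrywide setting at roughly one tenth
scale: a 280 x 380 km rectangle, 40 regions with class shares
0.25 / 0.40 / 0.35 and densities 500–3000 / 100–500 / 30–150 persons per
km², spacing 10.5 km (about 1100 centroids), 100 candidate sites, 31
current service sites (preserving the ~30% service share of the
motivating hospital registry), density bias 1. All stages are
deterministic functions of one seed.

What the generator does *not* emulate: road networks (travel time is
circuity-inflated straight-line, so no mountain passes or river
crossings), within-region density gradients (densities are piecewise
constant), coastline or border clipping (boundary hexagons keep their
full area — a small, documented bias also present in the population
totals), and any correlation between hospital capacity and location.
Passing tests therefore demonstrate correctness of the algorithms and
the claimed inequalities/identities under realistic scale and
heterogeneity — not calibration to any real country's numbers.

The two-grid protocol of the real analysis (optimize on a coarse grid,
evaluate metrics on a fine one) is supported: `runSweep()` and the
solution evaluators accept an evaluation grid distinct from the
optimization matrix. In synthetic mode the default is a single grid.

## Problem sizes and runtime

The default desk-scale study (about 1100 centroids by 100 sites) solves
in roughly 5–15 seconds per p-median instance; the bundled end-to-end
analysis including a quantity sweep over p in {20, 25, 30, 35, 40} in
both scenarios completes in about a minute. Oracle-equivalence checks
run at m ≤ 40, n ≤ 10, p ≤ 4, where exhaustive enumeration is instant.
These sizes were chosen so that the full structure of the countrywide
analysis — heterogeneous regions, a thousand-point grid, a meaningful
service share — is present while every result remains reproducible on a
single CPU.

## Degenerate inputs and edge rules

* Unreachable centroid–hospital pairs are an input error, not infinity:
  the objective must stay finite. The routing adapter rejects them.
* Zero-density cells carry zero weight; their rows of `W` are zero and
  any open site is equally good for them (ties to the first column).
* `n_service = n_hospitals` flags every site; `p` equal to the number of
  candidates opens all of them without a solver call.
* A hex spacing wider than the country is an "empty grid" error, not an
  empty object.
* Weighted quantiles refuse all-zero weights; distribution comparisons
  refuse samples shorter than 3.

## Known limitations

Only car travel time is modeled — no public transport, congestion, or
seasonal variability. Hospital capacity, case mix and regulatory
mandates are out of scope; the optimization treats all sites as
interchangeable vessels for the service. The k-means path is a
heuristic: its value is as a comparator, and the package's own tests
show it is dominated by the exact method on the shared objective.
Optimal site sets need not be unique; when ties occur the solver's
choice is arbitrary (the enumeration oracle's is lexicographic), so
downstream comparisons should rely on objectives and metrics rather
than site identities.
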
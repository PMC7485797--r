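---
title: "Multiple decrement life tables for stem-dwelling insect cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple decrement life tables for stem-dwelling insect cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdlt)
```

## The problem

Immature stages of the wheat stem sawfly (*Cephus cinctus*) spend their whole
pre-adult life inside a host stem, where they are exposed to several
mutually exclusive causes of death: host-plant defense acting on newly
emerged neonates (antibiosis), obligate cannibalism whenever a stem holds
more than one occupant, parasitoid attack during a mid-season vulnerable
window, entomopathogenic fungi during overwintering, and a residual
"unknown factors" class.  Because dissection of a stem is destructive, the
data are repeated cross-sections — weekly stem samples through the summer
and collections of overwintered "stubs" before and after the adult flight
period — rather than longitudinal follow-up of individuals.

This package implements the estimator chain such a study needs:

1. ingestion and validation of dissection records, with a fixed mapping
   from physical evidence codes to causes of death (`read_records()`,
   `classify_cause()`, `assign_stage()`, `aggregate_counts()`);
2. abridged multiple decrement life tables (`mdlt()`);
3. elimination-of-cause analysis: net probabilities of death, joint
   mortality of cause subsets, and irreplaceable mortality
   (`eliminate()`, `solve_two_cause()`, `irreplaceable()`);
4. a stage-structured competing-risks cohort simulator with known ground
   truth (`simulate_cohort()`), so the whole chain can be validated without
   access to field data;
5. pipeline orchestration and replicate summaries (`run_pipeline()`,
   `summarize_replicates()`).

## The life-table model

Let `x` index the sampled developmental classes in order — egg, Larva I
(pre-parasitism), Larva III (parasitism window), Larva IV (overwintered,
pre-flight), Larva V (overwintered, post-flight), adult.  For each
non-terminal stage the data supply `l_x`, the number of individuals
examined at the stage, and `d_ix`, deaths attributed to cause `i` among
them.  The stage-specific probability of dying from all causes is

    aq_x = d_x / l_x,      d_x = sum_i d_ix.

Cohort columns follow by recursion from a radix of 1:

    al_1 = 1,   ad_x = al_x * aq_x,   al_{x+1} = al_x - ad_x,

and stage mortality is apportioned among causes proportionally to the
observed deaths, `ad_ix = al_x * (d_ix / l_x)`, so the cause columns sum to
`ad_x` exactly and the cause totals `aD_i = sum_x ad_ix` partition total
mortality.  Two conventions matter:

* **`l_x` is not cohort survival.**  Stage counts come from independent
  cross-sectional samples, so the raw `l_x` column may be non-monotone
  (a later stage can be sampled more heavily than an earlier one).  The
  survival column is always produced by the `aq_x` recursion, never by
  reading `l_x` down the table.  Stage probabilities estimated this way are
  treated as conditional-on-entry probabilities, with no correction for the
  same stage being sampled on several occasions; that is the abridged-table
  method, and its approximations are inherited deliberately.
* **Conditional versus unconditional decrements.**  Internally the object
  stores both `cq_ix = d_ix / l_x` (conditional on being alive at stage
  entry) and `ad_ix = al_x * cq_ix` (proportion of the original cohort).
  Serialization prints the unconditional values, which is how printed
  tables of this kind are laid out; the terminal adult row repeats final
  survival in the `ad_x` column so the accounting closes to 1.

Numerical policy: all arithmetic is done in full precision; rounding is a
display/serialization concern (3 decimals, 4 for nonzero values below
0.01).  `mdlt_from_aq(..., digits = 3)` additionally offers per-step
rounding of the recursion, which reproduces desk arithmetic on an already
rounded printed table — useful when checking a published table whose
internal entries were themselves rounded before the recursion was run.
Degenerate inputs: a non-terminal stage with `l_x = 0` is an error unless
`skip_empty_stages = TRUE`, which bridges it with `aq_x = 0` and a warning.

```{r}
fit <- mdlt_from_aq(c(0.619, 0.478, 0.554, 0.169, 0.1368), digits = 3)
fit$table$al_x
```

## Cause classification and staging

Evidence codes map to causes with a fixed precedence when codes co-occur:
parasitoid/predator evidence over fungal evidence over multiplicity
(cannibalism) evidence over neonate/feeding-scar (plant defense) evidence
over the residual class.  The rationale is that specific physical evidence
(a cocoon, hyphae on the cadaver) dominates circumstantial evidence such as
multiple occupancy.  Parasitoids and predators are pooled into a single
"parasitism" class, as predation on stem-dwelling larvae is rare and
evidentially indistinguishable in routine dissection.

Dead and live larvae in weekly stem samples are staged by sampling week:
weeks 2–4 precede the parasitism window (Larva I), weeks 5–9 fall within
it (Larva III).  Week-1 larvae are biologically unexpected (week 1 should
contain eggs only) and are assigned Larva I with a warning rather than
rejected.  Egg-multiplicity evidence (`MULTIPLE_EGGS`, `LARVA_PLUS_EGG`)
marks a dead *egg*, staged at the egg stage regardless of sampling week.
Parasitism recorded before the vulnerable window draws a warning, matching
the structural zeros such tables show at the egg and Larva I rows.

**Prospective cannibalism scoring.**  Cannibalism in this species is
obligate: at most one occupant survives per stem.  A dissector who finds a
multiply-occupied stem therefore scores the surplus as already doomed:
with a live larva present, every live egg is a cannibalism decrement at
the egg stage and every extra live larva a decrement at its observed
stage; in an all-egg stem with `e > 1` eggs, `e - 1` are egg-stage
decrements.  `aggregate_counts(prospective = TRUE)` implements this field
convention (a doomed occupant still counts once in `l_x`).  Turn it off
for records that already carry explicit cannibalism evidence per death —
the simulator's census mode — since scoring both would double-count.

## Elimination of cause

Crude totals `aD_i` describe mortality *in the presence of* the other
causes.  To ask what a cause would do on its own, the two-cause
elimination solves, for crude proportions `D1` and `D2` with some
survivors (`D1 + D2 < 1`), the system "joint survival factorises" and
"risks are proportional":

    (1 - q1)(1 - q2) = 1 - (D1 + D2),      q1 / q2 = D1 / D2.

Substituting gives the quadratic `a q2^2 + b q2 + c = 0` with `a = D1`,
`b = -(D1 + D2)`, `c = D2 (D1 + D2)`.  The smaller root is taken: on the
valid domain the larger root always exceeds 1, while the smaller lies in
`[0, 1)` (verified by a grid property test against an independent
bisection solver).  Degenerate inputs short-circuit: if one crude
proportion is zero the other cause's net probability equals its crude
proportion.  `D1 + D2 >= 1` is a domain error — with no survivors the net
probabilities are unidentified.

For five causes the package uses focal-versus-pooled-rest solves: cause
`i`'s net probability `q_i` comes from `solve_two_cause(D_i, sum(D[-i]))`.
A simultaneous proportional-risk solution for all causes at once exists
and is kept as an independent test oracle; the pairwise scheme is the one
used for reporting because it mirrors how such analyses are conventionally
run (each cause against "all other mortality causes"), and the two agree
exactly in the two-cause case.  The schemes differ slightly for small
causes competing against a large pooled rest; reports always state the
scheme through the `mode` field.

**Irreplaceable mortality** of a focal cause is the part of total
mortality the remaining causes would not replace:

    irr_i = D_total - q_rest,

where `q_rest` is the net mortality of the pooled non-focal complement —
the `q2` companion root of the focal cause's own elimination solve.  This
choice has a clean guarantee: since `D_total - D_i <= q_rest <= D_total`,
the result always lies in `[0, D_i]`.  (Combining the non-focal causes'
*individually* solved net probabilities instead can exceed `D_i`, because
those probabilities are not mutually consistent; the package does not do
that.)  A floor at zero guards against floating-point negatives.

Two modes are exposed.  `totals` (default) eliminates on whole-cohort
crude totals, which is how pooled headline statements read.  `per_stage`
eliminates within each stage's conditional probabilities and recombines
survival across stages before subtracting, the way spreadsheet
implementations of stage-structured elimination operate.  Stage-wise
recombination lets replacement act across stages, so the per-cause ceiling
`irr_i <= D_i` is a totals-mode property only; per-stage results are
bounded by total mortality.

Crude combination statements ("these three causes would kill X% of the
population") are plain sums `100 * sum(D_i)` reported at integer
precision, with halves rounded away from zero as in reports (not banker's
rounding).

```{r}
D <- c(parasitism = 0.015, plant_defense = 0.165, cannibalism = 0.701,
       unknown = 0.054, pathogens = 0.002)
eliminate(D)
crude_combination(D, c("cannibalism", "unknown", "plant_defense"))
```

## The synthetic cohort generator

`simulate_cohort()` generates dissection records with a known ground truth
under the replicated design of the motivating study: site-years x 3 blocks
x 8 cultivar plots, weekly stem samples of 3 bags x 35 stems over 9 weeks,
and 25-stub collections pre- and post-flight.  Within a stem:

* the egg load is negative-binomial (`dispersion` is the size parameter;
  default 1.2).  Overdispersion reflects several females ovipositing in the
  same attractive stems; a Poisson and a fixed-count option exist for
  degenerate checks.  No eggs-per-stem distribution is reported for this
  system, so the default is a testability choice, not a calibration;
* eggs hatch in staggered order (hatch weeks 2–4); each neonate
  independently dies of plant defense at emergence with the cultivar's
  `p_plant_defense`;
* the first plant-defense survivor claims the stem; one week later it has
  consumed every other occupant.  Occupants still unhatched at that point
  die of cannibalism at the egg stage; hatched rivals (same-week
  survivors) die at Larva I.  Cannibalism is thus resolved after
  plant-defense deaths and before parasitism, matching the stage ordering
  of neonate mortality preceding larval encounters.  At most one occupant
  survives per stem, always;
* the survivor passes the parasitism window (`p_parasitism`, then
  `p_unknown_early`, both at Larva III) and the overwintering stages
  (`p_pathogens` then `p_unknown_late`, drawn at Larva IV and again at
  Larva V), emerging as an adult otherwise.

Default cultivar parameters span the attractiveness-versus-antibiosis
tradeoff (attractive cultivars: high egg intensity, low neonate mortality;
defended cultivars: the reverse), so the negative correlation between
cannibalism and plant-defense mortality emerges from the parameters rather
than being hard-coded.  Per-plot random streams are derived hierarchically
from the seed, so enlarging the design does not perturb existing plots'
draws.

**Census versus survey sampling.**  The generator has two emission modes,
and the distinction is the core of the validation design:

* `census` reports every occupant exactly once per stage it entered —
  alive if it survived the stage, as a dead observation with explicit
  evidence where it died.  Aggregating census records (with prospective
  scoring off) reproduces the ground-truth event log *exactly*, so the
  life-table recursion, apportionment and totals can be checked to
  machine precision, and parameter-recovery tests are tests of the
  estimator chain rather than of sampling noise.
* `survey` emulates the field protocol: each stem is dissected at most
  once, at its sampled week or stub phase, and scored as a dissector
  would score it then — live occupants by stage, dead occupants only
  while their evidence is fresh (the sampling window in which the death
  occurred; older remains are not re-scored), prospective scoring of
  doomed surplus, week-binned staging.  This mode deliberately carries
  the field method's attribution approximations: deaths surfacing late in
  a window are staged by sampling week, and surplus occupants scored
  prospectively as cannibalism may in truth die of plant defense first.
  Survey estimates therefore reproduce the *scoring conventions* of field
  tables (including their characteristic artifacts, e.g. small
  plant-defense or cannibalism entries appearing in the Larva III row),
  and they are validated structurally and qualitatively, not against a
  tight error band.  Passing census-mode tests shows the estimator chain
  is correct; it does not show that destructive weekly sampling is an
  unbiased design — it is not, and the package reproduces it faithfully
  rather than correcting it.

Stub collections draw without replacement from cut stems (survivors of all
pre-winter causes) never taken in summer sampling; a plot with fewer
available stubs than requested yields a smaller collection with a warning,
while requesting more weekly stems than the stand holds is an error.

## Validation problem sizes

The shipped tests run the elimination grid at 20 x 20 crude-proportion
pairs against a bisection oracle at `1e-10`; irreplaceable-mortality
bounds on 1,000 random profiles; exact census recovery on cohorts of a few
hundred stems per plot; and a 20-replicate recovery study at 10,000 stems
per replicate across the eight default cultivars, requiring every crude
cause total to sit within three binomial standard errors of the realised
ground truth.  These sizes were chosen so the full suite stays
interactive-fast while the recovery study still has standard errors near
half a percentage point.

## Known limitations

* Causes are assumed independent wherever elimination is applied — the
  joint-survival product has no copula or frailty structure.  Biologically,
  cannibalism and parasitism interact (cannibals eat parasitised rivals);
  none of that enters the elimination algebra.
* No confidence intervals on life-table entries: uncertainty is reported
  only as replicate-plot standard errors of the crude percentages
  (`summarize_replicates()`), mirroring how such studies present means.
  Mixed-effects comparisons and post-hoc tests are out of scope.
* The survey sampling operator models neither partially decayed evidence,
  observer error in evidence coding, nor within-plot spatial structure;
  stems are exchangeable within a plot.
* The stage list follows the sampled classes of the motivating design
  (there is no "Larva II" class; the instar passed through between the
  pre-parasitism and parasitism windows is not separately observable in
  week-binned samples), and week-9 harvest samples are staged with weeks
  5–8.
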
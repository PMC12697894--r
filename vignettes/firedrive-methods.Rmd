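---
title: "Modeling homing suppression drives in fire ants: methods and design notes"
author: "firedrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling homing suppression drives in fire ants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model: what is simulated,
which parameters matter, where the design was genuinely open and how we
decided, and what the test suite does and does not establish.

## The biological system

The red imported fire ant is haplodiploid: females (queens, workers) are
diploid, males develop from unfertilized eggs and are haploid.  A homing
suppression drive targets a haplosufficient gene required for female
fertility.  In the germline of drive/wild-type heterozygous females, Cas9
cleaves the wild-type allele; homology-directed repair copies the drive
("drive conversion", probability `conversion`), otherwise end joining can
leave a nonfunctional resistance allele ("germline resistance").  Maternally
deposited Cas9 additionally cuts wild-type alleles in early embryos
(`embryo_resistance`), and leaky somatic expression reduces heterozygous
females' fecundity (`somatic_fitness`).  Males carry and transmit the drive
but it has no activity in them.  Females with no functional fertility allele
are sterile, and — because a queen without workers cannot sustain a nest —
sterile females never found colonies.

Colony social organization is controlled by the *SB/Sb* supergene.  Any *Sb*
copy makes a queen head a polygyne (multi-queen) colony; *Sb/Sb* females die;
polygyne workers cull *SB/SB* daughter queens (the greenbeard effect), so
polygyne colonies only export *SB/Sb* daughters and lose half their queen
production to culling.  Monogyne daughter queens disperse on nuptial flights
(average 100 m here); polygyne daughters bud short distances (half) and also
replace the reproductives of existing polygyne colonies.

## The colony life cycle

One time step is a year.  In order: ages increment; colonies of age 2+
produce daughter queens (Poisson, mean `(S(t) - 10000)/10800` times a 0.95
calibration factor and the queen's fecundity multiplier, with
`S(t) = 170000/(1 + 66 e^{-1.3t})` the monogyne-equivalent size); daughters
receive a maternal germline gamete plus the stored paternal genome, undergo
embryo resistance, and are filtered by viability, fertility and the
greenbeard rule before dispersing (Gaussian per axis, sigma set so the mean
displacement equals the configured average; out-of-arena draws are fully
redrawn).  Polygyne colonies then have a 50% yearly chance to adopt a newly
mated queen from a reproducing polygyne colony within budding range as their
representative genotype; a colony that seeks but cannot complete a
replacement (no candidate colony in range, no viable surviving daughter, or
the candidate fails to mate) dies with probability 0.8.  Age-1 queens take
up to 10 weighted mating attempts among colonies capable of producing
offspring (weight proportional to biomass times queen fecundity, polygyne
fathers discounted by 0.8374); monogyne queens reject *Sb*-bearing males;
unmated queens are removed.  Finally, survival: age-0 colonies by the
low-density rule `0.1 g/((g-1)R + 1)`, established colonies by
`L - 0.6714 exp(-2.2221e-5 S_t/R)` (`L` 0.95 monogyne/native, 0.9
polygyne), then age-related death (50% at age 6 and a hard cap at 7 for
monogyne and natives; a 70-year cap for polygyne).

Competition is pairwise: a source colony of age `t` exerts
`S_eff (1 - d/r_t)` on neighbors within its radius
`r_t = 2 sqrt(A_t/pi)`, where `A_t` is its territory (100 m² at maturity,
proportional to monogyne-equivalent biomass before that; the doubling lets
overlapping territories interact).  Polygyne sources exert 1.2 times the
monogyne-equivalent strength (twice the workers at 0.6 mass), but
polygyne-on-polygyne pressure is discounted by 1/1.2 because polygyne
colonies do not attack one another.  Cross-species terms are scaled by an
interspecies factor.  The *expected* competition — the denominator of the
competition ratio `R` — integrates this kernel over a uniformly random
population at carrying capacity (100 000 monogyne colonies in the full
1.85 km arena) with the stationary age structure, summed over source ages 1
through 7.  We include age-1 sources in both the expected reference and the
realized computation (their term is below 0.5% of the total) so that the
mean ratio is exactly 1 at capacity; age-0 colonies exert nothing.

### The scale of density regulation

The two survival responses act on different scales, and this is a deliberate
design decision.  Established-colony survival uses each colony's *local*
competition ratio: territorial fighting is a neighborhood affair, and this
is what lets colonies that escape into emptied space persist (the "chasing"
failure mode of spatial suppression drives).  Recruitment, in contrast, uses
the *population-level* ratio (the mean over established colonies of the
species): the low-density growth rate `g` is a population-scale quantity,
and it is this choice that makes the elimination threshold `1 - 1/g` of the
non-spatial theory carry over to the simulator.  We originally evaluated
recruitment at each offspring's landing position; because the kernel leaves
a few percent of the arena uncovered and the low-density response is convex,
that reading inflates equilibrium census roughly 1.5-fold above the intended
capacity and makes populations nearly immune to suppression (every locally
emptied patch triggers a recruitment surge).  Neither behavior is compatible
with the system being modeled.

Even with population-scale recruitment, residual heterogeneity in the local
survival response leaves equilibrium about 8-11% above nominal capacity
(checked at two fixture scales, so it is not an edge artifact).  The
parameter `competition_calibration` (default 1.1) multiplies the competition
ratio inside the simulator's survival step to trim exactly this, calibrated
once against the carrying-capacity criterion — the same empirical
calibration procedure that fixed the 0.95 offspring factor — and left alone
since.  Exported functions (`density_survival()`, the life table) are
untouched by it.

## Drive variants

* `standard`: recessive nonfunctional resistance at the fertility locus.
* `dominant_sterile`: any resistance allele sterilizes its carrier female.
* `two_target_haplosufficient` / `two_target_haplolethal`: the drive sits at
  (and rescues) an essential gene, while extra gRNAs cut a distant fertility
  locus at the total cut rate with no homing there.  Haploid males carrying
  a nonfunctional essential-gene allele are nonviable regardless of
  haplosufficiency — a haploid has no second copy; this male-viability rule
  is our own call, on biological grounds.
* `polygyne_drive`: the drive carries a dominant polygyne determinant.
* `greenbeard_drive`: drive-carrying *SB/SB* daughters escape the cull.
* `cleave_SB` / `cleave_Sb`: in drive-carrying *SB/Sb* germlines the social
  locus is converted (ideal efficiency) toward *Sb* or *SB*; a cleave-SB
  queen mated to an *Sb* male yields only *Sb/Sb* workers and her colony
  fails, and a cleave-Sb queen mated to an *SB* male cannot serve as a
  polygyne representative (all her daughters are culled).

Germline resistance is parameterized *conditionally* on non-conversion by
default (net rate `(1-c) r_g`), the only reading under which the default
pair (conversion 0.95, resistance 0.5) are both probabilities.  Setting
`germline_res_absolute = TRUE` treats the two as additive, with resistance
capped at `1 - c`; load sweeps over "total cut rate" use this mode.

## The panmictic layer

`panmictic_init()` / `next_generation()` iterate exact genotype-frequency
recursions over all diploid female and haploid male genotypes (enumerated
per variant, with precomputed gamete and embryo operators), seeded with a 1%
drive-male introduction.  `equilibrium_genetic_load()` iterates to a 1e-9
fixed point (period-2 oscillations are detected by comparing to the state
two generations back; a lost drive reports the load at its peak frequency
with a flag).  Genetic load is defined as one minus the fertile,
fecundity-weighted reproductive output of daughters relative to an all-wild
population, with nonviable daughters counting zero — the convention of the
suppression-drive modeling lineage, stated here explicitly because the term
is often used without a formula.  The recursion is verified in the test
suite against an independently coded stochastic Wright-Fisher haplodiploid
simulation (100 000 individuals, 25 generations, 3-standard-error
agreement).

With default drive parameters the equilibrium load is 0.899, above the
`1 - 1/6 = 0.833` deterministic elimination threshold at the default
low-density growth rate.  Published estimates for this system quote a
slightly lower equilibrium load (0.87); we probed every reading we could
construct (absolute versus conditional resistance, embryo cutting on or off
for sons and the paternal allele, male drive fitness costs, alternative load
denominators) and none reproduces that figure, so the package reports its
own computed value.

`monogyne_generation_time()` builds the equilibrium life table (low-density
recruitment at ratio 1, density survival, the age-6 and age-7 rules) and
returns the mean mother age weighted by `l_t m_t`: 4.77 years with defaults.
A commonly quoted figure for this construct is 5.4 years; we note that under
the stated fecundities the mean mother age cannot exceed about 5.3 even with
all mortality removed, so the discrepancy is structural, not a tolerance
issue.  An alternative convention — mother age when daughters themselves
mate — adds one year.  The polygyne effective generation time follows from
yearly genotype retention `(1 - p_repl) s`: about 2.8 years.

## Scenarios, releases, and metrics

Scenarios: monogyne-only (100 000 colonies), polygyne-only (61 882), the
mixed default (50 000 + 30 941, both forms interspersed over the arena),
native coexistence (adds 50 000 native colonies with symmetric interspecies
competition 0.5), and an invasion front (fire ants confined to the left 40%
of the arena — polygyne leftmost — natives to the right 60%, dispersal
raised to 138.75 m, competition asymmetric: natives exert half strength on
fire ants, suffer full strength; releases begin when fire ants reach half
the biomass in the left half of the seventh arena slice).  Releases add
drive males equal to 15% of the resident male pool for six years,
implemented as a per-attempt probability `0.15/1.15` that a mating samples a
released male (males are not agents); half the released males carry *Sb*;
pools expire yearly.  Metrics per year: colony counts and biomass by species
and form (biomass in monogyne-worker units, mass factor 0.6 for polygyne),
drive/resistance/*Sb* frequencies over queens plus stored mates, the
Clark-Evans nearest-neighbor index, and optional 10-slice biomass profiles.

## Numerical and implementation notes

Neighbor search uses a uniform grid (cell = maximum interaction radius) in
C++, verified exactly against brute-force all-pairs on mixed-species
instances; mate sampling uses max-weight rejection sampling over the
candidate disc (radius twice the queen form's dispersal sigma, nearest-50
fallback when empty), which reproduces exact weighted sampling.  All
randomness flows from the single seed given to `simulate_drive()`;
replicates derive sub-seeds from the base seed.  The stationary age
distribution is the fixed point of the survival recursion (tolerance 1e-10),
not hardcoded.  Degenerate inputs (empty populations, all-sterile queens,
zero-competition neighborhoods) are exercised in the tests.

Desk-scale runs use `make_fixture()`, which scales arena area and all counts
together so densities, competition ratios and per-capita rates are
unchanged; the shipped analyses use scale 0.04 (a 370 m arena with a
4 000-colony monogyne capacity), where a 100-year mixed run takes a couple
of seconds.

## What the generator emulates, and known limitations

The synthetic scenarios reproduce the study conditions: carrying-capacity
equilibria, the two-form social system, the release program, and the drive
variants.  They do not emulate landscape heterogeneity, weather-driven
vital-rate variation, worker-level behavior, sperm depletion, or functional
(target-preserving) resistance, which targeted-design gRNA multiplexing is
assumed to prevent.

Three limitations deserve emphasis.  First, the monogyne-polygyne
competitive balance is a knife edge: defensible readings of polygyne queen
production straddle outcomes from slow polygyne decline to rapid polygyne
takeover.  We use the monogyne-equivalent queen-production rule, under which
polygyne colonies decline slowly in drive-free mixed populations; this
preserves the robust qualitative result that the drive eliminates polygyne
colonies first while monogyne colonies persist at low level through chasing,
at the cost of the (supplementary) claim that polygyne should slowly gain
without intervention.  Second, the simulator's suppression timescales are
slower than some published figures for comparable settings (median ~62 years
to 90% biomass reduction under a perfect drive, versus ~30): the spatial
trajectory tracks our verified panmictic recursion, so closing that gap
would require roughly twice-faster drive fixation than the release size and
generation times permit under our reading.  Third, at the weakest drive
corner (conversion 0.8, fitness 0.8) the equilibrium load is ~0.49 and the
drive stalls near frequency 0.5, giving ~35-40% biomass reduction at year
100; deeper suppression there would require a load surface that stays high
at low conversion, which the genetics as specified do not produce.  All
three are documented as computed by `scripts/acceptance.R` and the test
suite; none was tuned.
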
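---
title: "Modeling endotoxin-induced acute inflammation with endoabm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling endotoxin-induced acute inflammation with endoabm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoabm)
```

## The model

`endoabm` is a stochastic, spatially explicit agent-based model of the acute
inflammatory response (AIR) of blood leukocytes to bacterial endotoxin
(lipopolysaccharide, LPS).  The world is a toroidal grid of 161 x 161
patches holding four composite macrophages and, during a response, a few
thousand mobile molecule agents.  Each macrophage is itself built from more
than 400 constituent agents: a membrane ring of 240 point agents around a
nuclear region, 60 receptors embedded in the ring (30 TLR4 endotoxin
receptors, 15 TNF receptors, 15 IL-4 receptors), and 120 inactive
NF-kB:IkBa complexes in the cytosol.  T-helper precursors (Th0) enter the
world while pro-inflammatory mediators circulate and differentiate into Th1
or Th2 effectors.

Signal propagation follows the canonical NF-kB cascade as local,
probabilistic interaction rules rather than mass-action kinetics:

* **Recognition.** Free LPS random-walks; on contact with an unoccupied
  TLR4 it binds with probability governed by the receptor's *sensitivity*
  counter: an integer is drawn uniformly on 1..5 and binding succeeds when
  the draw is strictly below the current sensitivity, so a fresh receptor
  (sensitivity 5) binds with probability 4/5 and a desensitized one
  (sensitivity 1 or 0) not at all.  Every successful binding decrements the
  sensitivity, releases one TNF-a unit, opens a renewable 100-tick
  activation window that emits a further TNF-a unit per 100 active ticks,
  and the bound LPS is degraded within 1-2 ticks.
* **Amplification.** Free TNF-a (600-tick budget) binds TNFR; each newly
  formed TNF-TNFR complex activates the cell's currently inactive IKK pool
  (kinase is produced at 1 unit per 5 ticks and degrades after a uniform
  1-799 tick lifetime).  Active IKK binds an inactive NF-kB:IkBa complex on
  contact with probability 0.70, dissociates after 10 ticks, the IkBa
  partner is ubiquitinated, and the freed NF-kB translocates to the nucleus.
* **Transcription.** Every 10 nuclear ticks NF-kB directs one transcription
  cycle: exactly 1 activated IkBa, 1 unit of IL-12 with probability 0.80,
  and 1 unit of TNF-a (amplified while the cell's energy switch is on).
  Each cycle costs the macrophage one unit of energy.
* **Negative feedback.** Activated IkBa seeks activated NF-kB within a
  1-patch radius (nucleus entry permitted), re-forming the inactive complex
  in the cytosol, and shuts down kinase inside its zone of influence.
* **Anti-inflammatory arm.** While free IL-12 is present, the world
  produces 3 units of IL-4 with probability 0.86 every 1-5 ticks.  IL-4
  binding to a macrophage receptor raises the energetic level by one;
  Table-literally, a bound IL-4 near a forming TNF-TNFR complex extends the
  complex's degradation from 50 to 200 ticks (a config flag
  `il4_speeds_tnf_decay` swaps the two constants for the alternative
  text reading, under which anti-inflammatory binding accelerates TNF-a
  removal; the two readings are never merged).
* **Cellular arm.** Th0 cells enter while circulating IL-12 exceeds a
  threshold, count the interleukin units bound on their surface, and at 25
  units differentiate irreversibly: Th1 when IL-12 strictly outnumbers
  IL-4, otherwise Th2.  Th1 secretes IL-12, Th2 secretes IL-4.
* **Bistability switch.** When a macrophage's energy falls strictly below
  25% of its initial value, its TNF-a output per transcription cycle is
  amplified and anti-inflammatory production is boosted; energy-starved
  cells also fail to resynthesize IkBa on every cycle
  (`p_ikba_starved`), weakening their own negative feedback.

One tick advances the world through a fixed phase order (dosing, LPS,
receptor production, TNF-a, macrophage production and chemotaxis, IKK,
NF-kB transcription, IkBa, cytokines, T helpers, energy update, census).
Molecular agents move every tick; cellular agents every 800th tick, which
realizes the published 800:1 movement-frequency ratio without 800 molecular
sub-steps per tick.  Macrophages are chemotactic: they turn toward the
45-degree sector with the highest free-LPS count within `5 + cell radius`
patches (ties to the lowest sector index, east first).

## Time mapping and problem sizes

The rule constants are stated in ticks; the hour axis of the dosing
scenarios requires a conversion that we expose as `ticks_per_hour`
(default 800, the same constant as the movement-frequency ratio).  A
24-hour run is therefore 19,200 ticks.  At this scale a full scenario
replicate takes on the order of a second, and the shipped test-suite
ensembles use 20 seeded replicates per scenario; these sizes are the
package's own choice of a desk-scale study design.

## Tracked quantities and outcome classification

Per tick the engine records the model's aggregate observables: total LPS in
circulation (bound plus free), free TNF-a, the pro-inflammatory indicator P
(circulating IL-12), the anti-inflammatory indicator A (IL-4 agents, free
and receptor-bound), the energetic state E (summed macrophage energy),
activated NF-kB/IKK/IkBa summed over all cells, and the Th0/Th1/Th2 census.

`classify_outcome()` calls a run **resolved** when (i) the stimulus was
eliminated (total LPS reached zero and stayed there) and (ii) the three
pro-inflammatory channels - P, free TNF-a and activated NF-kB - each
returned to within `tol` (default 5%) of their pre-dose baseline, relative
to each channel's own run peak, and held that band through the 24 h horizon
for at least `hold_hours` (default 1 h).  Requirement (i) goes beyond a
pure channel criterion: a self-limited episode means successful elimination
of the stimulus *followed by* transcriptional resolution, and the runs that
retain stimulus at the horizon are exactly the persistent class.  The
channel-only behavior is available with `require_clearance = FALSE`.  The
numeric `tol` and `hold_hours` are artifact definitions, exposed in the
configuration.

## Parameters and their provenance

Printed rule constants (fixed, not calibration dials): sensitivity maximum
5 with strict-below comparison, bound-LPS decay 1-2 ticks, TNF-a budget
600, bound-TNF decay 50/200, IKK production interval 5 and lifetime 1-799,
binding probability 0.70, dissociation after 10 ticks, transcription
interval 10, IL-12 probability 0.80, IL-4 burst 3 at 0.86 every 1-5 ticks,
TLR4 production interval 100, differentiation threshold 25, energy-switch
fraction 25% (strict), movement ratio 800, world 161 x 161 with 4
macrophages, >400 constituents per cell, and the seven dose schedules.

Everything else is an artifact default fixed once by pattern-oriented
calibration (parameter sweeping) against the self-limited pattern -
stimulus clearance within the first 2 h and resolution within 24 h - and
then frozen:

* geometry and copy numbers: cell radius 10, nucleus radius 4, membrane
  240, receptors 30/15/15, 120 NF-kB per cell (the documented composition
  of 420 constituents);
* movement: LPS step 20 patches per tick ("several steps forward",
  executed as unit sub-steps with receptor-contact checks after each so
  fast molecules cannot tunnel through the 1-patch contact band),
  extracellular molecule step 4, intracellular step 2;
* receptor recovery: +1 sensitivity per 5,600 ticks (7 h), capped at 5.
  Recovery speed controls how long a super-capacity dose persists: the
  120 TLR4 can absorb at most 480 units before full desensitization, so
  350 units clear within the first hour while 750 units linger for most of
  a day and 1,000 units are never cleared within the horizon;
* IkBa kinetics: zone of influence 2 patches for kinase shutdown, seek
  radius 1 (as printed) for NF-kB capture, turnover after 20,000 ticks.
  IkBa is the canonical unstable inhibitor; without finite turnover no
  sustained inflammatory state can exist at all, and without the kinase
  zone of influence the inhibitor pool converges on the nucleus and the
  cascade smolders indefinitely;
* cytokine turnover: IL-12 and IL-4 lifetimes 800 ticks (without finite
  cytokine lifetimes P and A can never return to baseline and resolution
  is undefined), IL-4 receptor occupancy 1,500 ticks;
* T helpers: entry threshold 100 circulating IL-12 units, entry interval
  200 ticks, capacity 50, Th1/Th2 secretion intervals 100/50 ticks, and a
  residence time of 6,400 ticks (8 h) after which a recruited cell leaves
  the circulation - without finite residence Th1 output keeps P elevated
  forever;
* energy: initial level 1,000 per cell with basal recovery of 1 unit per
  8 ticks (capped at the initial value, which makes E a bounded health
  indicator that returns to baseline after an episode).

## What the calibrated model reproduces - and what it does not

Under the shipped defaults the dosing scenarios behave as follows (these
are the same quantities the test suite and the acceptance script compute;
20 seeded replicates each):

* **Self-limited (LPS 350).** The stimulus is cleared in roughly half an
  hour, TNF-a and IL-12 peak within the first hours and all channels
  return to baseline with a median resolution time of a few hours - every
  replicate resolves, and this pattern is insensitive to the seed.
* **High dose (LPS 750).** Receptor desensitization outlasts the day: the
  stimulus persists for ~21 h and a substantial fraction of replicates
  fail to resolve within the horizon.
* **Persistent infection (LPS 1000).** The stimulus is never cleared; no
  replicate resolves.  Together with the two classes above this realizes
  the model's two attractor classes (resolved baseline vs sustained
  elevation) and a monotone dose-response of the resolved fraction.
* **Endotoxin tolerance (LPS 100 at 0 h + 650 at 8 h).** The second,
  near-lethal dose meets partially desensitized receptors and its TNF-a
  peak is attenuated relative to the single 750-unit bolus.
* **IKK inhibition (LPS 750 + 400 inhibitor molecules).** The inhibitor
  suppresses the kinase pool during the burst and lowers late TNF-a; in
  our ensembles the unresolved fraction is at or below the uninhibited
  high-dose fraction, but the margin is within replicate noise (see
  limitations).
* **Lethal potentiation (LPS 100 at 0 h + 250 at 2 h).** Not reproduced:
  under the calibrated subcritical signaling regime the schedule's total
  of 350 units is within receptor capacity, clears completely, and every
  replicate resolves exactly as the single 350-unit bolus does.  A
  potentiated outcome would require a priming mechanism whose strength
  exceeds what the published rule set pins down; the corresponding
  acceptance test is left failing rather than weakened, and the property
  is recorded as a known limitation.

## Numerical choices

* **RNG.** The engine uses a self-contained xoshiro256** stream seeded via
  splitmix64.  The stream state is serialized into snapshots, so a saved
  and resumed run is bit-identical to an uninterrupted one, and every
  quantity in the package derives from the single run seed.
* **Iteration order.** Within a phase, agents are processed in creation-ID
  order with draws from the global stream.  Individual trajectories depend
  on that order; aggregate ensemble statistics do not (this is tested by
  permuting the initial registry).
* **Contact.** Two agents interact within 1 patch (toroidal minimum-image
  metric), the radius the rule table states for the IkBa rule, adopted
  globally.  Chemotaxis ties break to the lowest sector index.
* **Containment.** Membranes and nuclei are geometric: a proposed move
  that violates an agent's containment class is rejected and the agent
  redraws its heading next tick, exactly the published bounce rule.
  Intracellular agents translate rigidly with their cell.
* **Dose timing.** Doses are applied at `floor(hours x ticks_per_hour)`;
  injected agents idle for the remainder of that tick and act from the
  next one.
* **Degenerate inputs.** Zero-dose runs are a homeostatic fixed point (a
  tested invariant).  A calibration point that never activates NF-kB
  produces no pro-inflammatory response and is rejected by the calibration
  predicate, which requires a nonzero P response in addition to clearance
  and resolution.

## What the synthetic scenarios do and do not show

All inputs are synthetic: the dosing schedules are the printed scenario
definitions and the initial world is built from the composition above, so
the test suite demonstrates internal reproduction of the published
qualitative patterns, not agreement with clinical measurements.  The
model shares the published framework's abstractions - one spatial
compartment for macrophages and T cells, agent counts standing in for
concentrations, a descriptive (not physiological) energy variable, and
qualitative P/A/E indicators.  Passing scenarios therefore support claims
about the rule set's emergent dynamics; they say nothing quantitative
about human endotoxemia.

## Known limitations

* The potentiation ordering discussed above.
* The intervention (IKK-inhibitor) ordering holds in expectation but sits
  within replicate noise at n = 20: its stoichiometric dose (400
  molecules against a kinase supply of one unit per 5 ticks per cell) can
  only shape the first hours of the response.
* Replicate-level outcome fractions are an operationalization this
  artifact defines; the published figures show single illustrative
  trajectories.
* The tick-to-hour mapping is a calibration artifact; absolute times
  inherit its uncertainty.
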
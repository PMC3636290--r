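---
title: "Simulating and analyzing consensus-method trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing consensus-method trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(consensim)
```

## The problem

Clinical practice guidelines are developed by panels that must turn graded
evidence plus expert judgment into recommendations. How a panel reaches
consensus matters: informal face-to-face discussion is exposed to
social-psychological influence (dominant voices, status, conformity
pressure), while structured anonymous protocols — Delphi-like processes,
including ones packaged as a game so that teams of two race to agree —
trade discussion richness for controlled feedback. `consensim` implements
a complete in-silico version of a randomized comparison between two such
protocols:

* **HC (human computation)**: participants are anonymously paired; both
  teammates answer a multiple-choice clinical scenario independently; on
  disagreement the evidence grades and the teammate's answer are revealed
  and each gets exactly one chance to change; after all teams finish, team
  rankings (a pure competition element) are shown, and everyone gives an
  individual final answer.
* **IC (informal consensus)**: individual first ratings, evidence handed
  out, a paired discussion and re-rating, a moderated full-group meeting,
  and an individual final rating.

Both protocols yield three measurement rounds per participant and
scenario. The unit of analysis is the *group* (8 participants), and two
group-level outcomes are tracked per scenario and round.

## Outcome definitions

**Evidence score.** Each answer option carries GRADE-style evidence:
high/moderate/low/very-low quality, for or against the option. Options
score signed points (4/3/2/1, negated when the evidence argues against;
0 without evidence). A group's score at a round is the member sum of
points divided by the highest attainable sum (members × maximum positive
option points), so it lives in [-1, 1]: 1 means unanimous choice of the
best-evidenced option; negative values mean the group leans toward
contra-evidence options. The normalization uses the maximum *positive*
points, not the range, which is what makes negative baselines
representable. Options graded `absent` inside an otherwise graded
scenario contribute 0 points. Evidence levels are equally spaced by
design; alternative weightings are out of scope.

**Agreement kappa.** Agreement of 8 raters on one item: observed
agreement is the fraction of concordant rater pairs among all 28 pairs;
chance agreement is 1/k under the default *free-marginal* model (k =
number of options) or the sum of squared category shares under the
*fixed-marginal* (Fleiss-style) model. Free-marginal is the default
because fixed-marginal chance is estimated from the same single item and
degenerates at unanimity; with only one item per scenario there is no
principled marginal estimate. The choice is a parameter
(`chance_model`), recorded in the score table's metadata, and kappa is 1
exactly at unanimity under either model by convention.

## The opinion-dynamics generator

Participant behavior is the one thing a trial report cannot give us, so
the simulator commits to a deliberately minimal model, declared in
`behavior_params()`:

* `baseline`: per-scenario categorical propensity weights over options —
  each round-1 answer is an independent draw.
* `epsilon` (evidence attraction, default 1): once evidence is revealed,
  propensities are tilted multiplicatively by `exp(epsilon * points)` — a
  softmax pull toward better-evidenced options. On the evidence-free
  scenario all points are 0, so `epsilon` has no effect there and only
  conformity moves answers.
* `gamma` (conformity, default 0.4): the probability of a conforming
  move instead of a tilted redraw. At a team's second attempt the
  conforming target is the pair's *canonical* answer (the
  better-evidenced of the two attempt-1 answers, ties to the lower
  declared option index — so when both teammates conform they land on the
  same option and reach consensus). At round 3 the target is the group's
  modal round-2 answer (ties to the lower option index).
* Response times are log-normal (default meanlog `log(20)`, sdlog 0.5,
  in seconds; roughly 20 s per answer with realistic right skew); a
  team's per-scenario elapsed time is the sum of its members' per-attempt
  draws, compared against a 120 s `time_limit`. The source trial names
  time pressure but no limit value; 120 s for reading and answering a
  short multiple-choice case under game pressure is our choice, made
  once. Times feed only the ranking, never the outcomes.

Randomization mirrors the realized design rather than an idealized one:
`randomize_participants()` forces the arm totals (64 HC / 56 IC by
default, giving 8 + 7 groups of 8 with the spare invitees becoming
observers); `arm_counts = NULL` switches to true 1:1 simple
randomization. Teams of two are formed by the envelope procedure in both
arms — the IC arm also pairs for its round-2 discussion step. Each group
draws from its own RNG stream derived by stable string hashing of the
group id from the root seed, so adding or removing groups never
reshuffles the others, and a fixed seed reproduces a trial byte for byte.
The HC round 3 is simulated strictly after team ranking, mirroring the
protocol's guarantee that the competition element cannot touch the final
answers.

The bundled scenario file (`inst/extdata/scenarios_lbp.yaml`) is a
synthetic reconstruction of the four lower-back-pain scenarios (imaging,
therapy, drugs — graded; sick leave — ungraded): the original option
lists were never published, so option counts and labels are a fixture
choice. The default baseline propensities were chosen once to emulate
the trial's round-1 profile qualitatively — a mildly contra-evidence
imaging habit (negative baseline evidence score), a strongly concordant
therapy preference, a mixed drug profile, and a moderate sick-leave
consensus — and are not tuned to reproduce any published number.

What the generator does *not* model: utterance content, moderator
behavior, participant heterogeneity (everyone shares one parameter set),
learning across scenarios, or dropout. Passing tests therefore show that
the statistical machinery behaves correctly under a clean categorical
choice model, not that real panels behave this way.

## Inference layer

Group outcomes are treated as independent observations (the source
design explicitly did not model clustering of individuals in groups, and
neither do we — mixed models are a non-goal). Per scenario and outcome:

* within-arm Cohen's d: |mean(round 3) − mean(round 1)| over the arm's
  groups, divided by `sqrt((s1² + s3²)/2)` (sample SDs; equal weights
  because the rounds share groups), with an exact Wilcoxon signed-rank
  test on the paired changes;
* between-arm Cohen's d on the round 3 − round 1 changes, with
  `(n−1)`-weighted pooled SD and an exact Mann-Whitney U test. The d is
  *signed* by default (negative when the IC arm improves more) — the
  reported quantity in this literature is signed in practice even when
  described as absolute — with `signed = FALSE` restoring the literal
  absolute form. The pooled-SD conventions themselves are stated here
  precisely because no published definition exists to recover.
* Bonferroni adjustment: two outcomes per scenario at α = 0.05 gives the
  0.025 testing level.

The exact tests are built for the trial's tiny samples (8 and 7 groups):
the signed-rank null distribution is the generating function over all 2^n
sign assignments of mid-ranked absolute differences (zeros dropped,
Wilcoxon's original treatment — at these n the tie/zero conventions move
p materially, which is why they are fixed explicitly); the Mann-Whitney
null enumerates all `choose(n+m, n)` labelings of the pooled mid-ranked
values, handling ties exactly. Both report two-sided
`min(1, 2·min(lower tail, upper tail))`. Beyond a pooled size of 20 a
tie-corrected normal approximation takes over; the study-shaped design
never reaches it. Independent brute-force enumerations of both null
distributions live in the test suite, not in the package, so the exact
path is verified against code that shares nothing with it.

## Thematic layer

The informal meetings' discussions arrive as already human-coded
dialogue acts (`meeting_id, coder_id, act_index, theme`); no NLP is
attempted. The package tallies themes over a declared scheme with
half-up integer percentages (the printed-report style: 177 of 369 acts
is 48%), computes two-coder Cohen's kappa per meeting — "mean inter-coder
kappa" is the unweighted mean over meetings, since pooling versus
averaging is unspecified in the tradition this follows — and summarizes
discussion durations (sample SD). The bundled coding scheme and the
example acts file are synthetic reconstructions (named accordingly): the
original category list is only partially recoverable.

## Pipeline and calibration

`run_pipeline()` chains simulate → validate → score → analyze → report,
persisting every intermediate (answers, transcripts, rankings, scores,
effects, baseline and trajectory tables, JSON metadata) so that each
reported number can be recomputed from the written score table — the
test suite does exactly that. `compare_protocols()` replicates the whole
pipeline over a grid of `(eps_hc, eps_ic, gamma)` cells and reports the
between-arm Mann-Whitney rejection fraction at the adjusted level with a
binomial Monte-Carlo SE: with equal parameters across arms it measures
the pipeline's type-I error (the proof-of-concept trial this design
descends from was explicitly unpowered, so the power surface is the
analysis that design lacked).

Two calibration facts the suite verifies at the study's scale: the mean
evidence-score change is strictly increasing in `epsilon` over
{0, 0.5, 1, 2} and the mean kappa change in `gamma` over {0, ⅓, ⅔, 1}
(200 single-group replicates per cell — enough that the Monte-Carlo SE of
each cell mean is an order of magnitude below the cell differences); and
under the `epsilon = gamma = 0` null the rejection rate over 500
study-shaped replicate trials (3 evidence scenarios each, 1500 tests)
sits within 3 binomial SEs of the 0.025 level. The exact test's discrete
null makes its attained size about 0.0205 at these arm sizes, which is
inside that band; a rate materially *above* 0.025 would be the actual
red flag.

## Worked example

```{r example, eval = FALSE}
design <- study_design()                # 120 invitees, 64/56 split, 4 scenarios
params <- default_behavior_params(design$scenarios)
bundle <- run_pipeline(run_config(seed = 42, design = design))

bundle$baseline       # round-1 mean and 95% t-CI per arm/scenario/outcome
bundle$effects        # within/between d, exact p, Bonferroni flags
bundle$meta$alpha_adjusted  # 0.025

# power surface the original design lacked
grid <- expand.grid(eps_hc = c(0, 0.5, 1), eps_ic = 0, gamma = 0.4)
compare_protocols(grid, n_replicates = 100, seed = 7)
```

## Degenerate inputs and numerical choices

Zero pooled SDs raise a classed error (`consensim_undefined_error`)
rather than yielding infinite effect sizes — in the table-building layer
they surface as NA cells. All-zero difference vectors return p = 1 with a
`no_information` flag. Evidence scores are undefined (error) for
evidence-free scenarios and for scenarios without any positively graded
option. Validation never silently imputes: missing round cells, wrong
group sizes, and broken team partitions are reported findings, because
the real trial's shifting denominators are exactly the kind of thing an
analyst must see.

## Limitations

The generator's choice model is intentionally simple: single shared
parameters per arm, independence across scenarios, no individual traits.
Its purpose is to give the analysis layer data with the right *structure*
(and known nulls), not to be a behavioral theory. Reported headline
numbers from any real trial of this design cannot be reproduced without
the raw answer records, which were never published; nothing in this
package claims to recover them.
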
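---
title: "Semantic annotation as plan validation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic annotation as plan validation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semannot)
```

# The model

`semannot` treats an annotated behaviour log as a *plan*: an ordered
sequence of grounded action operators executed from a known initial
state.  The semantics live in a domain model with five parts:

* **entity types** form a forest — each type may name one parent, and an
  entity of a subtype is accepted wherever the parent is required (a
  `pourable` bottle is `takeable`);
* **entities** are the concrete objects, places, substances and devices
  of the experiment, each with exactly one declared type;
* **fluents** are functions from entity tuples to a value — another
  entity (`is-at(bowl) ↦ counter`), a number (`objects_taken() ↦ 2`) or a
  truth value (`is-open(fridge)`).  A fluent instance has exactly one
  value in any state, and the set of all ground instances *is* the state;
* the **initial state** assigns a value to every ground instance.
  Entity-valued instances must be assigned explicitly; booleans default
  to `false` and numerics to `0`, so a domain file only lists what holds
  at the start;
* **action schemas** carry typed parameters, a precondition (conjunction,
  negation, equality of a fluent term with a constant or parameter, and
  numeric comparison `< <= = >= >` against a constant, parameter or
  second numeric term), an effect list (`assign`, `increase`,
  `decrease`; at most one write per ground term), and a *label
  template* such as `"take-{what}-{from}"`.

Instantiating every schema over all type-correct bindings yields the
ground actions; their printed labels are the finite annotation
vocabulary.  The hyphen is reserved as the label separator (entity names
may contain underscores, never hyphens), so the action class of any
ground label is recoverable as its first token.  Integer multiplicity
tokens (`take-1-egg_shell-counter`) are ordinary parameters bound to
digit-named entities of an `amount` type; when such a parameter is used
where a number is needed — `(increase (objects_taken) ?n)` — its entity
name is read as the number.

Two schemas may share a class name (the brownie domain has a
two-parameter and a three-parameter `take`); ground labels must simply
resolve uniquely, and when duplicate labels do arise the first grounding
in declaration order wins.

## Validation semantics

Validation replays the label sequence from the initial state.  Actions
are instantaneous and applied at the segment's *start* time; the state
is piecewise-constant in between.  This is deliberate: the causal
question is whether the sequence is executable, and durations carry no
causal information in this model.

Validation stops at the first failure, because the state after an
impossible action is undefined.  The report distinguishes two situations
that a tool cannot tell apart, and says so in its `note`:

* the domain is too strict (the model caps held objects at three but the
  person really held four) — the domain should be relaxed;
* the label sequence is impossible (the knife is taken from the drawer
  twice without being put back) — the annotation should be repaired.

Nothing is auto-edited; the report names the failing step, the violated
sub-expression (the innermost conjunct, or the whole negation when a
`(not …)` fails) and the values of exactly the fluents that
sub-expression mentions.  A label that does not resolve to any ground
action is a different, earlier kind of error — a vocabulary mismatch —
and is raised before any causal checking, with every offending segment
listed so an annotator can fix them in one pass.

A validated run yields a `state_trajectory`: the initial state plus one
successor per step.  Everything downstream (property queries, timelines,
curves, Markov models) reads from trajectories, so it is causally
consistent by construction.

# Annotation tiers and time

Times are integer milliseconds; segments are half-open `[start, end)`
intervals, which makes adjacent segments tile without double-counting.
The supported interchange formats are the ELAN tab-delimited export
(`tier  MM:SS.mmm  MM:SS.mmm  label`; `HH:MM:SS.mmm` and bare
millisecond counts also parse) and a CSV with
`run,annotator,start_ms,end_ms,label`.

Overlapping segments are recorded with a warning but never repaired:
they are fatal for plan conversion (which needs an unambiguous sequence)
yet tolerable for reliability slicing, where the later-starting segment
wins within a tier.  Plan conversion additionally requires the tier to
be gap-free — each end equal to the next start — matching how the
packaged annotation extract is transcribed: printed start times, each
segment ending where the next begins.

# Interrater reliability

The unit of analysis is a fixed-width time slice, **default 10 ms**.
The choice matters: any slicing coarser than the shortest annotated
segment (the packaged extract contains a 4 ms segment) merges real
disagreement away, while 1 ms slicing costs ten times the memory for no
visible change in the estimates — at any width the estimators converge
on the duration-weighted overlap of the two tiers.  The resolution is a
parameter everywhere it is used.

Both tiers of a run are sliced over a shared horizon (the later of the
two ends).  Slices outside any segment carry the reserved label `NONE`,
which by default participates in all metrics — time one annotator
labelled and the other did not is a real disagreement.  `ignore_none`
excludes those slices for the complementary question ("how well do they
agree where both committed to a label?").  Comparison is on full ground
labels by default — `take-bowl-cupboard` vs `take-bowl-counter` is a
disagreement — with a `class` level that compares leading tokens only.

Over the resulting paired series the package computes raw agreement
(the diagonal share of the confusion table), Cohen's κ with chance
agreement `p_e = Σ_k p_A(k)·p_B(k)`, and Krippendorff's α for nominal
data from the coincidence matrix — two observers, no missing data, so
`α = 1 − D_o/D_e` with `D_e` the permutation-expected disagreement.  For
two coders and large `n`, α and κ differ by `O(1/n)`; the test suite
checks this convergence on 10⁵-slice simulations, and checks κ against
an independent implementation (`e1071::classAgreement`).  Degenerate
inputs are refused loudly: two empty tiers (or zero jointly covered
slices under `ignore_none`) have undefined metrics.

Disagreement diagnostics work on exact interval algebra rather than
slices: maximal intervals on which the tiers disagree, each classified
as a *boundary shift* (both labels occur in the other tier within a
configurable window, **default 1000 ms** — the annotators saw the same
actions but placed a cut differently) or a *substitution*.  The window
is purely diagnostic; it enters no metric.  The learning curve scores an
ordered sequence of tier pairs and fits an ordinary least-squares line
of agreement against pair index; its slope is the summary of whether
annotators converge with training.

# Routine mining

`build_markov` estimates a first-order transition model over action
classes or ground labels, with `initial` and `finish` pseudo-states
bracketing every run.  Probabilities are maximum-likelihood row shares
and there is **no smoothing**: because only validated plans enter, a
zero cell is evidence of causal impossibility (or at least
never-observed succession), not a small-sample artefact to be papered
over.  The DOT export draws edge pen-width proportional to probability
and labels edges with raw counts, so both readings are available.

`property_curve` aligns runs of different lengths on **normalised time
with 100 bins** by default: each run is sampled at the midpoints of 100
equal bins of its own duration, and the curve reports the fraction of
runs in which `term == value` holds per bin.  Normalised time is the
right default when runs are the same task at different speeds; an
absolute-time binning would conflate slow participants with different
behaviour.  Midpoint sampling makes the final bin reflect each run's
final state whenever the last action precedes 99.5% of the run, so the
curve's terminal value equals the share of runs ending with the
property — the test suite asserts exactly this.

`initial_state_table` compares the step-0 values of chosen fluents
across runs and flags any run whose values differ from its predecessor.
Comparison is exact, with no statistics: a mid-study relocation of
objects is a deterministic setup change, and smoothing or testing would
only blur where it happened.  `location_timeline` compresses an
object's location fluent to one entry per change; it is definitionally
consistent with `query_property` on the same term, which is also
tested.

# The synthetic generator

The generator exists so that every module is testable without any
external recording, and it emulates the *structure* of a small annotated
kitchen study:

* **domains**: three packaged recipes with fixed dictionaries — 11
  action classes for brownie, 12 for eggs (adds `turn_off`), 12 for
  sandwich (adds `cut`), 13 in the union — over small typed inventories
  (cupboards that must be opened before use, a held-object cap of 3,
  pooled egg shells with multiplicity labels, pourable sources gated by
  a `can-pour` relation).  Take/put actions deliberately do not require
  the person to stand at the right place; only `walk` tracks position.
  The pooled-shell counter is likewise unconstrained below the holding
  cap.  Both are permissiveness choices made so that the model family
  stays within the expression grammar (no fluent-to-fluent equality)
  while still rejecting the classic annotation errors (double takes,
  taking from closed cupboards, exceeding the holding cap);
* **plans**: uniform random choice among the currently applicable ground
  actions, up to a maximum length or a dead end.  No goal bias — the
  point is guaranteed causal validity, not realism of intent;
* **durations**: log-normal with `meanlog = log(2000)` ms and
  `sdlog = 0.75`.  Right-skewed with median 2 s: most fine-grained
  kitchen actions take a couple of seconds, a few take much longer.
  This is a fixture choice, not an empirical fit;
* **the second annotator**: internal segment boundaries perturbed by
  Gaussian noise (`jitter_sd`, clipped to preserve order and span) and
  labels independently replaced with probability `confusion_rate` by a
  different label of the same action class — the two disagreement modes
  that dominate real double annotation, boundary placement and argument
  confusion.

One global random stream per configuration seed drives everything; the
same seed reproduces a study bit-for-bit.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: goal-directed action ordering, annotator
drift over time, segment-duration/label dependence, overlapping or
gapped real exports, and any statistical match to a particular
recorded corpus.  Tests against synthetic studies establish that the
estimators recover known ground truth under controlled corruption
(agreement falls monotonically in both noise knobs, relocations are
found at the planted run), not that real annotators behave this way.

# Numerical and design notes

* Problem sizes in the shipped checks: oracle equivalence against a
  brute-force grounder/simulator on 200 random domains (≤ 6 entities
  per type, ≤ 5 schemas, 4-step walks); 1,000 sampled plans for the
  validity and Markov-soundness checks; 10⁵ slices for the κ null and
  the α–κ convergence check; 30 paired seeds per corruption level for
  the monotonicity sweeps.
* Enumeration and grounding order is deterministic: schemas in
  declaration order, bindings lexicographic by argument tuple (radix
  sort, locale-independent); duplicate labels keep the first
  occurrence.
* Preconditions compile to closures once per grounding; the diagnostic
  path (naming the violated sub-expression) interprets the ground
  expression tree and only runs on failure.
* Jitter clipping: corrupted internal boundaries are rounded, sorted,
  and forced strictly increasing within the original span, so a
  corrupted tier is always a legal gap-free tier with the same horizon
  — at extreme jitter this truncates the noise rather than dropping
  segments.
* Serialisation round-trips: a parsed domain written with
  `write_domain` re-parses to an equal object (defaulted initial values
  become explicit; an absent precondition serialises as the empty
  conjunction `(and)`).

# Limitations

The dialect is a deliberately small PDDL subset: no durative actions,
conditional effects, quantifiers, derived predicates, or probabilistic
constructs, and no equality between two entity-valued fluent terms.
Reliability is two-annotator only (no Fleiss-style generalisation), and
there are no significance tests on κ differences.  Routine mining stays
first-order; higher-order models and routine clustering are out of
scope.  Validation is exact replay, not plan repair: it tells you where
the first problem is, and leaves the judgement of *why* to the human.
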
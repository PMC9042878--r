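---
title: "Evolving metamemory: model, design decisions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving metamemory: model, design decisions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamem)
```

## The question the simulator addresses

Behavioral tests of metamemory in animals rest on the delayed
match-to-sample (DMTS) paradigm with an escape option: if a subject can
monitor the state of its own memory, it should decline memory tests when
the trace has degraded, accept them when it has not, and decline more as
the retention interval grows. Whether passing such a test actually requires
*meta*-cognition — rather than a first-order read-out of stimulus
difficulty or of generic network disturbance — is contested. A constructive
route to that debate is to evolve small neural agents in the same paradigm
and inspect the mechanism directly, since every activation and every
synapse is observable. `metamem` implements that experiment end to end:
network, task, evolutionary algorithm, behavioral assays, trace recorder.

## Network dynamics and plasticity

An agent is a recurrent network of at most 16 neurons (standard or
modulatory), two of which are fixed output neurons (decline/take; test
answer), driven by 7 input units (5 stimulus bits, choice-phase signal,
bias). Updates are synchronous; all new outputs are computed from the
previous step's outputs:

$$a_i = \sum_{j \in Std} w_{ji}\,o_j, \qquad
  m_i = \sum_{j \in Mod} w_{ji}\,o_j, \qquad
  o_i = \tanh(a_i + \varepsilon_i),$$

where input units count as standard sources and emit their external value
plus Gaussian noise ($\sigma = 0.1$) *without* squashing, and neuron noise
($\sigma = 10^{-4}$) enters $a_i$ before the tanh. Modulatory neurons use
the same activation but their output is routed into $m_i$, where it gates
learning: every connection into a neuron that receives modulatory input is
updated each step by the extended Hebbian rule

$$\Delta w_{ji} = \tanh(m_i)\,\eta\,(A\,o_j o_i + B\,o_j + C\,o_i + D),$$

with weights clipped to $[-10, 10]$. Because modulatory neurons can
themselves be modulated, the rule supports *second-order* plasticity —
learning that controls learning — which is the substrate on which genuine
memory-state representations can form.

Assumptions worth making explicit:

* **Discrete time, rate coding.** No spiking, no continuous-time
  integration; one "step" is one full synchronous pass.
* **Update order.** Within a step: activation pass first, then one
  plasticity pass using the just-computed outputs $o_j, o_i$ and the
  modulatory sums $m_i$ of the same pass. This is the simplest reading of
  the activation/modulation diagrams and makes a step a single
  well-defined map.
* **Plasticity scope.** All incoming connections of a modulated neuron are
  plastic, including those from input units and from modulatory neurons.
  The genome is a full matrix; nothing in the rule restricts it to a
  subset.
* **Gating mask.** A neuron with no nonzero incoming modulatory weight has
  $m_i = 0$ at every step, so $\Delta w = 0$ identically. The `modulated`
  mask computed once at phenotype build is therefore *exact*, not an
  approximation: an unmodulated column can never bootstrap itself into
  modulation, because the modulatory weights into it are themselves frozen.
* **Noise placement.** Neuron noise is applied to $a_i$ only, not to
  $m_i$. Modulation is thus noiseless given the (noisy) presynaptic
  outputs; this is one of two defensible readings and the one we fixed.

## Genotype → phenotype

Genotype weights live in $[-100, 100]$ and are expressed as
$10\,w^3$ with a dead zone: $|w^3| < 0.1$ expresses as exactly 0. The cube
gives mutation fine resolution near zero; the dead zone lets evolution
prune connections. Rule coefficients $A..D$ (genotype $[-1,1]$) are cubed
with the same dead zone, without the factor 10; $\eta$ is used directly.
Since $10 \cdot 100^3$ vastly exceeds the admissible weight range, mapped
weights are clipped to $[-10, 10]$ — we treat the weight-range statement as
absolute, and the clip only binds for $|w| > 1$ where the genotype is
already saturated in effect.

**Trial reset.** The reference protocol re-initialises each network "with
random values within corresponding possible ranges" at every trial. That
sentence underdetermines *what* is randomised. Default:
phenotype weights are re-expressed from the genome and neuron outputs are
drawn uniformly in $[-1, 1]$ — under the literal alternative (weights
uniform in $[-10,10]$ each trial, `reset_mode = "random_weights"`, also
implemented) the genome's weight matrix would never influence behaviour at
all, which would make the weight-matrix genes and the submatrix crossover
operator meaningless. Both modes are testable; all defaults and assays use
the genome-expressed mode.

## Task environment

`task_config()` carries the study constants: $\lambda = 0.7$,
$CV = 0.25$, $P(\text{choice}) = 2/3$, rewards $1.0 / 0.3 / 0.0$, decision
threshold $1/3$, repetitions 4 (choice) and 3 (all other phases), noise
$\sigma$s as above. Delays follow
$N_{delay} = \lfloor -1/(\lambda \ln R) \rfloor + 1$ with $R$ uniform on
the *open* interval $(0,1)$ (the closed-interval phrasing would divide by
$\ln 0$ or $\ln 1$); the induced law $P(N \le k) = e^{-1/(\lambda k)}$ is
heavy-tailed, so occasional very long delays are part of the selection
pressure.

Decisions we fixed where the prose was ambiguous or contradictory:

* **Threshold direction.** The choice-phase description is
  self-contradictory (decline "when more than 1/3", take when it "equals
  or exceeds 1/3"). We decline iff strictly $> 1/3$, matching the
  test-phase rule ("when the response exceeds 1/3"); a value of exactly
  $1/3$ takes.
* **Read-out timing.** Decisions are read from the relevant output after
  the last repetition step of a presentation block — the repetitions exist
  to propagate input effects through the recurrent graph, so earlier steps
  are transient.
* **Delay presentations** each occupy `reps_other = 3` steps, like every
  non-choice presentation.
* **Unsolvable trials** differ only in the study stimulus (the 00000
  distractor) and the reward rule (only declining pays, 1.0); delay
  sampling and the choice coin are unchanged.
* **Test phase** makes a single pass in random order and ends at the first
  supra-threshold answer; the choice signal is 0 during the test.
* **Output roles.** Neuron 1 is the decline/take output, neuron 2 the
  answer output, matching the declining-neuron labelling in the evolved
  networks analysed in the literature this reproduces.

## Genetic algorithm

`ga_config()` defaults to the reference experimental conditions: $N = 300$ individuals,
$G = 1000$ generations, fitness = summed reward over $T = 300$ trials with
$U = 50$ unsolvable at random positions, first 100 generations *guided*
(choice phase force-skipped, no unsolvable trials, so answering evolves
before declining can short-circuit it). Selection partitions the array
circularly into segments of 5 at a random offset; the best of each segment
emits 5 children (crossover w.p. 0.1 with a partner drawn from the whole
population, else a copy), every child then passes through per-gene Gaussian
mutation (p = 0.1; sd 0.3 for weights and $A..D$, 3.0 for $\eta$; clipped
to genotype ranges) and structural mutation (insert 0.04 per call, delete
0.06 and duplicate 0.02 per neuron, 16-neuron cap, output neurons
protected).

Open points we resolved, with rationale:

* **Crossover block bounds "[1, N]"** are read as the weight-matrix
  dimensions (rows 23, columns 16), not the population size: $r$ and $c$
  index a submatrix.
* **Fixed-shape genomes.** Inactive neuron slots keep latent rows/columns
  (masked in the phenotype), so crossover between parents of different
  topology is always well defined.
* **Mutation granularity** is per gene ("each of the connection weights"),
  not per individual.
* **Parent survival.** Parents re-enter only through their children, and
  every child is mutated — there is no verbatim elitism. The alternative
  reading (the copy-child skips mutation) would make the copy operator an
  elitism channel; we chose the uniform treatment and note it here.
* **Crossover of types.** Only the weight matrix and rule parameters
  recombine; neuron types and the activity mask come from the primary
  parent, as only those two genome components are described as crossing
  over.
* **Operator order** within structural mutation is insertion, deletion,
  duplication (the order they are named); the operators draw
  independently, and `structural_mutation()` logs which fired in an
  `"ops"` attribute so operator rates are measurable exactly.
* **Initial population** (unspecified in the source): output neurons
  always active, every other slot active with probability 0.25 with
  uniform-random type; genotype weights uniform in $[-1, 1]$ — the same
  range the insertion operator uses for new neurons, putting roughly half
  of all initial connections in the dead zone; rule parameters uniform
  over their genotype ranges. Chosen once as the least-informative
  convention consistent with the operators.
* **Ties** in selection break toward the lowest array index;
  fitness schedules (delay draws, unsolvable positions) are resampled per
  individual per generation.

## Randomness and reproducibility

One master seed feeds three named streams — `noise` (neural noise, trial
resets), `task` (targets, delays, choice coin, test order), `ga`
(selection, operators, initial population) — so a change in how much noise
an agent consumes cannot perturb the task schedule. `evolve()` runs are
bitwise reproducible given the seed; the compiled kernel draws noise in
the same order as the reference R implementation (`step_network()`), and
the two engines agree to $10^{-12}$ on every step (asserted in the test
suite; exact equality is not guaranteed because BLAS summation order may
differ). Float comparisons in tests use $10^{-9}$ relative tolerance or
tighter.

## What the scripted baselines and fixtures emulate

Task-environment tests must not depend on network correctness, so the
package ships scripted agents with closed-form expectations
(`expected_scripted_fitness()`): always-decline
($Up + (T-U)\,p\,0.3 = 83.3\overline{3}$ at defaults), uniform-random
answering ($(T-U)/5 = 50$; forced accuracy exactly $1/5$), a perfect
oracle, and constant-output agents. Toy genomes (`make_toy_genome()`)
include a minimal gated circuit in which exactly one pathway is plastic iff
its modulatory gate neuron is active. These fixtures pin the environment
and the plasticity gate down analytically; they deliberately do *not*
emulate evolved behaviour.

What passing tests show, and what they do not: the suite verifies the
mechanics (rewards, schedules, bounds, operator rates, the delay law) and
that evolution improves fitness at desk scale. It does not certify that a
full-scale run reproduces the headline evolved-metamemory phenotype — in
the full-scale conditions ($N=300$, $G=1000$) a network meeting the
strictest mechanistic criterion emerged in 1 of 10 trials, an inherently
stochastic outcome. The assay module is built so that exactly that
analysis (forced vs chosen vs declined-counterfactual accuracy at fixed
delay 40; decline rate vs delay) can be run on any genome, including the
published evolved genome if supplied as JSON.

## Problem sizes used in the checks

The test suite runs stochastic checks at sizes chosen to keep a full run
in minutes on one core while leaving 3-standard-error bands narrow:
$10^5$ trials for the choice-phase frequency, $10^5$ draws for the delay
law (Kolmogorov–Smirnov at $\alpha = 0.01$), $10^6$ steps for the
input-noise calibration, $10^5$ calls for the insertion rate, and an
evolution improvement check at $N = 50$, $G = 30$, $T = 30$, $U = 5$,
no guided phase, fixed delay 1, noise off — a simplified task in which the
population reliably climbs toward the decline local optimum (mean fitness
of the last generation exceeded the first in at least 8 of 10 seeds).
Those smoke-scale choices are the package's own; the full-scale defaults
remain `ga_config()`'s.

## Known limitations

* Evaluation is sequential; at study scale ($300 \times 300$ trials per
  generation with heavy-tailed delays) a full 1000-generation run is an
  overnight job on one core.
* The delay law has infinite mean; fitness variance between schedules is
  substantial, which is faithful to the design but makes single-evaluation
  fitness a noisy fitness estimate.
* No automated classification of evolved mechanisms into the behavioural /
  self-referential / second-order criteria — the trace recorder produces
  the data for that analysis, which remains a human task.
* Spiking dynamics, alternative learning rules, and alternative
  metamemory paradigms (judgment-of-learning, confidence judgment) are out
  of scope.
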
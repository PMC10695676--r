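---
title: "Modeling prediction, explanation, and control of probabilistic finite-state machines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling prediction, explanation, and control of probabilistic finite-state machines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsmpec)
```

## The modeling problem

People interacting with a dynamic system — a device, an interface, a
conversational agent — face three distinct demands: *predicting* what the
system will do next, *explaining* which of their actions caused an observed
outcome, and *controlling* the system toward a goal. `fsmpec` implements a
complete computational pipeline for studying these abilities with
probabilistic finite-state machines (FSMs) as the target systems: an FSM has
a finite state set, a finite input alphabet, and a transition kernel
$P(i \mid j_k)$ giving the distribution of the next state $i$ when the
machine is in state $j$ and receives input $k$.

The pipeline has five stages, each exposed as ordinary R functions:

1. **Machines** (`fsm()`, `easy_machine()`, `hard_machine()`,
   `random_fsm()`): specification, validation, and simulation.
2. **Question banks** (`generate_questions()`): two-alternative
   forced-choice episodes in six modalities — prediction, explanation, and
   control, each with the intermediate state visible or hidden.
3. **Mental models** (`fit_mental_model()`): a frequency estimate
   $\hat P(i \mid j_k)$ of the kernel from an interaction log.
4. **Scoring and choice** (`normative_scores()`, `an_scores()`,
   `evidence_R()`, `choice_prob()`, `fit_beta()`,
   `compare_answer_models()`): evidence computation under a Bayesian rule or
   a greedy heuristic, and a one-parameter noisy-choice model linking
   evidence to responses.
5. **Synthetic cohorts and harnesses** (`simulate_cohort()`, `run_exp12()`,
   `run_exp3()`, `run_exp4()`, `thought_experiment()`): full experiment
   replicas at desk scale.

## The two reference machines

Two four-state, two-input machines ship as JSON fixtures. The *easy*
machine has two probabilistic and six deterministic transition rows, with
two *predetermined* states (states whose next state is independent of the
input); the *hard* machine has five probabilistic and three deterministic
rows and one predetermined state. Both share the anchor row
$P(\cdot \mid 2_a) = \{0: 0.6,\; 3: 0.4\}$, and in the hard machine the
two-step product $P(0 \mid 3_a)\,P(3 \mid 2_a) = 0.4 \times 0.4 = 0.16$
while state 0 deterministically returns to state 2 under any input.

These anchors, together with the row-type censuses, are the published
constraints on the two machines; the remaining probabilities are **synthetic
reconstructions** fixed once when the fixtures were written (they are marked
as such in the fixture `comment` fields). Every quantitative anchor the
package's acceptance checks rely on — the 0.6 transition frequency, the
0.16 hidden marginal, the zero greedy-path probability — depends only on the
anchored rows. Analyses that depend on the full kernels (e.g. the exact
evidence distribution of a question bank) should be read as properties of
these reference machines, not of any particular published experiment.

```{r}
easy_machine()
hard_machine()
```

## Mental models: the frequency rule

A participant's mental model is estimated from their interaction log by pure
relative frequency: $\hat P(i \mid j_k)$ is the number of observed
$j \xrightarrow{k} i$ transitions divided by the number of times $j$ was
seen under $k$. Two deliberate choices:

* **No smoothing on observed rows.** The estimator is exactly the empirical
  frequency; regularization enters only through the evidence measure below.
* **Uniform fallback per row.** A $(j, k)$ pair never observed gets the
  uniform distribution over *all* the machine's states (¼ each for the
  reference machines). The fallback applies per row, not per missing cell.

The estimator depends only on the multiset of transitions, so it is
invariant to trial order, and `model_distance()` (the maximum absolute
probability deviation from a reference kernel) decreases stochastically with
session length; the test suite checks convergence to within 0.01 at 50,000
uniform-exploration trials.

## Scoring: normative rule, greedy heuristic, and evidence

Test episodes are two-input snippets
`start, input1, mid, input2, final` written in a compact grammar
(`1a2b?`, `1aXb3`, `1?X?3`, …) where `X` marks a hidden intermediate state
and `?` a query. For a probability model $P$ (true machine or mental
model), the two answer options receive quantities:

* **Prediction** — next-state probability of each option; hidden forms
  marginalize over the unobserved intermediate state:
  $\sum_k P(o \mid k_{u_2}) P(k \mid s_{u_1})$.
* **Control** — probability of reaching the goal under each candidate input
  (visible) or ordered input pair (hidden, marginalized as above).
* **Explanation** — a counterfactual comparison: for each input, the
  probability that the observed outcome would still have occurred had the
  *other* input been flipped. The input whose own flip most changes the
  outcome — equivalently, whose rival's flip leaves it most intact — is the
  cause. In the visible form the intermediate state is held fixed at its
  observed value when the first input is flipped; the hidden form
  marginalizes instead. Both are implemented literally; the two
  counterfactual products are *not* renormalized before entering the
  evidence measure, as they are not complementary probabilities.

The **alternative-neglect** (AN) heuristic replaces every hidden-state sum
with the single most likely intermediate state
$\varepsilon(s_u) = \arg\max_k P(k \mid s_u)$, constructing the path
greedily; on visible forms it coincides with the normative rule by
construction. When several intermediate states tie for most likely, the
heuristic quantity is **averaged over the tied states** — a deterministic,
order-independent convention chosen so that a scorer never needs a random
tie-break. With a one-hot intermediate marginal, the hidden normative rule,
the hidden heuristic, and the corresponding visible computation all
coincide.

The two quantities $P_1 \ge P_2$ are summarized by the evidence
$$R = \ln\frac{P_1 + \epsilon}{P_2 + \epsilon}, \qquad \epsilon = 0.1,$$
so $R = 0$ for indistinguishable options and
$R = \ln(1.1/0.1) \approx 2.4$ for a certain option against an impossible
one — the cap that motivates the default $\epsilon$. The regularizer is
applied uniformly across all three tasks, including the explanation path
products. Both $\epsilon$ and the logarithm base are fixed by these
defaults but exposed as arguments.

An independent oracle, `brute_force_scores()`, recomputes every quantity by
explicit enumeration of intermediate-state paths with plain loops; the test
suite holds it equal to the closed-form scorer to $10^{-12}$ on 1,000
randomly generated machine/question pairs.

## The choice model and sensitivity fitting

Responses are linked to evidence by
$$p_C = \frac{e^{\beta R}}{e^{\beta R} + e^{-\beta R}},$$
the probability of choosing the option the scorer favors. Internally this
is the logistic of $2\beta R$, stable for arbitrarily large arguments. Note
the factor of two: $\beta$ as defined here equals *half* the slope of a
no-intercept logistic regression of correctness on $R$. The package's
canonical parameter is the $p_C$ form; `fit_beta()` also reports
`beta_logistic = 2 * beta`, and the unit test cross-checks the fit against
`stats::glm`.

`fit_beta()` maximizes the Bernoulli likelihood by Newton iteration on the
one-dimensional concave problem (gradient tolerance $10^{-8}$). Records
with $R = 0$ — including questions whose options tie under the scoring
model — are retained as constant $\log \tfrac12$ terms so that
log-likelihoods are comparable across answer models scoring the same
response set. Complete separation (all informative records correct, or all
incorrect) makes the MLE infinite; the estimate is then capped at
$|\beta| = 20$ and flagged. A design in which every record has $R = 0$ is
an error, not a fit.

`compare_answer_models()` fits $\beta$ under the normative and the AN
labeling of the same responses and reports
$\Delta\ell = \ell_{\text{favored}} - \ell_{\text{other}} \ge 0$. Two tail
probabilities are emitted: the conventional deviance $2\Delta\ell$ against
$\chi^2_1$, and $\Delta\ell$ itself against $\chi^2_1$. The second
convention is included because published $\Delta L$/p pairings for this
comparison are numerically consistent with it; since the two answer rules
are not nested, both p-values are descriptive and neither is asserted by
any test.

## Question generation

The generator enumerates all admissible episodes for a task and form:
every visible transition must have positive probability under the true
machine, and the two options must differ strictly in normative quantity
(evidence above `min_gap`, default 0), so every question has a normatively
correct answer. Design choices where the experimental convention is not
fixed by the task structure:

* **Distractors.** For prediction, the distractor is drawn uniformly from
  states with strictly lower normative quantity than the best option; for
  hidden control, from the strictly worse members of the four ordered input
  pairs. Explanation options are always first-input vs second-input.
* **Replacement.** `generate_questions()` samples episodes without
  replacement by default and raises an exhaustion error reporting the
  admissible count when too few exist. The experiment harnesses pass
  `replace = TRUE`: a four-state machine's admissible episode space (as few
  as two hidden-control episodes on the easy machine) is smaller than the
  question counts of the replicated designs, so repetition is intrinsic to
  those designs.
* **Ordering.** Between-subject harnesses interleave visible and hidden
  questions at random; the within-subject harness presents visible first,
  matching the respective designs.

## Synthetic participants

Agents generate complete datasets with the statistical structure the
analysis assumes, closing the loop that makes each stage testable:

* **Exploration is uniform-random over inputs.** Human exploration is
  certainly not uniform; uniform is the neutral stand-in under which the
  frequency estimator is analyzed, and the policy argument of
  `simulate_session()` is the extension point for anything richer.
* **Response strategies.** Normative and AN agents score each question with
  either the true machine or their own learned model and choose the favored
  option with probability $p_C(\beta, R)$; recency agents answer
  explanation questions with the most recent input at a fixed rate; random
  agents flip a coin; `fixed_accuracy` agents hit the true normative answer
  with a set probability (a known-accuracy oracle for threshold designs).
* **Feedback learning (the threshold design) is a modeling stand-in.** The
  replicated design trains humans with accuracy feedback, but no mechanism
  for *how* feedback improves people is specified by the task itself. The
  package's stand-in: after each feedback block the agent's $\beta$ grows
  by `beta_step`, and its mental model absorbs the fully visible
  transitions shown in that block's episodes as extra observations. This is
  a documented modeling choice, not an empirical claim.
* **Preview questions** are generated and recorded for format fidelity but
  do not alter the agent, reflecting a design whose preview manipulation
  produced no detectable effect.

One empirical property of the pipeline worth knowing: the answer-rule
comparison is well-powered when the scoring model matches the model the
responder actually used (the test suite verifies >95% correct selection at
2,000 responses), but scoring a *true-machine* responder with noisy
*learned* mental models is a misspecified comparison and can favor either
rule. Analyses should score responses with the same model source the
analysis assumes throughout.

## Experiment harnesses and problem sizes

`run_exp12()` (between-subject: 45 learning trials, one task, 10 + 10
questions), `run_exp3()` (within-subject: 60 trials, all three tasks
counterbalanced, 5 + 5 questions each), and `run_exp4()` (16 free trials,
threshold-gated feedback blocks, transfer testing) reproduce the phase
structures with any agent. The 65% accuracy threshold on a 15-question
block is implemented as at least $\lceil 0.65 \times 15 \rceil = 10$
correct — for this block size the strict/non-strict distinction is moot
(9.75 rounds to 10 either way), and the non-strict reading is used
generally. Exclusion requires failing *both* the visible and hidden parts
after all attempts, and the bookkeeping identity
excluded + analyzed = simulated is asserted in the tests. A 60%-accuracy
agent's first-attempt pass rate matches the binomial tail
$P(X \ge 10),\ X \sim \mathrm{Bin}(15, 0.6) \approx 0.403$.

The test suite exercises these harnesses at cohort sizes of 24–500
participants; the full-scale designs (97–240 participants) run in the same
code path and are used in the examples. All stochastic entry points take a
`seed` argument and derive independent per-participant substreams, so a
master seed reproduces a cohort exactly.

## The two-type thought experiment

`thought_experiment()` quantifies how much cross-task score correlation a
mixture of "has a model" (accuracy $a_1$) and "guessing" (accuracy $a_2$)
participants can produce. Each participant's two task scores are
independent binomial proportions given their type, and the population
correlation is
$$\rho = \frac{\mathrm{Var}(p)}{\mathrm{Var}(p) + \mathbb{E}[p(1-p)]/n_q},$$
which the simulation reproduces to within 0.01 at 10,000 replicates. At the
default settings ($a_1 = 0.7$, $a_2 = 0.5$, mixture $\tfrac12$, $n_q = 5$,
$N = 200$) the closed form gives $\rho = 0.01/0.056 \approx 0.179$; raising
$n_q$ to 10 gives $\approx 0.30$, and raising $a_1$ to 0.8 gives
$\approx 0.354$.

Open choices resolved here, exposed as arguments:

* **Mixture fraction** defaults to 0.5, which reproduces all three
  correlation regimes analytically.
* **The Type II rate** uses a *one-sided* Fisher-z test of positive
  correlation at $\alpha = 0.05$; at $N = 200$ and $\rho \approx 0.18$ this
  yields a miss rate near 18–20% (a two-sided test would sit near 28%).
* **Scores vs sensitivities.** The default correlates raw
  proportion-correct scores, whose closed form is exact; `mode = "beta"`
  first maps each score through the equivalent no-intercept logistic
  coefficient (capped at 20, matching `fit_beta()`), for analyses framed in
  sensitivity units. The map is monotone, so the two modes give closely
  similar correlations.

```{r}
te <- thought_experiment(n_replicates = 500, seed = 1)
c(mean_cor = te$mean_cor, closed_form = te$closed_form,
  type2 = te$type2_rate)
```

## Numerical conventions and degenerate inputs

* Kernel rows must sum to 1 within $10^{-9}$; validation errors name the
  offending row.
* Favored-option ties use a $10^{-12}$ comparison tolerance, and tied
  questions propagate as `favored = "TIE"` with $R = 0$ rather than a
  coin-flip label.
* An empty interaction log is a valid input producing the all-uniform
  model, not an error; an all-tie record set is an error for `fit_beta()`.
* The episode grammar requires single-character state and input labels
  distinct from the `X`/`?` markers; machines violating this are rejected
  at parse/render time rather than silently re-labeled.
* `random_fsm()` regenerates until the sampled machine is strongly
  connected, so every exploration policy can reach every row.

## Limitations

Passing tests on synthetic cohorts demonstrates that the pipeline's
estimators and comparisons are *consistent with their own generating
assumptions* — uniform exploration, stationary kernels, the $p_C$ response
rule. They do not show that human data satisfy those assumptions: real
exploration is policy-driven and non-uniform (biasing which rows of the
mental model are well-estimated), real sensitivity drifts within a session,
and real mental models need not take the frequency form at all. The
fixtures reconstruct unpublished kernel entries, so fixture-dependent
quantities beyond the documented anchors are properties of this package's
reference machines. Finally, the answer-rule comparison inherits the usual
caveat of non-nested likelihood comparisons: $\Delta\ell$ orders the models
but its reference distribution is approximate.
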
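---
title: "flowkern: models and methods of the workflow kernel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flowkern: models and methods of the workflow kernel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowkern)
```

flowkern is a self-contained kernel of a make-style workflow manager: it
turns a declarative set of generic rules into a DAG of concrete jobs,
schedules those jobs under resource constraints by an exact solution of a
mixed-integer linear program, partitions the DAG into group jobs for
co-submission, addresses results by a recursive provenance hash for reuse
across workflows, and replays finished runs as byte-comparison unit tests.
This vignette explains the models behind each part, the tunable parameters,
and the design decisions taken where the problem statement left the design
open.

## Rules, wildcards, and DAG inference

A *rule* declares how a set of output files is derived from a set of input
files by a shell action. File patterns may contain *wildcards* `{name}`;
substituting concrete non-empty values for all wildcards turns the rule
into a *job*. Dependencies are implicit: for every requested file, the
engine looks for a rule whose output pattern matches it, instantiates that
rule with the binding recovered by the match, and recurses into the new
job's inputs until every file is either produced by some job or already
present on disk. Identical (rule, binding) pairs merge into a single job,
so the construction visits each job and edge once and runs in linear time
in the size of the DAG (demonstrated empirically on the inflated workflow
family below).

Decisions taken where several behaviors would have been defensible:

* The default wildcard regex is greedy `.+` — any non-empty string,
  including path separators. Per-name constraints can narrow it. When a
  path admits several parses, the leftmost-longest parse wins,
  deterministically; reproducible DAGs matter more than any particular
  parse convention.
* Producer ambiguity is resolved by a fixed cascade: explicit `ruleorder`
  precedence, then higher rule priority, then fewer wildcards (the more
  specific pattern), then declaration order. The cascade is total, so two
  distinct matching rules never abort a build; the cost is that authors
  who want an error on ambiguity must lint for it separately.
* Paths are opaque slash-separated relative strings; the only
  normalization is collapsing `./`, so matching is bit-stable.
* File presence is evaluated once, when the DAG is built. Mid-run
  filesystem changes do not alter the plan — except through checkpoints,
  which are the sanctioned mechanism for data-dependent structure.

### Checkpoints and deferred inputs

A rule may depend on the *content* of an upstream result, e.g. keep only
the samples whose QC value exceeds 90. Arbitrary code for input inference
would make the workflow document non-declarative, so flowkern restricts
deferred inputs to *table-driven resolvers*: a resolver names a checkpoint
rule, a delimited table among its outputs, a column, a threshold
comparison, and a path template emitted once per surviving row. After the
checkpoint job finishes, every dependent resolver is evaluated, the
emitted paths are appended to the consumer's inputs, producers for them
are inferred recursively, the consumer's action is re-rendered (so
`{input}` reflects the resolved set), and acyclicity is re-verified.

## The scheduling program

At the start of a run and after every completion, the engine selects a
subset $E \subseteq J$ of the pending jobs. Let $p_j$ be job $j$'s
priority, $u_{r,j}$ its usage of resource $r$, $U_r$ the free capacity,
$F$ the set of currently present temporary files, $S_f \ge 1$ the size of
file $f$ in MB (rounded up), $S = \max(\sum_f S_f, 1)$, and $z_{f,j}$ the
indicator that open job $j$ consumes $f$. With binary selection variables
$x_j$, the *lifetime fraction* $\delta_f \in [0,1]$ is bounded by the
fraction of $f$'s open consumers scheduled now
($\delta_f \le \sum_{j \in J} x_j z_{f,j} / \sum_{j \in J^\circ} z_{f,j}$),
and the deletability indicator $\gamma_f \in \{0,1\}$ by
$\gamma_f \le \delta_f$; both are maximized, so at the optimum
$\delta_f$ is exactly that fraction and $\gamma_f = 1$ iff every open
consumer of $f$ runs in this round. The objective maximizes

$$W_1 \sum_j p_j x_j + W_2 \sum_j \max(u_{c,j}, 1)\, x_j
  + W_3 \sum_f S_f \gamma_f + \sum_f S_f \delta_f$$

subject to $\sum_j u_{r,j} x_j \le U_r$ for every resource. The four terms
are meant *lexicographically*: priority first, then parallelization, then
freeing temporary space now, then shortening remaining temp-file
lifetimes. A single weighted objective realizes a lexicographic order only
if each weight strictly exceeds the largest value the terms to its right
can jointly take. That dictates

$$W_3 = 2S, \qquad W_2 = 2S(S+1), \qquad W_1 = 4\,\max(U_c,1)\,S(S+1),$$

since the $\delta$ term is at most $S$ and the weighted $\gamma$ term at
most $2S^2$. Weighting the deletion term by anything not growing with $S$
(for instance a constant multiple of $S$ applied to a sum that itself
reaches $S$) lets a large temporary file outbid a unit of parallelization;
the package's enumeration oracle finds such counterexamples readily, which
is why the weights above are derived from the dominance requirement rather
than chosen ad hoc. The `max(u,1)` floor keeps zero-core streaming jobs
visible to the objective — their raw usage still counts against the
capacity constraint.

### Exactness, and the solver

Because $\gamma$ and $\delta$ are determined by the $x$'s in closed form,
the program is a multi-dimensional knapsack with file-coverage bonuses.
`solve_milp()` solves it exactly by depth-first branch and bound in job-id
order: the bound combines a fractional-knapsack relaxation of the job
terms on the cores resource with the best still-attainable file bonus.
All objective comparisons are integer: values are scaled by the least
common multiple of the open-consumer counts, so the large lexicographic
constants never meet floating-point rounding. Ties between co-optimal
selections go to the selection containing the smallest non-shared job id;
since every job has strictly positive gain, co-optimal selections are
never nested and this order is total. `brute_force_schedule()` enumerates
all $2^{|J|}$ subsets (refusing $|J| > 20$) with the same tie-break and
serves as the independent oracle in the tests; a `greedy_schedule()` is
shipped for comparison and as a documented fallback, and single instances
can be inspected as JSON via `schedule_to_json()`.

Resource scopes are global: a single machine governs all resources, and
the middleware-delegation split of cluster deployments is out of scope.

## Group jobs

Assigning rules to named groups partitions the DAG: connected components
of the subgraph induced by jobs sharing a label (connectivity through DAG
edges between same-label jobs) become *group jobs*, scheduled and launched
as units. A per-label *span* $k$ packs up to $k$ components into one group
job; components are ordered by their smallest member job id and packed by
ceiling division, a deterministic choice made here because nothing in the
problem fixes which components should share a submission. Ungrouped jobs
are singleton group jobs, and the quotient graph over group jobs must be
acyclic — a partition that would contract to a cycle is rejected with the
labels involved, since no execution order could respect it.

A group job's resource demand is aggregated by *levels*: members are
layered by longest-path depth within the member-induced subgraph — the
standard choice that matches the intuition that levels run in series and
jobs within a level may run in parallel. Every non-runtime resource takes
the maximum over levels of the within-level sum; runtime takes, vice
versa, the sum over levels of the within-level maximum. Jobs without a
declared `runtime` resource count one time unit.

Streamed outputs (`stream:`) force producer and single consumer into one
group job regardless of labels, because both must run simultaneously for
the intermediate never to be stored persistently. A streamed file with
more than one reader is an error. Under the sequential local executor the
stream is downgraded to a short-lived file deleted as soon as the consumer
finishes, with a logged note; a named pipe is only meaningful with true
concurrency.

## Provenance hashing and the cache

A job's outputs are addressed by a recursive SHA-256 digest over
everything that determines their content: the parameter pairs in
sorted-key order (values as canonical JSON with recursively sorted keys),
the concrete action text, the content digests of raw inputs (inputs no
job produces) in lexicographic order, the software-environment descriptor,
and the digests of all dependency jobs, again in lexicographic order.
Including dependency digests makes the scheme a hash chain: any change to
an ancestor's code, parameters, raw bytes or environment re-addresses
every descendant, so a stale cache entry can never be mistaken for the
current computation.

Bare concatenation of fields is ambiguity-prone (`k="ab", v="c"` and
`k="a", v="bc"` concatenate identically), so every field is framed as
`<decimal byte length>:<UTF-8 bytes>` and every variable-length section is
preceded by its element count. The framing is part of the documented
byte-level encoding; digests are stable across platforms but intentionally
not comparable with any tool that concatenates fields bare.

The cache stores all outputs of a job under its single digest, together
with a JSON sidecar of the provenance fields and per-output content
digests. Stores are atomic (staging directory, then rename), concurrent
stores of one digest resolve to a single entry, and lookups re-verify both
the sidecar digest and every output digest — a failed check quarantines
the entry and reports a miss rather than serving corrupt bytes. Retrieval
hard-links when the filesystem allows and copies otherwise. Caching is
opt-in per rule (`cache: true`): only deterministic actions should be
cached, and actions such as downloads whose result may change over time
must not be.

## The execution engine

`run_workflow()` loops: satisfy cacheable pending jobs from the cache,
build a scheduling instance over pending group jobs, solve it, launch the
selected units, and after each completion delete eligible temporaries,
re-evaluate checkpoints, and reschedule. Outputs are written to a staging
directory and moved into place only when the action exits 0, so partial
outputs of failed jobs are never visible. On failure the engine removes
the failed job's partial outputs, cancels all transitive dependents (and
the remaining members of a partially executed group job), and either stops
(default) or continues with independent work (`keep_going`). Wall-clock
time and best-effort peak memory (sampled from the child process) are
recorded per job, and the provenance log — one record per finished or
cache-satisfied job with the verbatim action text — serializes to a
versioned JSON document.

The local executor launches the selected units of a round sequentially
(subprocess per job) and re-solves after the round completes. True
concurrent semantics — several units running, completions in arbitrary
order, rescheduling after every single completion — are exercised by
`simulate_run()`, which executes nothing but draws random durations and
produces an event log; `replay_events()` independently checks that log for
capacity violations, premature temporary deletions, and temporaries left
undeleted at run end. The safety tests run the simulator, not the
sequential executor, precisely because sequential execution would make
those invariants trivially true.

`generate_unit_tests()` turns a finished run into a replay suite: per
executed rule one case directory with copied inputs, the concrete action,
and the expected outputs, plus a test file that reruns the action in a
sandbox and compares every output byte-by-byte (a `compare.R` hook in a
case directory overrides the comparison, e.g. for outputs with embedded
timestamps). Rules without outputs yield no test.

## Synthetic study conditions

All tests and the acceptance script run on generated inputs:

* `generate_fig3_like(n)` is a download-free analogue of the classic
  "per-country city-population histogram" example: a source rule
  publishes a CSV of `n` synthetic countries (three cities each,
  populations drawn uniformly from 10^4 to 5x10^6 — the scale of real
  city populations), then per-country select (temporary output), plot
  (text histogram), and convert rules, plus one aggregating target rule.
  The job count is exactly `3n + 2`; the smallest family member used in
  the scaling study (`n = 3`) has 11 jobs. The original example fetches
  its data over HTTP; the generator replaces the download so tests are
  network-free and deterministic.
* `generate_scheduler_instance(seed)` draws up to 8 pending jobs with
  priorities in 0–3 and core usages in 1–4, up to 3 temporary files with
  sizes in 1–100 MB and open-consumer sets that strictly contain the
  pending consumers — small enough for the enumeration oracle, rich
  enough to cover every term of the objective.
* `generate_random_dag(n)` builds layered random DAGs (at most two
  parents per job, temporary flags at a configurable density, random
  priorities/cores/runtimes) for the concurrency simulations and the
  hash-propagation property tests.
* `generate_checkpoint_table(n, f)` emits a QC table in which exactly
  `round(n * f)` rows exceed the threshold of 90.

Problem sizes used by the shipped tests and the acceptance script: 200
random instances for solver-oracle equivalence, 100 equal-priority
instances for the lexicographic property, 50 DAGs for hash propagation,
100 simulated executions for temp-file safety, and family sizes
1–100 (3–302 jobs) for the scaling law — sizes at which the enumeration
oracles are exact and the whole suite completes in well under a minute
per property.

What the generators do *not* emulate: real tool runtimes and their
variance, I/O contention, filesystem races, cluster middleware, or
network storage. Passing tests therefore demonstrate the correctness of
planning, scheduling, hashing and bookkeeping — not throughput on real
pipelines.

## Numerical and degenerate-input choices

* With no temporary files, $S$ is floored at 1 so the weights stay
  positive and strictly separated.
* File sizes are measured in MB rounded up, with a floor of one unit, so
  a present temporary file never has weight zero.
* The $\delta$ denominator counts *open* consumers only; jobs already
  running are not in it. Actual deletion is gated separately by the
  executor on *all* consumers having finished, so the stricter executor
  invariant holds regardless of the denominator convention.
* Empty pending sets yield an empty selection with objective 0; an empty
  workflow document is a parse error.
* A unit whose aggregated demand exceeds the *configured* capacity is an
  error at instance construction (it could never run); one exceeding only
  the currently *free* capacity simply waits.

## Known limitations

* The executor is single-machine and sequential within a scheduling
  round; no cluster or cloud submission, no remote storage.
* Deferred inputs are restricted to table-driven resolvers; arbitrary
  input-inference code is deliberately unsupported.
* Software environments are free-text descriptors that participate in
  hashing and logging; nothing is installed or containerized.
* The cache addresses all outputs of a job under one digest; per-output
  addressing would require a finer record shape.
* Streams require true co-execution to avoid materialization; the local
  sequential executor always takes the documented file-based downgrade.
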
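---
title: "Learning RNA folding paths by self-play tree search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning RNA folding paths by self-play tree search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnafoldpath)
```

## The problem

An RNA secondary structure is a set of base pairs — Watson-Crick A-U and
C-G plus the G-U wobble — over a sequence of length $L$. Structure
*prediction* asks what the final pair set is; this package is about the
*folding path*: the order in which those pairs form, from the open strand
to the native structure. The model of folding is deliberately minimal: a
folding trajectory is a sequence of single pair-formation events, each
drawn from the set of pairs that are still stereochemically available (the
*action space*), and the quality of an endpoint is its distance to the
native structure. No free energy enters anywhere: what the method learns is
the most probable route to the native state under its own pairing-level
scoring, which need not coincide with the thermodynamically dominant
pathway. That caveat matters when interpreting any output of this package
against experiments.

## States, actions, reward

A state is the set of pairs chosen so far. It is represented two ways: as a
strictly upper-triangular $L \times L$ contact matrix (entry $(i,j) = 1$
iff pair $(i,j)$ is formed, $i<j$), and, for the network, as an
$18 \times L \times L$ tensor: sixteen one-hot channels encode the ordered
base combination at each cell $(i,j)$ (order A, U, C, G; these channels
never change within an episode), channel 17 marks the currently legal
pairs, channel 18 the chosen ones.

A pair $(i,j)$ is legal when the bases are complementary (A-U, C-G, G-U)
and $j - i \ge 4$, i.e. at least three unpaired bases lie between the
partners. We read "at least three bases apart" as three *intervening*
bases; this off-by-one choice changes every action space, so it is pinned
by tests (a hairpin loop of three is the smallest that closes). After a
pair is chosen, every pair sharing one of its positions disappears from
the action space, and in the default pseudoknot-free mode so does every
pair crossing it ($i < a < j < b$ or $a < i < b < j$); what remains are
the four coexistence regions of a nested pair — both before, both after,
enclosed, enclosing. In pseudoknot-allowed mode crossing pairs stay
selectable. Legality is sequence-only: the native structure is never
consulted when building action spaces.

The reward of a finished episode is the squared-error distance between the
final and native contact matrices. Because entries are 0/1 and both
matrices are strictly upper-triangular, this is exactly the symmetric
difference of the two pair sets: missing pairs plus spurious ones. It is
an error, not a gain — lower is better, zero means the native state.
Episodes end on one of three hard conditions (empty action space, exact
native match, or the step cap $\lfloor L/2 \rfloor$) or when the value
head's estimate of the remaining error drops below the stop threshold
$\tau$ (default 0.5 — on an integer-valued error scale, "less than half a
base pair wrong" is the natural reading of "done"). The stop signal is
evaluated on the post-action state; an episode therefore always takes at
least one action.

## The network

Policy and value share a trunk of three 3x3 "same"-padded convolutions
(default widths 32/64/128, ReLU), applied to the
$18 \times L \times L$ encoding. Two heads follow:

* **policy**: 1x1 convolution to one channel, flattened to $L^2$ and
  softmaxed — a probability per cell $(i,j)$;
* **value**: per-channel global average pooling over the last feature
  maps, a dense layer to one unit, softplus — a strictly positive scalar
  predicting the state's error from the native structure. Pooling before
  (not after) the channel reduction matters: collapsing to one channel
  first leaves the head a single scalar feature, and in early experiments
  such a head regularly regressed to the mean of its targets and never
  differentiated states.

Both heads are fully convolutional, so a single parameter set serves every
sequence length; with a dense $L^2 \times L^2$ policy head the parameters
would be length-specific and the multi-RNA pool (below) could not share
one model. Training minimizes the sum of a squared-error value loss and a
cross-entropy policy loss against search-corrected targets, with Adam at
learning rate 0.001. The implementation is plain vectorized R: im2col
gathers turn each convolution into one BLAS matrix multiply, and the
backward pass is written against that same layout. At the problem sizes
this package targets (tens of nucleotides) this is faster to maintain and
entirely adequate; it is not a route to GPU-scale training.

Raw policies are masked to the current action space and renormalized
before use; if the network puts zero mass on every legal cell the masked
policy falls back to uniform, so the search never loses its footing on a
legal state.

## The search

Each folding step runs a Monte Carlo tree search whose nodes carry three
numbers: $V$, the running value estimate (predicted error-to-go, lower is
better); $N$, the visit count; and $P$, the prior from the policy head.
Selection descends by the score

$$ -V + c \, P \, \frac{\sqrt{N'}}{1 + N} $$

with $N'$ the parent's visits and the exploration constant $c = 5$. There
is no rollout: the leaf is evaluated by the value function directly, the
leaf's children are created from its action space with masked-policy
priors, and the value is backed up along the path, each node keeping the
running mean of everything backed through it. Three implementation choices
the formula leaves open:

* **Unvisited children** score with their parent's running mean in place
  of $V$ (first-play urgency). With $V = 0$ they would outrank every
  visited sibling — the error scale is positive — and the search would be
  forced through one visit of every child before statistics could matter.
* **Ties** break to the lexicographically smallest $(i,j)$, making
  single-threaded searches bit-reproducible.
* **Root reuse**: after an action is taken the chosen child becomes the
  new root and its subtree statistics persist; each step then adds its
  full simulation budget on top. The classical UCT score
  $W/N + c\sqrt{\ln T / N}$ is provided as a reference scorer only.

During self-play training a fraction (default 0.25) of Dirichlet noise is
mixed into the root priors at the start of every search. At the simulation
budgets the scaled studies use, self-play without it repeatedly collapses:
a mediocre network plus deterministic tie-breaking replays one trajectory,
whose samples further entrench the policy that produced it. Root-prior
noise is the standard antidote in self-play learners and leaves the
corrected policy a genuine search product (the noise perturbs where
simulations go, not the recorded visit counts). Prediction mode never adds
noise.

The search's product is the *corrected policy*: root-child visit counts
normalized to a distribution. During training the next action is drawn
from it for the first `explore_frac` of episodes (default 2/3) and taken
greedily (most visits) thereafter; prediction mode is always greedy and
hence deterministic. Sampling during the exploration phase is what
populates the folding-path tree with alternatives; annealing it away lets
the late episodes concentrate on the learned path. Drawing every training
action greedily from the start is supported (`action_select = "argmax"`)
but collapses all early episodes onto one deterministic trajectory, which
leaves the trainer no signal to improve on — and it is why prediction
mode has to remove the randomness explicitly: training-time selection is
stochastic by design.

## Training

Every episode contributes one sample per step: the state encoding, the
corrected policy, the final error $r$ (attached identically to every step
once the episode ends), and the value target. The value head is trained on
the *per-state* error — the state's own distance to the native structure —
because that is what $V$ stands for everywhere in the search: the
predicted error of a state, which the leaf evaluation stands in for. The
alternative (training the value head on the shared final $r$) was
implemented first and measurably defeats itself: once training converges,
every state on a successful episode carries target 0, the predicted value
of near-native states sinks below the stop threshold, and the stop rule
truncates a quarter to a half of late episodes one pair short of native —
an equilibrium in which the value hovers at exactly $\tau$. With per-state
targets the stop signal fires only where the structure really is
(predicted) complete, and value learning becomes ordinary regression on
visited states, which is also far more sample-efficient at small episode
counts. The recorded per-step search value estimate is kept for
diagnostics only. Samples enter a
FIFO replay buffer of capacity 100,000 and each generation round draws a
uniform batch (default 2024 samples, clamped to the buffer size) for one
Adam update; `updates_per_round` allows several smaller batches at the
same sample throughput. A generation round is `workers` episodes played
against a frozen parameter snapshot, merged into the buffer before the
update — the concurrency contract of the reference protocol (20 workers
sharing parameters) expressed sequentially; with `workers = 1` runs are
bit-reproducible under a fixed seed.

With several target RNAs, each episode folds one RNA drawn with
probability

$$ P_i = \frac{e^{V_i / (N_i L_i)}}{\sum_i e^{V_i / (N_i L_i)}} $$

where $V_i$ is the cumulative error over that RNA's episodes (initialized
to 1), $N_i$ its sampling count and $L_i$ its length. $N_i$ is initialized
to 1 so the initial exponent is $1/L_i$ — the sampling count appears in a
denominator and the reference leaves its start value unstated. RNAs that
keep folding badly, or have rarely been drawn, are revisited more often.
The advantage $A = Q - V$ of the actor-critic framing is exposed as a
diagnostic (`compute_advantage()`); the optimization itself is the
supervised fit to search-corrected targets described above.

## Path analysis

Episode paths accumulate in a trie keyed by *ordered* prefixes — the
object of study is formation order, so two episodes reaching the same pair
set by different routes occupy different branches. The modal ("fastest")
path descends the trie through maximally visited children (ties to the
smallest pair) and stops where more episodes terminate than continue.
Near-native filtering keeps paths whose endpoint is within `max_diff`
pairs of the native structure (default 2), by default after removing the
native's pseudoknot-layer pairs — a pseudoknot-free search cannot form
those, and should not be penalized for them. Formation-order maps rank
pairs by their position in a path; across several near-native paths the
ranks are aggregated by mean (the aggregation method behind published
order colorings is unstated; mean rank is the least-committal choice and
is labelled as such in the output).

## The synthetic generator and the benchmark fixtures

`gen_hairpin(stem_len, loop_len)` builds the canonical test article: a
Watson-Crick stem around an all-A loop, native pairs exactly the stem
rungs, legal by construction for `loop_len >= 3`. It emulates the one
structural motif whose folding order has a textbook expectation (zipping
from the loop-closing pair outward) and none of the features that make
real RNAs hard: no competing helices, no multiloops, no pseudoknots, no
misleading complementarity away from the stem. Tests passing on hairpins
therefore validate the machinery — environment, search, learning loop —
not biological realism.

Six benchmark RNAs are bundled as code fixtures (`get_fixture()`),
storing the printed sequence and dot-bracket of their source verbatim
plus a curated pair list. Three of the six printed records are internally
inconsistent, and the fixtures say so rather than silently repairing
them: PDB_00972's 31-character sequence and unbalanced dot-bracket are
kept alongside a reconstructed 30-nt sequence (dropping one G of its GGG
run — the unique single-deletion class under which all six printed pairs
become complementary); 1Y26's 73-character sequence is kept alongside a
71-nt reconstruction (removing a duplicated AU) matching its 71-character
dot-bracket; bpRNA_RFAM_25409's 39-character dot-bracket against a
38-character sequence is kept alongside an editorialized 7-pair
structure. Curated parts are labelled synthetic reconstructions in the
fixture notes; the explicit pair lists are authoritative throughout.

## Numerical and degenerate-input choices

* Coordinates are 1-based with $i<j$ everywhere user-visible; contact
  matrices are strictly upper-triangular (this is what makes the
  squared-error reward equal the symmetric difference).
* Stray spaces inside dot-brackets are stripped before parsing; `T` is
  normalized to `U`; any other character is an error, not a wildcard.
* A native structure violating the pairing alphabet triggers a warning,
  not an error: the native is ground truth for the reward, legality
  governs actions only (a pseudoknotted or non-canonical native is then
  simply unreachable, which is the honest answer).
* An empty action space at the root makes a search an error for the
  caller to handle; inside an episode it is a terminal state.
* `sample_rna` probabilities are computed with a single exponential
  normalization; pool sizes here are far too small for overflow to be a
  concern (the exponent is at most $V_i/L_i$, a per-episode error rate).

## Scaled study sizes

The reference protocol (1000 episodes x 2000 simulations per step, and a
21,650-episode multi-RNA run) is cluster-scale. The bundled tests and the
acceptance script instead run the whole pipeline at sizes chosen so each
stage still exercises its full mechanism: oracle-valued reachability on
the 30-nt benchmarks at 200 simulations per step; policy sharpening on a
three-action toy at 200 simulations; and self-play convergence on
`gen_hairpin(4, 4)` — 150 episodes, 64 simulations per step, an
8/16/16-channel network, batches of 128 with four updates per round at
learning rate 0.003, single worker. The raised learning rate is part of
the scaling: 0.001 belongs to the full protocol's batch of 2024, and at a
sixteenth of that batch with only ~600 total updates the value head
otherwise cannot fit the error surface inside the run. These sizes are the package's declared scaled-down study
conditions; the convergence check (last-fifty median error below
first-fifty, modal path ending at the native state) is the miniature
analogue of the full protocol's convergence behaviour.

## Known limitations

* The value head predicts a state's current error, not the best
  achievable error-to-go; the search's one-step-lookahead use of it is
  greedy in spirit, which suffices for nested targets (forming a native
  pair always reduces the error) but has no notion of sacrificing
  immediate distance for a better endpoint.
* Multi-worker rounds are reproducible only up to buffer merge order;
  bit-reproducibility requires `workers = 1`.
* Training at the published scale (hundreds of RNAs, thousands of
  episodes) is mechanically supported but computationally out of reach of
  this implementation by design.
* Nothing in the scoring knows thermodynamics; "fastest path" means
  most probable under the learned pairing-level policy.
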
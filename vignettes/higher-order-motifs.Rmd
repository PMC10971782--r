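---
title: "Higher-order motifs and the tempo of fixation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher-order motifs and the tempo of fixation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question this package addresses

In a graph-structured population, each node carries one individual and
edges describe who can replace whom. Two quantities summarise the
evolutionary fate of a new mutant: its **fixation probability** (the
chance its lineage takes over) and its **conditional fixation time** (the
mean time to takeover, averaged over the realisations that do take over).
Node-level (degree) and edge-level (mixing) structure are known to move
both quantities at once. The point of this package is the next level of
organisation: **three-node motifs** — wedges and triangles. On graphs with
a fixed degree structure, the triangle fraction turns out to be a dial
that changes fixation *time* nearly continuously while leaving fixation
*probability* essentially untouched, which makes it the natural control
knob when designing population topologies for directed evolution or
evolutionary-optimization workloads.

`evomotif` implements the full apparatus: generators that tune triangle
content at fixed lower-order structure, exact stochastic simulation of
the Moran Birth-death (Bd) and death-Birth (dB) processes, the
pair-approximation/diffusion theory that explains the simulations, and
rank-selection optimization experiments on smooth and rugged landscapes.

# The Moran model on a graph

A mutant allele *a* has fitness $1+s$; the resident *A* has fitness 1.
The population size $N$ is fixed. Under **Bd**, one individual is chosen
to reproduce with probability proportional to fitness from the whole
population, and its offspring replaces a uniformly random neighbour.
Under **dB**, a uniformly random individual dies and its neighbours
compete fitness-proportionally for the vacancy. One replacement attempt
is one **event**; $N$ events make a generation. All times this package
reports are in events (with a generations accessor); every comparison
against theory is made through dimensionless ratios, so the unit
convention cannot contaminate results.

The simulator keeps three integers exactly: the mutant count, the mixed
($Aa$) edge count, and the summed degree of mutants. With $p_{Aa}$ the
ordered-pair mixed-edge frequency $\mathrm{mixed}/2E$ and $p_a$ the
degree-weighted mutant frequency (equal to the node frequency on regular
graphs), the identities $p_{AA} = (1-p_a) - p_{Aa}$ and
$p_{aa} = p_a - p_{Aa}$ hold *exactly* at every recorded step — there is
no floating-point bookkeeping to drift. The incremental mixed-edge count
can be audited against a from-scratch recount on any interval
(`check_interval`), which the test suite does.

Two independent oracles guard the engine. For any graph with $N \le 14$,
`exact_fixation()` builds the full $2^N$ configuration chain and solves
the absorbing-chain linear systems; the conditional time comes from the
Doob $h$-transform identity $(I-Q)g = h$, $t = g/h$. For the well-mixed
special case, `wellmixed_conditional_time()` solves the $(N+1)$-state
frequency chain the same way. The two constructions agree to solver
tolerance on complete graphs, and Monte Carlo agrees with both on random
small graphs within sampling error.

# Describing structure: the dK hierarchy

`count_motifs()` reports the 0K–3K summary: mean degree, degree
distribution, the joint degree matrix $J(i,j)$ (edges linking a degree-$i$
to a degree-$j$ node), wedge and triangle counts, the **global
transitivity** $\phi = 3\Delta/W$ (with $W = \sum_v \binom{k_v}{2}$), and
the degree **assortativity** $r$ (Pearson correlation of degrees at edge
ends, symmetric over orientation; reported as missing — never as 0 — on
regular graphs, where it is undefined). Global transitivity is used
rather than mean local clustering because the pair approximation below
consumes a single graph-level $\phi$.

# Generating graphs with prescribed motif content

Degree-preserving **double edge swaps** replace edges $(a,b),(c,d)$ by
$(a,c),(b,d)$; the degree sequence (hence $W$) is invariant, so only the
triangle count moves. The **2K-preserving swap** additionally requires
the two edges to have the same unordered degree pair and exchanges
like-degree endpoints, conserving $J$ — and therefore the assortativity —
exactly.

For regular graphs, `tune_transitivity_regular()` runs a
Metropolis–Hastings chain: a proposed swap is accepted when
$U \le \min\!\left[1, P(\phi'|\phi_{\rm target})/P(\phi|\phi_{\rm target})\right]$
with $P$ a Gaussian density of mean $\phi_{\rm target}$ and width
$\sigma$; moves toward the target are always accepted. $\sigma$ grows by
a factor 1.001 every $Nk$ proposals, and the default budget is
$k \times 10^6$ proposals. Three schedule details were genuinely open and
are resolved as follows:

* **Initial width $\sigma_0 = 0.001$.** The acceptance rule must stay
  effectively greedy while the chain is far from the target *and* while it
  closes the final distance; once $\sigma$ becomes comparable to the
  distance-to-target the chain is entropy-dominated and drifts back
  toward the low-$\phi$ bulk of graph space. A small $\sigma_0$ keeps the
  strict regime in force throughout the approach. (A unit test exhibits
  both regimes by holding $\sigma$ fixed: tight widths concentrate the
  visited $\phi$ at the target, loose ones wander to the entropic bulk.)
* **Best-visited return.** Because the growing $\sigma$ eventually
  loosens acceptance completely, the annealer snapshots the
  closest-to-target *connected* state it visits and returns that, with
  diagnostics in `attr(, "anneal")`; a target missed by more than the
  tolerance raises a warning, never a silent miss.
* **Early stop.** By default the run ends once the best-visited state is
  within `stop_tol = 0.01` of the target; set `stop_tol = NULL` to study
  the chain itself.

Invalid proposals (self-loop or parallel edge) are re-drawn without
consuming budget, preserving the Markov-chain uniformity argument; a
stall guard terminates gracefully on graphs with no admissible swap
(e.g. complete graphs). Connectivity is enforced by revert-on-disconnect:
after each accepted swap a traversal runs, and a disconnecting swap is
undone. This is the simplest behaviour that is certainly correct; a
faster local check could be added without changing semantics.

Degree-heterogeneous graphs are built by `build_two_class_graph()` from a
connected realisation of the two-class degree sequence, annealed to a
target assortativity (`tune_assortativity()`, same Gaussian MH machinery
on $r$, with an $O(1)$ incremental update since degrees are swap
invariant). Their triangle content is then tuned with
`tune_transitivity_2k()`: moves toward the target always accepted, moves
away accepted with probability $\gamma$ ($1/\gamma$ the annealing
temperature), $\gamma$ starting at 0.5 and decaying by 0.99 every
$N\bar{k}$ proposals. The schedule start/decay are package choices; only
the rule's form and the direction of the $\gamma$ trend were prescribed.
Uniform sampling over graphs at fixed $\phi$ is *not* guaranteed in the
heterogeneous case.

```{r}
library(evomotif)
g <- random_regular(100, 5, seed = 1)
g03 <- tune_transitivity_regular(g, 0.3, seed = 2)
count_motifs(g03)
```

# The pair approximation and the acceleration factor

Write $p_a$ for the mutant frequency and $p_{Aa}$ for the mixed-edge
frequency. The expected per-generation changes are

$$\mu(\Delta p_a) = \frac{s}{w}\,p_{Aa}, \qquad
\mu(\Delta p_{Aa}) = \frac{p_{Aa}}{k}\Big[(k-1)(1-\phi)\Big(1-\frac{p_{Aa}}{p_A p_a}\Big) - 1\Big] + O(s),$$

with $w = 1 + s p_a$ the mean fitness. Node frequency moves at rate
$O(s)$ while edge frequency has an $s$-free relaxation term, so for weak
selection the edges equilibrate on the fast timescale at

$$p_{Aa}^* = (1 - F)\,p_A p_a, \qquad F = \frac{1}{(k-1)(1-\phi)}.$$

$F$ plays the role of an inbreeding coefficient: triangles make it more
likely that neighbours share ancestry, depressing the mixed-edge count.
Substituting $p_{Aa}^*$ into the diffusion equations gives

* fixation probability
  $P(p_0) = \dfrac{1-e^{-Nsp_0}}{1-e^{-Ns}}$ — the well-mixed result,
  independent of $\phi$ (regular graphs are isothermal);
* conditional fixation time
  $T(p_0) = \dfrac{T_{\rm wm}(p_0)}{1-F}$, with $T_{\rm wm}$ the *exact*
  well-mixed conditional time from the $h$-transformed chain solve, not a
  diffusion formula.

The **acceleration factor** $1-F$ (well-mixed time over structured time)
can never exceed one on regular graphs: triangles only decelerate. At
$F \ge 1$ (e.g. $k=2$, or $\phi \ge 1 - 1/(k-1)$) the approximation
diverges; `inbreeding_F()` flags this rather than returning a silent
number. All exponential forms use `expm1` and resolve $s = 0$ by the
analytic limit, not a numerical epsilon.

For degree-heterogeneous graphs the package exposes
$P = (1-e^{-\alpha s})/(1-e^{-N\alpha s})$ with the amplification factor
$\alpha$ as a plug-in parameter. The dB-rule value
$\alpha = (\mathrm{E}[i])^2/\mathrm{E}[i^2]$ over the degree distribution
is implemented (`db_amplification()`; 0.8 for the half degree-12 / half
degree-4 population); a Bd-rule $\alpha$ derived elsewhere can be passed
directly. Re-deriving the full heterogeneous diffusion system is out of
scope here.

# What the simulations confirm (and at what scale)

The acceptance-style tests run, at fixed seeds, with sizes chosen so the
whole suite completes comfortably on one CPU:

* 5-regular, $N=100$, $s=0.01$, Bd, 50,000 replicates per graph at
  $\phi \in \{0, 0.2, 0.4, 0.5\}$: probabilities within 3 binomial
  standard errors of $0.015741$ and indistinguishable across $\phi$; time
  ratios $T(0.4)/T(0)$ and $T(0.5)/T(0)$ within Monte Carlo error of
  $0.75/(1-1/2.4) \approx 1.286$ and $1.5$.
* The conditioned mid-sweep ratio $p_{Aa}/(p_A p_a)$, averaged over
  $p_a \in [0.3, 0.7]$ and over three annealed graph realisations per
  $\phi$, sits within 10% of $1-F$. Averaging over realisations matters:
  the annealer does not spread triangles perfectly uniformly, and single
  graphs scatter a few percent around the pair-approximation value —
  a real limitation of the theory, not of the sampler.
* 21 random graphs with $N \le 8$, both rules,
  $s \in \{0, 0.05, 0.2\}$: Monte Carlo (20,000 replicates) within 4
  standard errors of the exact solver for probability and conditional
  time.
* The 12/4 two-class graph at $r \approx 0$, $\phi \approx 0$, dB,
  $s = 0.01$: probability within 3 SE of the $\alpha = 0.8$ formula,
  $0.014470$.

What passing these does **not** show: the synthetic study graphs are
small ($N = 100$) and two-degree-class at most; real contact networks
have broad degree distributions, degree–clustering correlations and
community structure that the dK-constrained generators deliberately
exclude — that exclusion is the point of the design, which isolates the
triangle effect.

# Optimization experiments

`evolve_on_graph()` runs the evolutionary-algorithm experiments: each
individual carries a real genotype vector mapped to an objective value;
fitness is the **rank-selection** ladder from $1+s$ (best) linearly down
to $1-s$ (worst), re-ranked after every replacement so selection pressure
is constant (mean fitness exactly 1; ties broken by a random
permutation). Reproduction is Bd with $s = 1$ on 5-regular graphs of
size 100; on every reproduction either the parent or the offspring (fair
coin — the description offers both with no stated bias) receives a
Gaussian mutation, unconditionally.

Design choices that were genuinely open:

* **Quadratic objective** — never printed in the source material beyond
  "optimal reward of one"; implemented as $1 - \lVert x - x^*\rVert^2$ in
  2-D, optimum at the origin, all individuals starting at a common
  genotype at distance 1 (value 0). The headline statistic is a
  correlation across graphs, insensitive to the exact bowl.
* **Rastrigin** — standard inverted form
  $-(10d + \sum_i x_i^2 - 10\cos 2\pi x_i)$, 2-D, maximum 0 at the
  origin; common start at $(2, 2)$, a few local peaks away, so reaching
  the optimum requires crossing fitness valleys. Mutation sd 0.12 (ten
  times the quadratic's 0.012).
* **Thresholds on the recording cadence** — the population mean value is
  recorded every $N$ events and time-to-threshold (0.95 for the
  quadratic) is the first recorded crossing; replicates that never cross
  within the event cap are censored and excluded from means with a
  reported count.

With 150 replicates per graph across six $\phi$ targets spanning 0–0.5,
the mean time-to-0.95 against $1-F$ gives a Pearson correlation near
$-0.996$ — `scripts/acceptance.R` recomputes exactly this from scratch.
On the Rastrigin landscape the low-$\phi$ population leads at an early
checkpoint (5,000 events) and is overtaken by the high-$\phi$ population
at a late one (100,000 events): fast fixation helps on smooth
landscapes and hurts when valleys must be explored. The checkpoints are
the package's reduced-scale rendering of "early" and "late"; the
crossover location itself depends on mutation scale and start point.

```{r}
g0 <- tune_transitivity_regular(random_regular(100, 5), 0, seed = 4)
res <- evolve_on_graph(g0, opt_problem("quadratic"), n_rep = 150,
                       max_events = 1e6, seed = 5)
print(res)
```

# Randomness, reproducibility, limits

All stochastic functions take an optional `seed` and otherwise consume
R's global RNG stream; identical seed and configuration give identical
output, including from the C++ engines (which draw through R's RNG).
Replicates are run sequentially from one stream rather than from
per-replicate derived seeds — simpler, and the reproducibility contract
is unchanged; parallel ensembles would need a splitting scheme on top.

Known limitations: the annealers hold the adjacency in a byte matrix and
are limited to $N \le 4096$ (far above the intended study sizes); the
exact solver stops at $N = 14$ by construction; Bd and dB coincide on
complete graphs only at neutrality (the dB parent pool excludes the
vacated node, an $O(s/N)$ difference); the pair approximation degrades
as $F \to 1$ and for graphs whose triangles are concentrated rather than
spread; and the heterogeneous-graph theory is exposed only through the
plug-in $\alpha$ interface described above.
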
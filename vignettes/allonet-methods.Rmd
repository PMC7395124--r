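---
title: "Methods: perturbation propagation on residue contact networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perturbation propagation on residue contact networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allonet)
```

This vignette documents the model implemented by `allonet`, the exact
algorithmic conventions it follows (tie-breaking, termination, random-number
discipline), and the assumptions and limitations a user should keep in mind.

## The physical picture

A mechanical perturbation applied at one site of a protein — ligand binding,
a mutation, phosphorylation — redistributes strain through the tightly packed
interior. Residues that share many atom-level contacts push on each other
strongly; residues connected only through sparse packing communicate weakly.
`allonet` coarse-grains a static structure into a network of residues whose
edges carry the probability that a perturbation of one residue propagates to
its neighbour, then estimates long-range coupling by simulating many
independent realizations of the propagation process. No dynamics, force
field, or sequence information is used; the only input is the heavy-atom
geometry of a single model.

## From coordinates to a probabilistic network

**Atoms and residues.** All non-hydrogen atoms of the selected model are
kept (optionally including HETATM groups, so bound ligands and cofactors can
participate as network nodes). A node is a unique (chain, residue number,
insertion code) triple, labelled `"A/57"`. When a file contains alternate
locations, each atom keeps the altloc with the highest occupancy, ties going
to the alphabetically first altloc identifier.

**Contacts.** Two atoms are in contact when their distance is strictly less
than the cutoff `r0` (default 3.4 Å). The residue contact count `C[i, j]` is
the number of contacting atom pairs between residues `i` and `j`. Pairs of
backbone atoms (`N`, `CA`, `C`, `O`) belonging to sequence-adjacent residues
of the same chain are excluded; without this exclusion every chain would be
trivially coupled end-to-end through the peptide bond and the network would
carry no structural information.

**Average contacts and probabilities.** The contact count is divided by the
residue's own atom count, `Navg[i, j] = C[i, j] / n_atoms[i]`, giving an
asymmetric measure of how much of residue `i`'s surface engages residue `j`.
The propagation probability is

```
P[i, j] = 1 - exp(-alpha * Navg[i, j])
```

with `alpha = 3.0` by default. Larger `alpha` saturates every edge toward 1
and washes out contrast; values around 0.5–3 keep the dynamic range useful.
Rows of `P` are intentionally *not* normalised to sum to 1 — this is not a
random walk. A perturbed residue may excite several neighbours in the same
round, or none, which is what lets the process model both signal branching
and signal extinction.

## The propagation process

One round of the process, given a set of source nodes:

1. Two state vectors over nodes: `V` (perturbed) and `W` (visited, i.e. has
   already received its one trial). Sources start with `V = W = 1` and are
   placed in a FIFO queue in ascending node order.
2. Pop the front node `i`. For each neighbour `j` of `i` in ascending index
   order with `W[j] == 0`: set `W[j] = 1`, draw one uniform variate `u`, and
   if `u < P[i, j]` set `V[j] = 1` and push `j` onto the queue.
3. Repeat until the queue is empty.

Three conventions matter and are fixed deliberately:

* **One trial per node.** A node gets its single Bernoulli trial from the
  *first* perturbed node to reach it (earliest in FIFO order). It is never
  retried, even if it later has other perturbed neighbours. This makes each
  round a frontier percolation: along any tree the probability of reaching a
  node is exactly the product of edge probabilities on the unique path from
  the source, which the test suite exploits as a closed-form oracle.
* **Only perturbed nodes propagate.** A node that received its trial and
  failed (`W = 1`, `V = 0`) is inert. The round therefore terminates when the
  frontier of newly perturbed nodes empties — including on disconnected
  graphs, where unreachable components simply keep `V = W = 0`.
* **Deterministic ordering.** The FIFO queue plus ascending neighbour order
  makes the sequence of uniform draws a pure function of the network and the
  RNG state, so a seed fully reproduces a run bit-for-bit.

The engine is written in C++ (Rcpp) but draws its uniforms from R's own
random number stream, so `set.seed()` governs it like any base-R simulation.

**ACI.** The allosteric coupling intensity of node `i` is the fraction of
`n_rounds` independent rounds (default `1e4`) in which `V[i] = 1`. Sources
report ACI 1 by construction. With `n` rounds the per-node standard error is
binomial, `sqrt(ACI * (1 - ACI) / n)` — at `1e4` rounds that is at most
0.005, and quadrupling precision costs sixteen-fold the rounds.
`convergence_report()` estimates this empirically by re-running batches
under derived sub-seeds.

**Pathways.** When a target set is given, each round that reaches the target
records the parent-pointer chain from the earliest-perturbed target node
back to the source. Identical chains are tallied; a pathway's weight is its
count divided by `n_rounds` (not by the number of successful rounds), so
weights are absolute traversal frequencies. Ties in the ranking are broken
lexicographically on the node sequence.

**Residue importance.** The importance of residue `a` for communication
between two sites aggregates the weights `p_i` of all distinct pathways that
pass through `a` as a probabilistic union:

```
p_a <- p_a + p_i - p_a * p_i        # equivalently 1 - prod(1 - p_i)
```

treating pathways as independent routes; a residue on every dominant route
approaches the total reach frequency.

**Hotspots.** Coupling peaks are extracted by a steepest-ascent clustering:
each non-source node points at the neighbour (minimum inter-atomic distance
strictly below 4.5 Å) with the highest ACI *strictly greater* than its own
(ties on ACI go to the lower node index); nodes with no higher neighbour are
cluster centers. Following pointers partitions the non-excluded nodes into
hotspots. When evaluating against a known functional site,
`evaluate_sites()` reports two numbers: the fraction of predicted hotspots
whose center (or a member within the contact radius) touches the site, and
the fraction of site residues reached by those matched hotspots. The second
is defined via *matched* hotspots on purpose: since the clustering partitions
all nodes, "site residue inside any hotspot" would always be true and the
metric would be vacuous.

## All-pairs coupling and CHESCA comparison

`pairwise_aci()` runs one profile per node (each node in turn the sole
source, default 2000 rounds per source) and stacks them into a coupling
matrix. Each row uses a deterministic sub-seed derived from the master seed,

```
subseed(seed, k) = (seed + 1000003 * k) mod 2147483647
```

so row `k` of the matrix is bit-identical to the standalone profile
`aci_profile(net, k, seed = subseed(seed, k))`, and rows are independent of
how many other rows are computed.

For comparison with NMR chemical shift covariance analysis (CHESCA):
`combined_chemical_shift()` collapses amide 1H/15N shifts to
`CCS = H + 0.15 * N` per residue and variant; `chesca_correlation()` takes
the absolute Pearson correlation of CCS vectors across at least three
variants (zero-variance residues are returned as `NA`);
`gaussian_filter_matrix()` smooths either matrix with a missing-aware 2-D
Gaussian kernel (absent cells are dropped from the kernel and the weights
renormalised, so gaps neither spread nor bias neighbours); and
`correlation_tpr()` ranks unordered residue pairs by predicted coupling and
reports the fraction of the top `n_top` whose reference value exceeds a
threshold (default 0.5), excluding sequence-adjacent pairs that would
trivially dominate.

## Synthetic fixtures

The package generates three families of test structures; the sizes used in
the tests and the acceptance script are the package's own choices, picked so
the full suite runs in seconds.

* `make_helix(n)` — an idealised helical backbone (1.5 Å rise, 100° twist)
  with atom offsets arranged so that contacts occur only between residues
  three and four apart, mimicking `i, i+3/i+4` helical packing. It exercises
  banded contact topologies; it does not have side chains or realistic
  stereochemistry.
* `make_two_domain(n, linker_len)` — two compact pseudo-domains (3 Å grids,
  two atoms per residue) joined only by a linker chain `L`. The linker is a
  graph cut: with it removed the domains are farther apart than any cutoff in
  use, so every inter-domain pathway provably traverses it. This is the
  workhorse for pathway, importance, and hotspot behaviour.
* `make_network(edges)` — a bare probabilistic network from an explicit edge
  list, bypassing geometry entirely; used wherever a closed-form answer
  exists (trees, stars, small cycles).

These fixtures validate the algorithms, not the biology: they contain no
real packing density, secondary structure, or chemistry, and metric values
obtained on them should not be read as predictions about proteins.

## Assumptions and limitations

* A single static model stands in for the conformational ensemble; coupling
  mediated by disorder, large-scale motions, or solvent is invisible.
* Rounds are independent and memoryless; there is no notion of perturbation
  magnitude, direction, or time.
* The backbone-adjacent contact exclusion removes covalent-chain signal
  entirely, including any genuine through-backbone mechanics.
* Edge probabilities depend on `alpha` and the contact cutoff; comparisons
  are meaningful within one parameterisation, and ACI values are relative
  coupling scores, not physical observables.
* All estimates are Monte Carlo; rare pathways (weight below roughly
  `10 / n_rounds`) are sampled too noisily to rank reliably.

## Defaults at a glance

| parameter | default | used by |
|---|---|---|
| contact cutoff | 3.4 Å | `count_contacts()` |
| probability scale `alpha` | 3.0 | `propagation_probabilities()` |
| rounds, single source | 10000 | `aci_profile()`, `sample_pathways()` |
| rounds per source, all-pairs | 2000 | `pairwise_aci()` |
| hotspot neighbour cutoff | 4.5 Å | `detect_hotspots()` |
| site-match contact radius | 4.5 Å | `evaluate_sites()` |
| CCS nitrogen weight | 0.15 | `combined_chemical_shift()` |
| top-k reference threshold | 0.5 | `correlation_tpr()` |
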
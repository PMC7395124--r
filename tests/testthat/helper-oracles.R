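# Independent oracles and fixture builders used across the suite.

# Brute-force contact counting: double loop over all atom pairs, applying the
# strict-cutoff rule and the backbone-backbone exclusion for chain-adjacent
# residues. Deliberately naive and independent of count_contacts().
brute_force_contacts <- function(model, cutoff = 3.4) {
  n <- nrow(model$nodes)
  at <- model$atoms
  counts <- matrix(0L, n, n)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    if (model$nodes$chain[i] == model$nodes$chain[i + 1]) {
      adj[i, i + 1] <- adj[i + 1, i] <- TRUE
    }
  }
  for (a in seq_len(nrow(at))) {
    for (b in seq_len(nrow(at))) {
      if (b <= a) next
      i <- at$node[a]; j <- at$node[b]
      if (i == j) next
      d <- sqrt((at$x[a] - at$x[b])^2 + (at$y[a] - at$y[b])^2 +
                  (at$z[a] - at$z[b])^2)
      if (d >= cutoff) next
      if (adj[i, j] && at$is_backbone[a] && at$is_backbone[b]) next
      counts[i, j] <- counts[i, j] + 1L
      counts[j, i] <- counts[j, i] + 1L
    }
  }
  counts
}

# Exact enumeration of the frontier process: branches over every Bernoulli
# draw in the same order the engine makes them (FIFO queue, neighbours in
# ascending index, each node tested at most once). Returns exact per-node
# perturbation probabilities. Feasible for ~6 nodes / ~8 edges.
enumerate_aci <- function(net, source) {
  n <- nrow(net$probs)
  probs <- net$probs
  nbrs <- net$neighbors
  total <- numeric(n)
  rec <- function(queue, V, W, prob) {
    if (!length(queue)) {
      total <<- total + prob * V
      return(invisible())
    }
    n0 <- queue[1]
    nb <- nbrs[[n0]]
    nb <- nb[W[nb] == 0]
    if (!length(nb)) {
      rec(queue[-1], V, W, prob)
      return(invisible())
    }
    m <- nb[1]
    W[m] <- 1
    p <- probs[n0, m]
    if (p > 0) {
      V2 <- V; V2[m] <- 1
      rec(c(queue, m), V2, W, prob * p)
    }
    if (p < 1) rec(queue, V, W, prob * (1 - p))
  }
  source <- sort(unique(source))
  V <- numeric(n); W <- numeric(n)
  V[source] <- 1; W[source] <- 1
  rec(source, V, W, 1)
  total
}

# Closed-form ACI on trees: the product of edge probabilities along the
# unique source-to-node path (single source).
tree_aci <- function(net, source) {
  n <- nrow(net$probs)
  aci <- rep(NA_real_, n)
  aci[source] <- 1
  visited <- source
  frontier <- source
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in setdiff(net$neighbors[[u]], visited)) {
        aci[v] <- aci[u] * net$probs[u, v]
        visited <- c(visited, v)
        nxt <- c(nxt, v)
      }
    }
    frontier <- nxt
  }
  aci[is.na(aci)] <- 0
  aci
}

# Random multi-atom structure in PDB format: residues scattered in a box,
# some atoms named as backbone, so both the cutoff and the exclusion rule
# are exercised.
random_pdb <- function(n_res = 6, atoms_per_res = 3, seed = 1, box = 8) {
  set.seed(seed)
  names_pool <- c("N", "CA", "C", "O", "CB", "CG", "CD1", "OG")
  lines <- character(0)
  serial <- 1L
  for (i in seq_len(n_res)) {
    base <- stats::runif(3, 0, box)
    nm <- sample(names_pool, atoms_per_res)
    for (a in seq_len(atoms_per_res)) {
      xyz <- base + stats::runif(3, -1.5, 1.5)
      nm_a <- nm[a]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, if (nchar(nm_a) < 4) paste0(" ", nm_a) else nm_a,
        "ALA", "A", i, xyz[1], xyz[2], xyz[3], 1, 0,
        substr(nm_a, 1, 1)))
      serial <- serial + 1L
    }
  }
  c(lines, "END")
}

# Fabricate an ACI profile object directly (bypasses the engine) for
# clustering tests with hand-designed coupling landscapes.
fake_profile <- function(aci, source = integer(0),
                         labels = as.character(seq_along(aci))) {
  names(aci) <- labels
  structure(list(aci = aci, source = source, n_rounds = NA_integer_,
                 seed = NA_integer_, labels = labels, replicate_std = NULL),
            class = "aci_profile")
}

# Single-atom-per-residue structure at given coordinates (one CB each, so no
# backbone exclusion interferes), for distance/hotspot geometry tests.
point_model_pdb <- function(coords, chain = "A") {
  lines <- vapply(seq_len(nrow(coords)), function(i) sprintf(
    "ATOM  %5d  CB  ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    i, chain, i, coords[i, 1], coords[i, 2], coords[i, 3], 1, 0),
    character(1))
  c(lines, "END")
}
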
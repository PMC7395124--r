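# Contact counting and the propagation probability matrix.
#
# C_ij  = number of atom pairs (a in i, b in j) closer than the cutoff,
#         excluding backbone-backbone pairs of chain-adjacent residues
# N_ij  = C_ij / (number of atoms in residue i)   (asymmetric)
# P_ij  = 1 - exp(-alpha * N_ij)

#' Count inter-residue atom contacts
#'
#' Two atoms form a contact when their Euclidean distance is strictly below
#' the cutoff (default 3.4 Å). Pairs in which both atoms are backbone atoms
#' (N, CA, C, O) of sequence-adjacent residues of the same chain are excluded:
#' without this rule perturbations would travel trivially along the covalent
#' backbone and swamp the through-space network. A distance exactly equal to
#' the cutoff does not count.
#'
#' @param model A `structure_model`.
#' @param cutoff Contact distance cutoff in Å (default 3.4).
#' @return An object of class `contact_matrix`: list with `counts`
#'   (symmetric integer matrix, zero diagonal) and `cutoff`.
#' @examples
#' m <- read_structure(text = make_helix(8))
#' cm <- count_contacts(m)
#' cm$counts[1:5, 1:5]
#' @export
count_contacts <- function(model, cutoff = 3.4) {
  stopifnot(inherits(model, "structure_model"), cutoff >= 0)
  n <- nrow(model$nodes)
  at <- model$atoms
  counts <- matrix(0L, n, n,
                   dimnames = list(model$nodes$label, model$nodes$label))
  if (cutoff > 0 && nrow(at) > 1) {
    xyz <- as.matrix(at[, c("x", "y", "z")])
    d <- .atom_dist(xyz)
    close <- d < cutoff
    diag(close) <- FALSE
    node <- at$node
    bb <- at$is_backbone
    # exclusion: both backbone & nodes chain-adjacent
    adj <- .adjacent_pairs(model)
    idx <- which(close, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    if (nrow(idx)) {
      ni <- node[idx[, 1]]; nj <- node[idx[, 2]]
      keep <- ni != nj
      if (nrow(adj)) {
        adjkey <- paste(adj[, 1], adj[, 2])
        pkey <- paste(pmin(ni, nj), pmax(ni, nj))
        excl <- bb[idx[, 1]] & bb[idx[, 2]] & pkey %in% adjkey
        keep <- keep & !excl
      }
      ni <- ni[keep]; nj <- nj[keep]
      if (length(ni)) {
        tab <- table(factor(pmin(ni, nj), levels = 1:n),
                     factor(pmax(ni, nj), levels = 1:n))
        counts <- counts + matrix(as.integer(tab), n, n)
        counts <- counts + t(counts) - diag(diag(counts))
        dimnames(counts) <- list(model$nodes$label, model$nodes$label)
      }
    }
  }
  diag(counts) <- 0L
  structure(list(counts = counts, cutoff = cutoff), class = "contact_matrix")
}

# blockwise pairwise atom distances (keeps memory bounded for big structures)
.atom_dist <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

#' Per-atom averaged contact matrix
#'
#' Divides contact counts by the number of atoms in the source residue:
#' `N[i, j] = C[i, j] / n_atoms[i]`, so `N` is generally asymmetric. `N[i, j]`
#' is the average number of contacts each atom of residue `i` makes with
#' residue `j`, a size-independent measure of packing between the two.
#'
#' @param contacts A `contact_matrix`.
#' @param model The `structure_model` the contacts were computed from.
#' @return Numeric matrix of class `avg_contact_matrix`.
#' @export
average_contacts <- function(contacts, model) {
  stopifnot(inherits(contacts, "contact_matrix"),
            inherits(model, "structure_model"))
  na <- model$nodes$n_atoms
  if (any(na <= 0)) stop("every node must contain at least one atom")
  vals <- contacts$counts / na          # divides row i by n_atoms[i]
  class(vals) <- c("avg_contact_matrix", class(vals))
  vals
}

#' Perturbation propagation probability matrix
#'
#' Converts averaged contact counts into edge-wise propagation probabilities
#' `P[i, j] = 1 - exp(-alpha * N[i, j])`. The matrix is not row-normalised:
#' a perturbed residue may excite several neighbours in one round, or none.
#' `alpha` amplifies or damps all probabilities; low values (0.5-3) keep the
#' coupling profile structured, while large values saturate it.
#'
#' @param avg An `avg_contact_matrix`.
#' @param alpha Positive scale parameter (default 3.0).
#' @return Object of class `prop_matrix`: list with `probs` (entries in
#'   `[0, 1)`), `alpha`, `neighbors` (per-node integer vectors, ascending) and
#'   `labels`.
#' @export
propagation_probabilities <- function(avg, alpha = 3.0) {
  if (inherits(avg, "contact_matrix"))
    stop("pass the averaged matrix from average_contacts(), not raw counts")
  stopifnot(is.matrix(avg))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop("alpha must be a positive number")
  probs <- 1 - exp(-alpha * unclass(avg))
  .new_prop_matrix(probs, alpha = alpha)
}

.new_prop_matrix <- function(probs, alpha = NA_real_) {
  stopifnot(is.matrix(probs), nrow(probs) == ncol(probs),
            all(probs >= 0), all(probs < 1))
  diag(probs) <- 0
  n <- nrow(probs)
  neighbors <- lapply(seq_len(n), function(i)
    as.integer(which(probs[i, ] > 0)))
  labels <- rownames(probs)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  structure(list(probs = probs, alpha = alpha, neighbors = neighbors,
                 labels = labels),
            class = "prop_matrix")
}

#' @export
print.prop_matrix <- function(x, ...) {
  n <- nrow(x$probs)
  ne <- sum(x$probs > 0)
  cat("Perturbation propagation network\n")
  cat(sprintf("  %d nodes, %d directed edges (alpha = %s)\n", n, ne,
              format(x$alpha)))
  if (ne)
    cat(sprintf("  edge probabilities: %.3f - %.3f\n",
                min(x$probs[x$probs > 0]), max(x$probs)))
  invisible(x)
}

#' Build the full residue network from a structure
#'
#' Convenience wrapper chaining [count_contacts()], [average_contacts()] and
#' [propagation_probabilities()].
#'
#' @param model A `structure_model`.
#' @param cutoff Contact cutoff in Å (default 3.4).
#' @param alpha Probability scale parameter (default 3.0).
#' @return A `prop_matrix` with the intermediate matrices attached as
#'   attributes `contacts` and `avg`.
#' @examples
#' net <- residue_network(read_structure(text = make_helix(10)))
#' net
#' @export
residue_network <- function(model, cutoff = 3.4, alpha = 3.0) {
  cm <- count_contacts(model, cutoff)
  av <- average_contacts(cm, model)
  pm <- propagation_probabilities(av, alpha)
  attr(pm, "contacts") <- cm
  attr(pm, "avg") <- av
  pm
}

#' Export network matrices as a sparse edge list
#'
#' @param net A `prop_matrix` produced by [residue_network()] (so that the
#'   contact and averaged matrices are available) or any `prop_matrix`
#'   (then only probabilities are exported).
#' @param file Optional CSV path.
#' @return Data frame with columns i, j, label_i, label_j, C_ij, N_ij, P_ij
#'   for every directed edge with positive probability.
#' @export
edge_table <- function(net, file = NULL) {
  stopifnot(inherits(net, "prop_matrix"))
  idx <- which(net$probs > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  cm <- attr(net, "contacts")
  av <- attr(net, "avg")
  tab <- data.frame(
    i = idx[, 1], j = idx[, 2],
    label_i = net$labels[idx[, 1]], label_j = net$labels[idx[, 2]],
    C_ij = if (!is.null(cm)) cm$counts[idx] else NA_integer_,
    N_ij = if (!is.null(av)) unclass(av)[idx] else NA_real_,
    P_ij = net$probs[idx],
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) utils::write.csv(tab, file, row.names = FALSE)
  tab
}
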
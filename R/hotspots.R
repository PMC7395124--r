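# Allosteric hotspot detection by ACI gradient-following, and the
# precision/recall-style site evaluation metrics.

#' Minimum inter-atomic residue distance matrix
#'
#' The distance between two residues is the minimum distance over all of
#' their atom pairs.
#'
#' @param model A `structure_model`.
#' @return Symmetric numeric matrix (class `residue_dist`) with zero
#'   diagonal, labelled by node.
#' @export
residue_distance_matrix <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  n <- nrow(model$nodes)
  at <- model$atoms
  d <- .atom_dist(as.matrix(at[, c("x", "y", "z")]))
  out <- matrix(Inf, n, n,
                dimnames = list(model$nodes$label, model$nodes$label))
  node <- at$node
  for (i in seq_len(n)) {
    ai <- which(node == i)
    for (j in seq_len(n)) {
      if (j < i) next
      aj <- which(node == j)
      out[i, j] <- out[j, i] <- min(d[ai, aj])
    }
  }
  diag(out) <- 0
  class(out) <- c("residue_dist", class(out))
  out
}

#' Detect allosteric hotspots by ACI gradient-following
#'
#' Each residue points to the highest-ACI neighbour (within
#' `neighbor_cutoff` Å, by minimum inter-atomic distance) whose ACI strictly
#' exceeds its own; residues with no higher-ACI neighbour are cluster centers
#' (direction -1). Following the pointers uphill partitions the residues into
#' hotspots, local peaks of the coupling landscape that are candidate
#' allosteric sites. The perturbation source (active site) is excluded from
#' clustering by default since its ACI of 1 would absorb its surroundings.
#'
#' @param profile An `aci_profile`.
#' @param dist A `residue_dist` matrix from [residue_distance_matrix()].
#' @param neighbor_cutoff Neighbour distance threshold in Å (default 4.5).
#' @param exclude Node indices excluded from clustering; defaults to the
#'   profile's source set.
#' @return Object of class `hotspot_set`: list with `direction` (per-node
#'   pointer, -1 for centers, NA for excluded), `centers`, `clusters`
#'   (center -> member indices), `excluded`, `labels`, `aci`.
#' @export
detect_hotspots <- function(profile, dist, neighbor_cutoff = 4.5,
                            exclude = NULL) {
  stopifnot(inherits(profile, "aci_profile"))
  stopifnot(is.matrix(dist), nrow(dist) == length(profile$aci))
  if (neighbor_cutoff <= 0) stop("neighbor_cutoff must be positive")
  if (is.null(exclude)) exclude <- profile$source
  n <- length(profile$aci)
  keep <- setdiff(seq_len(n), exclude)
  if (!length(keep)) stop("all nodes are excluded from clustering")
  aci <- profile$aci

  direction <- rep(NA_integer_, n)
  for (i in keep) {
    nb <- keep[dist[i, keep] < neighbor_cutoff & keep != i]
    nb <- nb[aci[nb] > aci[i]]
    if (!length(nb)) {
      direction[i] <- -1L
    } else {
      best <- nb[aci[nb] == max(aci[nb])]
      direction[i] <- min(best)         # ties -> lower index
    }
  }

  centers <- keep[direction[keep] == -1L]
  root <- rep(NA_integer_, n)
  for (i in keep) {
    j <- i
    while (direction[j] != -1L) j <- direction[j]
    root[i] <- j
  }
  clusters <- split(keep, root[keep])
  names(clusters) <- profile$labels[as.integer(names(clusters))]

  structure(list(direction = direction, centers = centers,
                 clusters = clusters, excluded = sort(unique(exclude)),
                 neighbor_cutoff = neighbor_cutoff,
                 labels = profile$labels, aci = aci),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat("Hotspot set:", length(x$clusters), "clusters (neighbor cutoff",
      x$neighbor_cutoff, "Å)\n")
  ord <- order(-x$aci[x$centers])
  for (c0 in x$centers[ord]) {
    mem <- x$clusters[[x$labels[c0]]]
    cat(sprintf("  center %-10s ACI %.4f, %d members\n",
                x$labels[c0], x$aci[c0], length(mem)))
  }
  invisible(x)
}

#' @export
as.data.frame.hotspot_set <- function(x, ...) {
  data.frame(
    center = names(x$clusters),
    center_aci = vapply(x$clusters, function(m) {
      max(x$aci[m])
    }, numeric(1)),
    n_members = lengths(x$clusters),
    members = vapply(x$clusters, function(m)
      paste(x$labels[m], collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Evaluate predicted hotspots against a known allosteric site
#'
#' A predicted hotspot counts as true when any of its members lies within
#' `contact_radius` Å (minimum inter-atomic distance) of any true-site
#' residue. Following the field's usage for this method family, TPR is the
#' fraction of predicted hotspots that are true (a precision), and PPV is the
#' fraction of true-site residues covered by some hotspot (a recall).
#'
#' @param hotspots A `hotspot_set`.
#' @param true_site Node indices of the known allosteric site.
#' @param dist The `residue_dist` matrix used for matching.
#' @param contact_radius Match radius in Å (default 4.5).
#' @return List with `tpr`, `ppv` and `matched_hotspots` (names of true
#'   hotspot centers).
#' @export
evaluate_sites <- function(hotspots, true_site, dist, contact_radius = 4.5) {
  stopifnot(inherits(hotspots, "hotspot_set"))
  true_site <- sort(unique(as.integer(true_site)))
  if (!length(true_site)) stop("true_site must be non-empty")
  is_true <- vapply(hotspots$clusters, function(mem) {
    any(dist[mem, true_site, drop = FALSE] < contact_radius)
  }, logical(1))
  # a site residue is identified when a matched hotspot reaches it: either by
  # membership or within the contact radius (the clusters partition all
  # non-excluded nodes, so membership in *any* cluster would be vacuous)
  matched_members <- unlist(hotspots$clusters[is_true], use.names = FALSE)
  covered <- vapply(true_site, function(s) {
    s %in% matched_members ||
      (length(matched_members) && any(dist[matched_members, s] <
                                        contact_radius))
  }, logical(1))
  list(
    tpr = if (length(is_true)) mean(is_true) else 0,
    ppv = mean(covered),
    matched_hotspots = names(hotspots$clusters)[is_true]
  )
}
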
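# Allosteric pathway sampling and residue importance.

#' Sample allosteric pathways between two sites
#'
#' Runs the perturbation propagation process from the source site and, in each
#' round where the target site is perturbed, records the transmission route:
#' the parent-pointer chain from the earliest-perturbed target node back to a
#' source node. Identical node sequences are aggregated; each pathway's weight
#' is its empirical frequency (occurrences / rounds). The heaviest pathway is
#' the most likely allosteric communication route.
#'
#' @param probs A `prop_matrix`.
#' @param source Source node indices (e.g. the allosteric site).
#' @param target Target node indices (e.g. the active site); must be disjoint
#'   from `source`.
#' @param n_rounds Number of rounds (default 10000).
#' @param seed Integer seed (default 1).
#' @return Object of class `pathway_ensemble`: list with `paths` (list of
#'   integer node sequences, heaviest first; ties broken lexicographically),
#'   `weights`, `counts`, `reach_frequency`, `n_rounds`, `seed`, `labels`.
#' @examples
#' net <- make_network(rbind(c(1, 2, 0.9), c(2, 3, 0.9)))
#' sample_pathways(net, source = 1, target = 3, n_rounds = 2000, seed = 1)
#' @export
sample_pathways <- function(probs, source, target, n_rounds = 10000,
                            seed = 1) {
  net <- .check_net(probs)
  source <- sort(unique(as.integer(source)))
  target <- sort(unique(as.integer(target)))
  if (length(intersect(source, target)))
    stop("source and target sets must be disjoint")
  if (!length(source) || !length(target))
    stop("source and target must be non-empty")
  set.seed(seed)
  nl <- .neighbor_lists(net)
  res <- cpp_sample_pathways(nl$nbr, nl$prb, source, target,
                             as.integer(n_rounds))
  counts <- res$counts
  paths <- res$paths
  # heaviest first; ties by lexicographic node order
  if (length(paths)) {
    lex <- vapply(paths, function(p) paste(sprintf("%08d", p), collapse = ","),
                  character(1))
    ord <- order(-counts, lex)
    paths <- paths[ord]
    counts <- counts[ord]
  }
  structure(list(paths = paths, counts = counts,
                 weights = counts / n_rounds,
                 reach_frequency = res$reached / n_rounds,
                 source = source, target = target,
                 n_rounds = n_rounds, seed = seed, labels = net$labels),
            class = "pathway_ensemble")
}

.format_path <- function(path, labels) paste(labels[path], collapse = "-")

#' @export
print.pathway_ensemble <- function(x, n = 10, ...) {
  cat("Pathway ensemble:", length(x$paths), "distinct pathways,",
      x$n_rounds, "rounds\n")
  cat(sprintf("  target reached in %.1f%% of rounds\n",
              100 * x$reach_frequency))
  k <- min(n, length(x$paths))
  if (k) {
    cat("  top pathways:\n")
    for (i in seq_len(k))
      cat(sprintf("    %6.4f  %s\n", x$weights[i],
                  .format_path(x$paths[[i]], x$labels)))
  }
  invisible(x)
}

#' Keep the k heaviest pathways
#'
#' @param ensemble A `pathway_ensemble`.
#' @param k Number of pathways (default 10); the whole ensemble if smaller.
#' @return A `pathway_ensemble` restricted to the top `k` pathways
#'   (`reach_frequency` and metadata preserved).
#' @export
top_pathways <- function(ensemble, k = 10) {
  stopifnot(inherits(ensemble, "pathway_ensemble"), k >= 1)
  k <- min(k, length(ensemble$paths))
  out <- ensemble
  out$paths <- ensemble$paths[seq_len(k)]
  out$counts <- ensemble$counts[seq_len(k)]
  out$weights <- ensemble$weights[seq_len(k)]
  out
}

#' Residue importance from a pathway ensemble
#'
#' Folds pathway weights into a per-residue score by the probabilistic union
#' `p_a <- p_a + p_i - p_a * p_i` over every pathway `i` containing residue
#' `a`, equivalently `1 - prod(1 - p_i)`: the chance that at least one of the
#' sampled transmission routes through `a` is realised. Residues on no
#' pathway score 0.
#'
#' @param ensemble A `pathway_ensemble`.
#' @return Object of class `importance_profile`: list with `importance`
#'   (named numeric in `[0, 1]`) and `labels`.
#' @examples
#' net <- make_network(rbind(c(1, 2, 0.9), c(2, 3, 0.9)))
#' ens <- sample_pathways(net, 1, 3, n_rounds = 2000, seed = 1)
#' residue_importance(ens)
#' @export
residue_importance <- function(ensemble) {
  stopifnot(inherits(ensemble, "pathway_ensemble"))
  n <- length(ensemble$labels)
  imp <- numeric(n)
  for (i in seq_along(ensemble$paths)) {
    p <- ensemble$weights[i]
    a <- ensemble$paths[[i]]
    imp[a] <- imp[a] + p - imp[a] * p
  }
  names(imp) <- ensemble$labels
  structure(list(importance = imp, labels = ensemble$labels,
                 n_pathways = length(ensemble$paths)),
            class = "importance_profile")
}

#' @export
print.importance_profile <- function(x, n = 10, ...) {
  cat("Residue importance from", x$n_pathways, "pathways\n")
  pos <- x$importance[x$importance > 0]
  top <- sort(pos, decreasing = TRUE)
  top <- utils::head(top, n)
  for (i in seq_along(top))
    cat(sprintf("  %-10s %.4f\n", names(top)[i], top[i]))
  invisible(x)
}

#' Export a pathway ensemble as TSV
#'
#' One row per pathway: rank, weight, count and the node chain rendered as
#' `A/57-A/87-A/106-B/1`.
#'
#' @param ensemble A `pathway_ensemble`.
#' @param file Optional TSV path.
#' @return The data frame, invisibly when `file` is given.
#' @export
pathway_table <- function(ensemble, file = NULL) {
  stopifnot(inherits(ensemble, "pathway_ensemble"))
  tab <- data.frame(
    rank = seq_along(ensemble$paths),
    weight = ensemble$weights,
    count = ensemble$counts,
    pathway = vapply(ensemble$paths, .format_path, character(1),
                     labels = ensemble$labels),
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) {
    utils::write.table(tab, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    return(invisible(tab))
  }
  tab
}
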
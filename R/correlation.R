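# All-pairs coupling maps and comparison with NMR chemical-shift covariance
# analysis (CHESCA).

#' All-pairs allosteric coupling matrix
#'
#' Computes one ACI profile per node (each node in turn as the single source)
#' and stacks them into a square coupling matrix: entry `[i, j]` is the ACI of
#' node `j` under perturbation of node `i`, with a unit diagonal. The matrix
#' is generally asymmetric; set `symmetrize = TRUE` for the elementwise mean
#' of the matrix and its transpose.
#'
#' @param probs A `prop_matrix`.
#' @param n_rounds Rounds per source (default 2000, chosen so that a
#'   ~130-residue protein completes in minutes; increase for tighter
#'   estimates).
#' @param seed Master seed; source `i` uses a deterministic sub-seed, so row
#'   `i` reproduces `aci_profile(probs, i, n_rounds, .subseed(seed, i))`.
#' @param symmetrize Return the symmetrized matrix (default `FALSE`).
#' @return A `coupling_matrix`: numeric matrix with attributes `kind`
#'   (`"predicted_aci"`), `n_rounds`, `seed`, `symmetrized`.
#' @export
pairwise_aci <- function(probs, n_rounds = 2000, seed = 1,
                         symmetrize = FALSE) {
  net <- .check_net(probs)
  n <- nrow(net$probs)
  vals <- matrix(NA_real_, n, n, dimnames = list(net$labels, net$labels))
  for (i in seq_len(n)) {
    vals[i, ] <- aci_profile(net, i, n_rounds = n_rounds,
                             seed = .subseed(seed, i))$aci
  }
  diag(vals) <- 1
  if (symmetrize) vals <- (vals + t(vals)) / 2
  .new_coupling_matrix(vals, kind = "predicted_aci", n_rounds = n_rounds,
                       seed = seed, symmetrized = symmetrize)
}

.new_coupling_matrix <- function(vals, kind, ...) {
  structure(vals, class = c("coupling_matrix", class(vals)),
            kind = kind, meta = list(...))
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat("Coupling matrix (", attr(x, "kind"), "): ",
      nrow(x), " x ", ncol(x), " nodes\n", sep = "")
  meta <- attr(x, "meta")
  if (length(meta)) {
    keys <- vapply(seq_along(meta), function(i)
      paste0(names(meta)[i], " = ", format(meta[[i]])), character(1))
    cat(" ", paste(keys, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.coupling_matrix <- function(x, ...) {
  n <- nrow(x)
  graphics::image(seq_len(n), seq_len(n), t(unclass(x))[, n:1],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "residue", ylab = "residue",
                  main = attr(x, "kind"), useRaster = TRUE, ...)
  invisible(x)
}

#' Combined chemical shifts from per-residue 1H and 15N shifts
#'
#' The combined chemical shift of residue `i` is `CCS(i) = H(i) + 0.15 * N(i)`
#' (ppm), compressing an amide's two-dimensional chemical-shift position into
#' one scalar per variant.
#'
#' @param table Data frame with columns `residue`, `variant`, `H_ppm`,
#'   `N_ppm` (tidy, one row per residue x variant).
#' @param on_missing Either `"drop"` (default: a residue missing any variant's
#'   shifts is dropped with a warning) or `"wildtype"` (substitute that
#'   residue's shifts from the variant named by `wildtype`).
#' @param wildtype Variant label used for substitution when
#'   `on_missing = "wildtype"`.
#' @return Numeric matrix of CCS values, residues (rownames, sorted) x
#'   variants (colnames, in order of first appearance).
#' @examples
#' tab <- data.frame(residue = 5, variant = "WT", H_ppm = 8, N_ppm = 120)
#' combined_chemical_shift(tab)   # 8 + 0.15 * 120 = 26
#' @export
combined_chemical_shift <- function(table, on_missing = c("drop", "wildtype"),
                                    wildtype = "WT") {
  on_missing <- match.arg(on_missing)
  need <- c("residue", "variant", "H_ppm", "N_ppm")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  variants <- unique(table$variant)
  residues <- sort(unique(table$residue))
  ccs <- matrix(NA_real_, length(residues), length(variants),
                dimnames = list(residues, variants))
  ccs[cbind(match(table$residue, residues),
            match(table$variant, variants))] <-
    table$H_ppm + 0.15 * table$N_ppm
  miss <- which(is.na(ccs), arr.ind = TRUE)
  if (nrow(miss)) {
    if (on_missing == "wildtype") {
      if (!wildtype %in% variants)
        stop("wildtype variant '", wildtype, "' not present")
      ccs[miss] <- ccs[miss[, 1], match(wildtype, variants)]
      miss <- which(is.na(ccs), arr.ind = TRUE)
    }
    if (nrow(miss)) {
      bad <- unique(rownames(ccs)[miss[, 1]])
      warning("dropping residues with missing shifts: ",
              paste(bad, collapse = ", "))
      ccs <- ccs[setdiff(rownames(ccs), bad), , drop = FALSE]
    }
  }
  ccs
}

#' CHESCA correlation matrix
#'
#' Absolute Pearson correlation of per-residue combined-chemical-shift
#' vectors across protein variants. Strongly correlated (or anti-correlated)
#' shift responses to a panel of mutations indicate that two residues sense a
#' common conformational equilibrium, i.e. are allosterically coupled.
#'
#' @param ccs Matrix from [combined_chemical_shift()] (residues x variants,
#'   at least 3 variants).
#' @return A `coupling_matrix` of kind `"chesca"`; residues whose CCS vector
#'   has zero variance get `NA` rows/columns.
#' @export
chesca_correlation <- function(ccs) {
  stopifnot(is.matrix(ccs))
  if (ncol(ccs) < 3)
    stop("need at least 3 variants to correlate (got ", ncol(ccs), ")")
  # zero-variance residues produce NaN correlations; they are flagged as
  # missing below, so cor()'s warning about them is redundant
  vals <- abs(suppressWarnings(stats::cor(t(ccs))))
  flat <- apply(ccs, 1, stats::sd) == 0
  vals[flat, ] <- NA
  vals[, flat] <- NA
  diag(vals) <- 1
  .new_coupling_matrix(vals, kind = "chesca", n_variants = ncol(ccs))
}

#' Gaussian low-pass filter for a coupling matrix
#'
#' Smooths a residue-pair coupling matrix with a 2-D Gaussian kernel,
#' suppressing single-pair noise so that coupled sequence blocks stand out.
#' Missing entries are excluded from the kernel and the remaining weights
#' renormalised, so gaps neither spread nor bias their surroundings.
#'
#' @param matrix A `coupling_matrix` (or plain numeric matrix).
#' @param sigma Kernel width in residues (default 1.0).
#' @param radius Kernel half-width (default `max(1, ceiling(3 * sigma))`).
#' @return Filtered matrix of kind `"chesca_filtered"` (missing cells stay
#'   `NA`).
#' @export
gaussian_filter_matrix <- function(matrix, sigma = 1.0, radius = NULL) {
  stopifnot(is.matrix(matrix))
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma))
  x <- unclass(matrix)
  off <- -radius:radius
  k1 <- exp(-off^2 / (2 * sigma^2))
  kern <- outer(k1, k1)
  n <- nrow(x); m <- ncol(x)
  num <- matrix(0, n, m)
  den <- matrix(0, n, m)
  present <- !is.na(x)
  xz <- ifelse(present, x, 0)
  for (a in seq_along(off)) for (b in seq_along(off)) {
    w <- kern[a, b]
    da <- off[a]; db <- off[b]
    ri <- seq_len(n); rj <- seq_len(m)
    si <- ri + da; sj <- rj + db
    vi <- si >= 1 & si <= n
    vj <- sj >= 1 & sj <= m
    if (!any(vi) || !any(vj)) next
    num[ri[vi], rj[vj]] <- num[ri[vi], rj[vj]] +
      w * xz[si[vi], sj[vj], drop = FALSE]
    den[ri[vi], rj[vj]] <- den[ri[vi], rj[vj]] +
      w * present[si[vi], sj[vj], drop = FALSE]
  }
  out <- num / den
  out[!present] <- NA
  out[den == 0] <- NA
  dimnames(out) <- dimnames(x)
  .new_coupling_matrix(out, kind = "chesca_filtered", sigma = sigma,
                       radius = radius)
}

#' Top-k agreement between predicted and reference coupling
#'
#' Ranks unordered residue pairs by predicted coupling (descending; ties
#' broken lexicographically), keeps the strongest `n_top`, and reports the
#' fraction whose reference coupling exceeds `threshold`. Pairs missing in
#' the reference are excluded before ranking, and sequence-adjacent pairs
#' (index difference <= `exclude_adjacent`) are skipped by default since
#' trivially coupled neighbours would dominate any top-k list.
#'
#' @param predicted,reference Square matrices over the same residues.
#' @param n_top Number of top-ranked pairs to keep.
#' @param threshold Reference coupling above which a pair counts as a match
#'   (default 0.5).
#' @param exclude_adjacent Maximum index separation to exclude (default 1;
#'   use 0 to keep all off-diagonal pairs).
#' @return The true-positive ratio in `[0, 1]`.
#' @export
correlation_tpr <- function(predicted, reference, n_top, threshold = 0.5,
                            exclude_adjacent = 1) {
  stopifnot(is.matrix(predicted), is.matrix(reference),
            all(dim(predicted) == dim(reference)))
  if (n_top < 1) stop("n_top must be >= 1")
  n <- nrow(predicted)
  idx <- which(upper.tri(predicted), arr.ind = TRUE)
  sep <- idx[, 2] - idx[, 1]
  keep <- sep > exclude_adjacent & !is.na(reference[idx])
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) < n_top)
    stop("only ", nrow(idx), " valid pairs but n_top = ", n_top)
  pred <- predicted[idx]
  ord <- order(-pred, idx[, 1], idx[, 2])
  top <- idx[ord[seq_len(n_top)], , drop = FALSE]
  mean(reference[top] > threshold)
}
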
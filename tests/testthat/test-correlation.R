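test_that("all-pairs coupling of an edgeless network is the identity", {
  net <- make_network(matrix(numeric(0), 0, 3), n_nodes = 4)
  cmap <- pairwise_aci(net, n_rounds = 100, seed = 1)
  expect_equal(unclass(cmap), diag(4), ignore_attr = TRUE)
})

test_that("two-node coupling estimates the edge probability both ways", {
  net <- make_network(cbind(1, 2, 0.4))
  cmap <- pairwise_aci(net, n_rounds = 1e4, seed = 3)
  bound <- 4 * sqrt(0.4 * 0.6 / 1e4)
  expect_lt(abs(cmap[1, 2] - 0.4), bound)
  expect_lt(abs(cmap[2, 1] - 0.4), bound)
})

test_that("tree coupling matches path products and rows match profiles", {
  edges <- rbind(c(1, 2, 0.8), c(2, 3, 0.5), c(2, 4, 0.6))
  net <- make_network(edges)
  cmap <- pairwise_aci(net, n_rounds = 5000, seed = 11)
  for (i in 1:4) {
    exact <- tree_aci(net, source = i)
    for (j in setdiff(1:4, i)) {
      se <- sqrt(exact[j] * (1 - exact[j]) / 5000)
      expect_lt(abs(cmap[i, j] - exact[j]), 4 * se + 1e-12)
    }
    # row i reproduces the single-source profile at the derived sub-seed
    prof <- aci_profile(net, i, n_rounds = 5000,
                        seed = allonet:::.subseed(11, i))
    expect_equal(unname(cmap[i, ])[-i], unname(prof$aci)[-i])
  }
  sym <- pairwise_aci(net, n_rounds = 500, seed = 2, symmetrize = TRUE)
  expect_true(isSymmetric(unclass(sym)))
})

test_that("combined chemical shifts are H + 0.15 N", {
  tab <- data.frame(residue = c(5, 5, 6, 6),
                    variant = c("WT", "M1", "WT", "M1"),
                    H_ppm = c(8.0, 8.1, 7.5, 7.4),
                    N_ppm = c(120, 121, 110, 0))
  ccs <- combined_chemical_shift(tab)
  expect_equal(ccs["5", "WT"], 8 + 0.15 * 120)
  expect_equal(ccs["5", "WT"], 26.0)
  expect_equal(ccs["6", "M1"], 7.4)      # N = 0 leaves CCS = H
  # linearity in the shifts
  tab2 <- tab; tab2$H_ppm <- 2 * tab$H_ppm; tab2$N_ppm <- 2 * tab$N_ppm
  expect_equal(combined_chemical_shift(tab2), 2 * ccs)
})

test_that("missing shifts drop the residue unless wild-type substitution", {
  tab <- data.frame(residue = c(5, 5, 6), variant = c("WT", "M1", "WT"),
                    H_ppm = c(8, 8.1, 7.5), N_ppm = c(120, 121, 110))
  expect_warning(ccs <- combined_chemical_shift(tab), "dropping")
  expect_equal(rownames(ccs), "5")
  ccs2 <- combined_chemical_shift(tab, on_missing = "wildtype")
  expect_equal(ccs2["6", "M1"], ccs2["6", "WT"])
})

test_that("CHESCA correlations are absolute Pearson across variants", {
  ccs <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
               d = c(1, 5, 2, 9))
  cm <- chesca_correlation(ccs)
  expect_equal(cm["a", "b"], 1)          # identical up to scale
  expect_equal(cm["a", "c"], 1)          # perfect anti-correlation
  expect_equal(cm["a", "d"], abs(stats::cor(ccs["a", ], ccs["d", ])))
  # independent textbook formula on random tables
  set.seed(8)
  r <- matrix(stats::rnorm(5 * 6), 5)
  rownames(r) <- letters[1:5]
  cm2 <- chesca_correlation(r)
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:5) for (j in 1:5) {
    expect_equal(unname(unclass(cm2)[i, j]), abs(pearson(r[i, ], r[j, ])))
  }
  expect_error(chesca_correlation(ccs[, 1:2]), "3 variants")
  # zero-variance rows are flagged missing
  flat <- rbind(ccs, e = c(2, 2, 2, 2))
  cm3 <- chesca_correlation(flat)
  expect_true(all(is.na(unclass(cm3)["e", -5])))
})

test_that("Gaussian filtering has an identity limit and conserves constants", {
  set.seed(4)
  x <- matrix(stats::runif(49), 7)
  x <- (x + t(x)) / 2
  out <- gaussian_filter_matrix(x, sigma = 1e-6)
  expect_equal(unclass(out), x, tolerance = 1e-9, ignore_attr = TRUE)
  const <- matrix(0.7, 6, 6)
  expect_equal(unclass(gaussian_filter_matrix(const, 1)), const,
               ignore_attr = TRUE)
  # symmetric input -> symmetric output; convex-combination range property
  sm <- gaussian_filter_matrix(x, sigma = 1.5)
  expect_true(isSymmetric(unclass(sm)))
  expect_gte(min(sm), min(x))
  expect_lte(max(sm), max(x))
})

test_that("a single spike smears into the normalised Gaussian kernel", {
  n <- 11
  x <- matrix(0, n, n)
  x[6, 6] <- 1
  sigma <- 1
  out <- gaussian_filter_matrix(x, sigma = sigma)
  r <- 3
  off <- -r:r
  k1 <- exp(-off^2 / (2 * sigma^2))
  kern <- outer(k1, k1)
  # interior cells see the full kernel, so the response at offset (da, db)
  # is kern[da, db] / sum(kern)
  for (da in -2:2) for (db in -2:2) {
    expect_equal(unclass(out)[6 + da, 6 + db],
                 kern[da + r + 1, db + r + 1] / sum(kern),
                 tolerance = 1e-12)
  }
})

test_that("missing entries are renormalised away rather than spread", {
  x <- matrix(1, 5, 5)
  x[2, 2] <- NA
  out <- gaussian_filter_matrix(x, sigma = 1)
  expect_true(is.na(unclass(out)[2, 2]))
  # all present values are 1, so every filtered value must stay exactly 1
  expect_true(all(unclass(out)[!is.na(x)] == 1))
})

test_that("top-k agreement matches an exhaustive hand count", {
  pred <- matrix(0, 4, 4)
  refm <- matrix(0, 4, 4)
  pred[1, 3] <- 0.9; refm[1, 3] <- 0.8   # match
  pred[1, 4] <- 0.8; refm[1, 4] <- 0.2   # miss
  pred[2, 4] <- 0.7; refm[2, 4] <- 0.6   # match
  pred[1, 2] <- 0.95; refm[1, 2] <- 0.9  # adjacent: excluded
  pred <- pred + t(pred); refm <- refm + t(refm)
  expect_equal(correlation_tpr(pred, refm, n_top = 2), 0.5)
  expect_equal(correlation_tpr(pred, refm, n_top = 3), 2 / 3)
  expect_equal(correlation_tpr(pred, refm, n_top = 3,
                               exclude_adjacent = 0), 2 / 3)
  expect_equal(correlation_tpr(pred, refm, n_top = 1,
                               exclude_adjacent = 0), 1)
  # reference below threshold everywhere -> zero
  expect_equal(correlation_tpr(pred, refm * 0, n_top = 2), 0)
  # perfect prediction -> 1 whenever the top-k all exceed the threshold
  expect_equal(correlation_tpr(refm, refm, n_top = 2), 1)
  expect_error(correlation_tpr(pred, refm, n_top = 100), "valid pairs")
})

test_that("top-k agreement is invariant to monotone transforms", {
  set.seed(12)
  n <- 8
  pred <- matrix(stats::runif(n * n), n)
  pred <- (pred + t(pred)) / 2
  refm <- matrix(stats::runif(n * n), n)
  refm <- (refm + t(refm)) / 2
  base <- correlation_tpr(pred, refm, n_top = 5)
  expect_equal(correlation_tpr(pred^3, refm, n_top = 5), base)
  expect_equal(correlation_tpr(log(pred + 1), refm, n_top = 5), base)
})

test_that("pairs with missing reference are excluded before ranking", {
  pred <- matrix(0.5, 5, 5)
  pred[1, 4] <- 0.99; pred[4, 1] <- 0.99
  refm <- matrix(0.9, 5, 5)
  refm[1, 4] <- NA; refm[4, 1] <- NA
  expect_equal(correlation_tpr(pred, refm, n_top = 3), 1)
})
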
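test_that("residue distances are minimum inter-atomic distances", {
  coords <- rbind(c(0, 0, 0), c(5, 0, 0), c(5, 3.8, 0))
  m <- read_structure(text = point_model_pdb(coords))
  d <- residue_distance_matrix(m)
  expect_equal(d[1, 2], 5)
  expect_equal(d[2, 3], 3.8)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_true(isSymmetric(unclass(d)))
})

test_that("multi-atom residue distances match a brute-force atom scan", {
  m <- read_structure(text = random_pdb(n_res = 5, atoms_per_res = 4,
                                        seed = 21))
  d <- residue_distance_matrix(m)
  at <- m$atoms
  for (i in 1:5) for (j in 1:5) {
    ai <- which(at$node == i); aj <- which(at$node == j)
    dd <- Inf
    for (a in ai) for (b in aj) {
      dd <- min(dd, sqrt((at$x[a] - at$x[b])^2 + (at$y[a] - at$y[b])^2 +
                           (at$z[a] - at$z[b])^2))
    }
    if (i == j) dd <- 0
    expect_equal(unname(d[i, j]), dd)
  }
})

# a straight chain of single-atom residues spaced 3 Å apart: every residue's
# 4.5 Å neighbourhood is exactly its sequence neighbours
chain_model <- function(n) {
  read_structure(text = point_model_pdb(cbind(3 * (seq_len(n) - 1), 0, 0)))
}

test_that("monotone ACI along a contiguous chain gives one hotspot", {
  m <- chain_model(8)
  d <- residue_distance_matrix(m)
  prof <- fake_profile(seq(0.1, 0.8, by = 0.1), labels = m$nodes$label)
  hs <- detect_hotspots(prof, d, exclude = integer(0))
  expect_length(hs$clusters, 1)
  expect_equal(hs$centers, 8L)
  expect_equal(sort(hs$clusters[[1]]), 1:8)
  expect_equal(hs$direction[8], -1L)
  expect_equal(hs$direction[1:7], 2:8)
})

test_that("uniform ACI makes every node its own center", {
  m <- chain_model(5)
  d <- residue_distance_matrix(m)
  prof <- fake_profile(rep(0.4, 5), labels = m$nodes$label)
  hs <- detect_hotspots(prof, d, exclude = integer(0))
  expect_length(hs$clusters, 5)
  expect_equal(hs$centers, 1:5)
})

test_that("two separated ACI peaks form exactly two clusters", {
  # two blobs of 4 residues each, 20 Å apart; ACI rises to a peak inside
  # each blob
  coords <- rbind(cbind(3 * (0:3), 0, 0), cbind(20 + 3 * (0:3), 0, 0))
  m <- read_structure(text = point_model_pdb(coords))
  d <- residue_distance_matrix(m)
  prof <- fake_profile(c(0.2, 0.5, 0.9, 0.4, 0.3, 0.7, 0.95, 0.1),
                       labels = m$nodes$label)
  hs <- detect_hotspots(prof, d, exclude = integer(0))
  expect_length(hs$clusters, 2)
  expect_setequal(hs$centers, c(3L, 7L))
  expect_setequal(hs$clusters[[m$nodes$label[3]]], 1:4)
  expect_setequal(hs$clusters[[m$nodes$label[7]]], 5:8)
  # brute-force pointer check: following direction reaches the center
  for (i in setdiff(1:8, hs$centers)) {
    j <- i
    steps <- 0
    while (hs$direction[j] != -1L && steps < 10) {
      expect_gt(prof$aci[hs$direction[j]], prof$aci[j])  # strictly uphill
      j <- hs$direction[j]
      steps <- steps + 1
    }
    expect_true(j %in% hs$centers)
  }
})

test_that("pointer graph is acyclic on random profiles", {
  set.seed(77)
  m <- chain_model(12)
  d <- residue_distance_matrix(m)
  for (rep in 1:5) {
    prof <- fake_profile(stats::runif(12), labels = m$nodes$label)
    hs <- detect_hotspots(prof, d, exclude = integer(0))
    for (i in 1:12) {
      seen <- integer(0)
      j <- i
      while (hs$direction[j] != -1L) {
        expect_false(j %in% seen)
        seen <- c(seen, j)
        j <- hs$direction[j]
      }
    }
    # partition: every node in exactly one cluster
    all_members <- sort(unlist(hs$clusters, use.names = FALSE))
    expect_equal(all_members, 1:12)
  }
})

test_that("excluded source nodes are left out of the clustering", {
  m <- chain_model(6)
  d <- residue_distance_matrix(m)
  prof <- fake_profile(c(1, 0.5, 0.4, 0.3, 0.6, 0.2), source = 1L,
                       labels = m$nodes$label)
  hs <- detect_hotspots(prof, d)           # default exclude = source
  expect_equal(hs$excluded, 1L)
  expect_false(1L %in% unlist(hs$clusters))
  expect_true(is.na(hs$direction[1]))
  expect_error(detect_hotspots(prof, d, exclude = 1:6), "excluded")
})

test_that("cluster count does not increase with a larger neighbor cutoff", {
  set.seed(5)
  m <- chain_model(15)
  d <- residue_distance_matrix(m)
  prof <- fake_profile(stats::runif(15), labels = m$nodes$label)
  counts <- vapply(c(3.1, 4.5, 6.5, 9.5, 15.5), function(cutoff)
    length(detect_hotspots(prof, d, neighbor_cutoff = cutoff,
                           exclude = integer(0))$clusters), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("site evaluation reproduces hand counts", {
  # 2 predicted hotspots, one overlapping the true site -> TPR 0.5
  coords <- rbind(cbind(3 * (0:3), 0, 0), cbind(30 + 3 * (0:3), 0, 0))
  m <- read_structure(text = point_model_pdb(coords))
  d <- residue_distance_matrix(m)
  prof <- fake_profile(c(0.2, 0.5, 0.9, 0.4, 0.3, 0.7, 0.95, 0.1),
                       labels = m$nodes$label)
  hs <- detect_hotspots(prof, d, exclude = integer(0))
  expect_length(hs$clusters, 2)

  ev <- evaluate_sites(hs, true_site = c(2L, 3L), d)
  expect_equal(ev$tpr, 0.5)
  expect_equal(ev$ppv, 1.0)     # both site residues inside the true hotspot

  # hotspots covering the full site
  ev_all <- evaluate_sites(hs, true_site = c(1:3, 6:7), d)
  expect_equal(ev_all$tpr, 1.0)
  expect_equal(ev_all$ppv, 1.0)

  # site far from every hotspot member
  far <- rbind(coords, c(100, 100, 100))
  m2 <- read_structure(text = point_model_pdb(far))
  d2 <- residue_distance_matrix(m2)
  prof2 <- fake_profile(c(prof$aci, 0.01), labels = m2$nodes$label)
  hs2 <- detect_hotspots(prof2, d2, exclude = 9L)
  ev2 <- evaluate_sites(hs2, true_site = 9L, d2)
  expect_equal(ev2$tpr, 0)
  expect_equal(ev2$ppv, 0)
})

test_that("hotspot detection is deterministic", {
  m <- chain_model(10)
  d <- residue_distance_matrix(m)
  prof <- fake_profile(c(0.3, 0.6, 0.2, 0.8, 0.5, 0.5, 0.9, 0.1, 0.4, 0.7),
                       labels = m$nodes$label)
  h1 <- detect_hotspots(prof, d, exclude = integer(0))
  h2 <- detect_hotspots(prof, d, exclude = integer(0))
  expect_identical(h1, h2)
})
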
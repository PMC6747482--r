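# Clustering, scoring, interaction annotation and evaluation metrics.

randomEnsemble <- function(n, seed = 1) {
  hp <- hairpinFixture()
  el <- movableElements(hairpinSS())
  lapply(seq_len(n), function(k)
    perturbConformation(hp, el, nMoves = 3, seed = seed * 1000 + k))
}

test_that("the pairwise RMSD matrix matches per-pair superposition", {
  confs <- randomEnsemble(4, seed = 2)
  M <- pairwiseRMSD(confs)
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(0, 4))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(M[i, j], kabsch(atomCoords(confs[[i]]),
                                 atomCoords(confs[[j]]))$rmsd)
  expect_equal(pairwiseRMSD(list(confs[[1]], confs[[1]]))[1, 2], 0)
  other <- Conformation("A", data.frame(resi = 1, atom = "C1'",
                                        x = 0, y = 0, z = 0))
  expect_error(pairwiseRMSD(list(confs[[1]], other)), "sequence")
})

test_that("k-medoid clustering satisfies the argmin-sum centroid rule", {
  # k = n: every conformation is its own centroid
  M <- pairwiseRMSD(randomEnsemble(5, seed = 3), atomNames = "C1'")
  cs <- kmeansRMSD(M, 5, seed = 1)
  expect_setequal(cs@centroids, 1:5)
  expect_equal(cs@sizes, rep(1L, 5))

  # all-identical conformations, k = 1: first index wins the tie
  Z <- matrix(0, 6, 6)
  cs0 <- kmeansRMSD(Z, 1, seed = 4)
  expect_equal(cs0@centroids, 1L)
  expect_equal(sum(Z[cs0@centroids, ]), 0)

  # 7 conformations, k = 2: converged centroids equal brute-force medoids
  M7 <- pairwiseRMSD(randomEnsemble(7, seed = 5), atomNames = "C1'")
  cs2 <- kmeansRMSD(M7, 2, seed = 6)
  for (ci in 1:2) {
    members <- which(cs2@assignment == ci)
    sums <- rowSums(M7[members, members, drop = FALSE])
    expect_equal(cs2@centroids[ci], members[which.min(sums)])
  }
  expect_error(kmeansRMSD(M7, 8, seed = 1), "exceeds")

  # convergence monitor: within-cluster sums never increase
  hist <- attr(cs2, "withinHistory")
  expect_true(all(diff(hist) <= 1e-9))
})

test_that("annotation finds pairs and stacks with monotone thresholds", {
  helix <- idealHelix6()
  ann <- annotateInteractions(helix)
  expect_equal(nrow(ann@wcPairs), 6)
  expect_gte(nrow(ann@stacks), 10)

  # a fully extended chain has no interactions at all
  ext <- extendedChain()
  annE <- annotateInteractions(ext)
  expect_equal(nrow(annE@wcPairs), 0)
  expect_equal(nrow(annE@stacks), 0)

  # loosening every threshold yields a superset of the defaults
  loose <- annotateInteractions(helix, nnBounds = c(0, Inf), c1Bounds = c(0, Inf),
                                planeAngleMax = 180, stackDistMax = Inf,
                                stackAngleMax = 180, exclusive = FALSE)
  strict <- annotateInteractions(helix, exclusive = FALSE)
  key <- function(m) paste(m[, 1], m[, 2])
  expect_true(all(key(strict@wcPairs) %in% key(loose@wcPairs)))
})

test_that("interaction network fidelity follows its closed form", {
  p4 <- BaseInteractions(rbind(c(1, 5), c(2, 6), c(3, 7), c(4, 8)))
  expect_equal(interactionFidelity(p4, p4, "wc"), 1)
  q <- BaseInteractions(rbind(c(9, 12), c(10, 13)))
  expect_equal(interactionFidelity(p4, q, "wc"), 0)
  half <- BaseInteractions(rbind(c(1, 5), c(2, 6), c(9, 12), c(10, 13)))
  expect_equal(interactionFidelity(p4, half, "wc"), 0.5)   # sqrt(0.5 * 0.5)
  none <- BaseInteractions()
  expect_equal(interactionFidelity(none, none, "wc"), 1)
  expect_equal(interactionFidelity(p4, none, "wc"), 0)
  expect_equal(interactionFidelity(none, p4, "wc"), 0)
  # symmetry under swapping prediction and reference set sizes
  two <- BaseInteractions(rbind(c(1, 5), c(2, 6)))
  expect_equal(interactionFidelity(p4, two, "wc"),
               interactionFidelity(two, p4, "wc"))
  v <- interactionFidelity(half, p4, "wc")
  expect_gte(v, 0); expect_lte(v, 1)
})

test_that("the knowledge-based score is invariant and discriminative", {
  pot <- defaultPotential()
  native <- hairpinFixture()
  sNat <- scoreStructure(native, pot)

  # rigid-motion invariance
  R <- rotationMatrix(c(1, 2, 3), 1.1)
  rot <- native
  rot@atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(native@atoms[, c("x", "y", "z")]) %*% t(R), 2, c(5, -3, 2), `+`)
  expect_lt(abs(scoreStructure(rot, pot) - sNat), 1e-9)

  # empty potential scores zero
  expect_equal(scoreStructure(native, list()), 0)
  expect_equal(scoreStructure(native, NULL), 0)

  # native hairpin beats loop-coordinate-randomised decoys, 20 of 20 seeds
  wins <- 0
  for (sd in 1:20) {
    pert <- native
    sel <- pert@atoms$resi %in% 7:10
    set.seed(sd)
    cen <- colMeans(as.matrix(native@atoms[sel, c("x", "y", "z")]))
    pert@atoms[sel, c("x", "y", "z")] <-
      sweep(matrix(runif(sum(sel) * 3, -6, 6), ncol = 3), 2, cen, `+`)
    if (scoreStructure(pert, pot) > sNat) wins <- wins + 1
  }
  expect_equal(wins, 20)
})

test_that("centroid ranking equals an independent sort of the scores", {
  confs <- randomEnsemble(8, seed = 9)
  cs <- kmeansRMSD(confs, 3, seed = 2, atomNames = "C1'")
  pot <- defaultPotential()
  ranked <- rankCentroids(cs, confs, pot)
  expect_equal(length(ranked), 3)
  scores <- vapply(confs[cs@centroids], scoreStructure, numeric(1), potential = pot)
  expect_equal(attr(ranked, "indices"), cs@centroids[order(scores)])
  expect_equal(attr(ranked, "scores"), sort(scores))
  # the known-best centroid (the unperturbed native, if clustered) ranks first
  expect_identical(ranked[[1]]@atoms, confs[[attr(ranked, "indices")[1]]]@atoms)

  one <- kmeansRMSD(confs[1:2], 1, seed = 1, atomNames = "C1'")
  expect_equal(length(rankCentroids(one, confs[1:2], pot)), 1)
})

test_that("model evaluation reports RMSD and both fidelity scores", {
  native <- hairpinFixture()
  ev <- evaluateModel(native, native)
  expect_equal(ev$rmsd, 0, tolerance = 1e-9)
  expect_equal(ev$infWC, 1)
  expect_equal(ev$infStack, 1)
  pert <- perturbConformation(native, movableElements(hairpinSS()),
                              nMoves = 4, seed = 3)
  ev2 <- evaluateModel(pert, native)
  expect_gt(ev2$rmsd, 0.5)
  expect_lte(ev2$infWC, 1)
})
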
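# Conformation ensemble analysis: pairwise RMSD, k-medoid clustering with
# the argmin-sum centroid rule, knowledge-based scoring, geometric
# interaction annotation, and evaluation metrics (RMSD, INF).

#' Pairwise RMSD matrix of an ensemble
#'
#' @param confs list of \code{Conformation} with identical sequences
#' @param atomNames optional atom subset (e.g. \code{"C1'"} for a fast
#'   backbone-level matrix); default all atoms
#' @return symmetric matrix of superposed RMSDs (Angstrom), zero diagonal
#' @export
pairwiseRMSD <- function(confs, atomNames = NULL) {
  n <- length(confs)
  if (!n) stop("need at least one conformation")
  seqs <- vapply(confs, function(c) paste(c@sequence, collapse = ""), character(1))
  if (length(unique(seqs)) > 1)
    stop("conformations have different sequences")
  coords <- lapply(confs, atomCoords, atomNames = atomNames)
  M <- matrix(0, n, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    M[i, j] <- M[j, i] <- kabsch(coords[[i]], coords[[j]])$rmsd
  M
}

# centroid of one cluster: member with the smallest sum of distances to all
# other members; ties broken by the smallest conformation index
clusterCentroid <- function(D, members) {
  sums <- rowSums(D[members, members, drop = FALSE])
  members[which.min(sums)]
}

#' k-medoid clustering on an RMSD matrix
#'
#' k-means-style clustering where the distance is the pairwise RMSD and the
#' mean point of each cluster is the member with the smallest sum of
#' distances to all other members of the cluster.  Initial centroids are
#' chosen by farthest-point seeding from a seeded random start; assignment
#' and the centroid update iterate to a fixed point.
#'
#' @param x list of \code{Conformation} or a precomputed symmetric distance
#'   matrix
#' @param k number of clusters (1 <= k <= n)
#' @param seed RNG seed for the initialisation
#' @param atomNames atom subset when \code{x} is a conformation list
#' @return a \code{\link{ClusterSet}}; attribute \code{"withinHistory"}
#'   records the total within-cluster centroid-distance sum per iteration
#' @export
kmeansRMSD <- function(x, k, seed = 1, atomNames = NULL) {
  D <- if (is.matrix(x)) x else pairwiseRMSD(x, atomNames)
  n <- nrow(D)
  if (k > n) stop("k (", k, ") exceeds the number of conformations (", n, ")")
  if (k < 1) stop("k must be >= 1")
  withSeed(seed, {
    cent <- sample.int(n, 1)
    while (length(cent) < k) {
      dmin <- apply(D[, cent, drop = FALSE], 1, min)
      dmin[cent] <- -Inf
      cent <- c(cent, which.max(dmin))
    }
    history <- numeric(0)
    assign <- rep(NA_integer_, n)
    for (iter in 1:100) {
      newAssign <- apply(D[, cent, drop = FALSE], 1, which.min)
      newCent <- vapply(seq_len(k), function(ci) {
        members <- which(newAssign == ci)
        if (!length(members)) {
          # re-seed an emptied cluster with the point farthest from all centroids
          dmin <- apply(D[, cent, drop = FALSE], 1, min)
          which.max(dmin)
        } else clusterCentroid(D, members)
      }, integer(1))
      history <- c(history, sum(D[cbind(seq_len(n), newCent[newAssign])]))
      if (identical(newAssign, assign) && identical(newCent, cent)) break
      assign <- newAssign; cent <- newCent
    }
    cs <- new("ClusterSet", assignment = as.integer(assign),
              centroids = as.integer(cent), distMatrix = D,
              sizes = tabulate(assign, k))
    attr(cs, "withinHistory") <- history
    cs
  })
}

## ------------------------------------------------------------- annotation

baseFrame <- function(conf, resi) {
  base <- conf@sequence[resi]
  ring <- atomCoords(conf, resi, baseRingAtoms(base))
  if (nrow(ring) < 3) return(NULL)
  cen <- colMeans(ring)
  sv <- svd(sweep(ring, 2, cen))
  list(centroid = cen, normal = sv$v[, 3])
}

angleBetween <- function(a, b) {
  ca <- abs(sum(a * b) / (vnorm(a) * vnorm(b)))
  acos(pmin(1, ca)) * 180 / pi
}

#' Geometric annotation of base pairs and stacking
#'
#' Detects canonical pairs (Watson-Crick and G-U) by complementarity plus
#' three geometric criteria: the Watson-Crick edge nitrogen distance
#' (purine N1 / pyrimidine N3), the C1'-C1' distance, and the angle between
#' base planes.  Stacking is detected by base-centroid distance and plane
#' angle; pairs annotated as paired are not also reported as stacked.
#'
#' @param conf a \code{Conformation}
#' @param nnBounds WC-edge N-N distance window (Angstrom)
#' @param c1Bounds C1'-C1' distance window (Angstrom)
#' @param planeAngleMax maximum base-plane angle for pairing (degrees)
#' @param stackDistMax maximum base-centroid distance for stacking
#' @param stackAngleMax maximum plane angle for stacking (degrees)
#' @param exclusive if TRUE (default), each residue joins at most one pair
#'   (best N-N distance wins)
#' @return a \code{\link{BaseInteractions}}
#' @export
annotateInteractions <- function(conf, nnBounds = c(2.3, 3.5),
                                 c1Bounds = c(9.0, 11.5), planeAngleMax = 30,
                                 stackDistMax = 5.5, stackAngleMax = 30,
                                 exclusive = TRUE) {
  n <- nResidues(conf)
  frames <- lapply(seq_len(n), function(i) baseFrame(conf, i))
  c1 <- atomCoords(conf, atomNames = "C1'")
  c1resi <- as.integer(sub(":.*", "", rownames(c1)))
  c1row <- match(seq_len(n), c1resi)
  wcXyz <- lapply(seq_len(n), function(i) {
    m <- atomCoords(conf, i, wcAtom(conf@sequence[i]))
    if (nrow(m)) m[1, ] else NULL
  })
  cand <- list()
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    # adjacent residues cannot pair unless a chain break separates them
    if (j == i + 1 && !(i %in% conf@breaks)) next
    if (!isComplementary(conf@sequence[i], conf@sequence[j])) next
    if (is.null(frames[[i]]) || is.null(frames[[j]])) next
    if (is.null(wcXyz[[i]]) || is.null(wcXyz[[j]])) next
    dnn <- vnorm(wcXyz[[i]] - wcXyz[[j]])
    if (dnn < nnBounds[1] || dnn > nnBounds[2]) next
    if (is.na(c1row[i]) || is.na(c1row[j])) next
    dc1 <- vnorm(c1[c1row[i], ] - c1[c1row[j], ])
    if (dc1 < c1Bounds[1] || dc1 > c1Bounds[2]) next
    if (angleBetween(frames[[i]]$normal, frames[[j]]$normal) > planeAngleMax) next
    cand[[length(cand) + 1]] <- c(i, j, dnn)
  }
  wc <- NULL
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    if (exclusive) {
      cm <- cm[order(cm[, 3]), , drop = FALSE]
      used <- logical(n); keep <- logical(nrow(cm))
      for (r in seq_len(nrow(cm))) {
        if (!used[cm[r, 1]] && !used[cm[r, 2]]) {
          keep[r] <- TRUE
          used[cm[r, 1]] <- used[cm[r, 2]] <- TRUE
        }
      }
      cm <- cm[keep, , drop = FALSE]
    }
    wc <- cm[, 1:2, drop = FALSE]
  }
  wcSet <- canonicalPairs(wc)
  stacks <- list()
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    if (is.null(frames[[i]]) || is.null(frames[[j]])) next
    if (nrow(wcSet) && any(wcSet[, 1] == i & wcSet[, 2] == j)) next
    if (vnorm(frames[[i]]$centroid - frames[[j]]$centroid) > stackDistMax) next
    if (angleBetween(frames[[i]]$normal, frames[[j]]$normal) > stackAngleMax) next
    stacks[[length(stacks) + 1]] <- c(i, j)
  }
  BaseInteractions(wcSet, if (length(stacks)) do.call(rbind, stacks) else NULL)
}

#' Interaction network fidelity
#'
#' INF = sqrt(PPV x STY) with PPV = |pred & native| / |pred| and
#' STY = |pred & native| / |native|, over the chosen interaction type.
#' Both sets empty gives 1; exactly one empty gives 0.
#'
#' @param pred,native \code{BaseInteractions} of model and reference
#' @param which "wc" (canonical pairs) or "stack"
#' @return value in [0, 1]
#' @export
interactionFidelity <- function(pred, native, which = c("wc", "stack")) {
  which <- match.arg(which)
  p <- if (which == "wc") pred@wcPairs else pred@stacks
  q <- if (which == "wc") native@wcPairs else native@stacks
  if (!nrow(p) && !nrow(q)) return(1)
  if (!nrow(p) || !nrow(q)) return(0)
  key <- function(m) paste(m[, 1], m[, 2])
  both <- length(intersect(key(p), key(q)))
  sqrt((both / nrow(p)) * (both / nrow(q)))
}

## -------------------------------------------------------------- scoring

# coarse atom types used by the knowledge-based score
scoreAtomType <- function(base, atom) {
  glyc <- glycAtom(base); wcn <- wcAtom(base)
  ifelse(atom == "P", "P",
  ifelse(atom == "C4'", "C4",
  ifelse(atom == "C1'", "C1",
  ifelse(atom == glyc, "NG",
  ifelse(atom == wcn, "NW", NA_character_)))))
}

SCORE_TYPES <- c("P", "C4", "C1", "NG", "NW")

scoreAtoms <- function(conf) {
  a <- conf@atoms
  type <- scoreAtomType(conf@sequence[a$resi], a$atom)
  sel <- !is.na(type)
  list(xyz = as.matrix(a[sel, c("x", "y", "z")]), type = type[sel],
       resi = a$resi[sel])
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- crossv(b1, b2); n2 <- crossv(b2, b3)
  m1 <- crossv(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# backbone pseudo-torsions eta/theta built on P and C4' atoms
pseudoTorsions <- function(conf) {
  n <- nResidues(conf)
  P <- atomCoords(conf, atomNames = "P")
  C4 <- atomCoords(conf, atomNames = "C4'")
  rP <- as.integer(sub(":.*", "", rownames(P)))
  rC <- as.integer(sub(":.*", "", rownames(C4)))
  eta <- theta <- numeric(0)
  for (i in 2:max(2, n - 1)) {
    if (n < 3) break
    iP <- match(i, rP); iC <- match(i, rC)
    pP <- match(i - 1, rC); nP <- match(i + 1, rP); nC <- match(i + 1, rC)
    if (!anyNA(c(iP, iC, pP, nP)))
      eta <- c(eta, dihedral(C4[pP, ], P[iP, ], C4[iC, ], P[nP, ]))
    if (!anyNA(c(iP, iC, nP, nC)))
      theta <- c(theta, dihedral(P[iP, ], C4[iC, ], P[nP, ], C4[nC, ]))
  }
  list(eta = eta, theta = theta)
}

#' Train the knowledge-based scoring tables
#'
#' Counts distances between coarse atom types (P, C4', C1', glycosidic N,
#' Watson-Crick N) of distinct residues, bins them, and converts
#' to pseudo-energies by the log-ratio to the pooled (type-blind) reference
#' distribution; backbone pseudo-torsions eta/theta are binned against a
#' uniform reference.  Lower score = more native-like.
#'
#' @param structures list of training \code{Conformation}
#' @param binWidth distance bin width (Angstrom)
#' @param maxD maximum scored distance
#' @param torsionBins number of torsion bins over (-pi, pi]
#' @return potential table list for \code{\link{scoreStructure}}
#' @export
trainPotential <- function(structures, binWidth = 0.5, maxD = 20,
                           torsionBins = 24) {
  if (is(structures, "Conformation")) structures <- list(structures)
  nb <- as.integer(maxD / binWidth)
  nt <- length(SCORE_TYPES)
  counts <- array(0, c(nt, nt, nb))
  torEta <- numeric(torsionBins); torTheta <- numeric(torsionBins)
  for (conf in structures) {
    sa <- scoreAtoms(conf)
    D <- as.matrix(stats::dist(sa$xyz))
    np <- nrow(D)
    for (i in seq_len(np - 1)) for (j in (i + 1):np) {
      if (sa$resi[i] == sa$resi[j]) next
      b <- ceiling(D[i, j] / binWidth)
      if (b < 1 || b > nb) next
      ti <- match(sa$type[i], SCORE_TYPES); tj <- match(sa$type[j], SCORE_TYPES)
      counts[ti, tj, b] <- counts[ti, tj, b] + 1
      if (ti != tj) counts[tj, ti, b] <- counts[tj, ti, b] + 1
    }
    pt <- pseudoTorsions(conf)
    bin <- function(x) pmin(torsionBins, pmax(1, ceiling((x + pi) / (2 * pi) * torsionBins)))
    if (length(pt$eta)) for (b in bin(pt$eta)) torEta[b] <- torEta[b] + 1
    if (length(pt$theta)) for (b in bin(pt$theta)) torTheta[b] <- torTheta[b] + 1
  }
  ref <- apply(counts, 3, sum)
  refP <- (ref + 1) / sum(ref + 1)
  energies <- array(0, c(nt, nt, nb))
  for (ti in seq_len(nt)) for (tj in seq_len(nt)) {
    cab <- counts[ti, tj, ]
    pab <- (cab + 0.5) / sum(cab + 0.5)
    energies[ti, tj, ] <- pmax(-4, pmin(6, -log(pab / refP)))
  }
  torE <- function(ct) {
    p <- (ct + 0.5) / sum(ct + 0.5)
    pmax(-4, pmin(6, -log(p * torsionBins)))
  }
  list(pair = energies, binWidth = binWidth, maxD = maxD,
       etaE = torE(torEta), thetaE = torE(torTheta),
       torsionBins = torsionBins)
}

#' Score a conformation with the knowledge-based potential
#'
#' Sum of distance-binned pairwise atom-type pseudo-energies plus
#' torsion-binned backbone pseudo-energies; rigid-motion invariant; lower
#' is better.  An empty potential scores 0.
#'
#' @param conf a \code{Conformation}
#' @param potential tables from \code{\link{trainPotential}}; default is
#'   the packaged potential trained on the synthetic fixtures (a stand-in
#'   for a potential trained on experimental structures)
#' @return scalar pseudo-energy
#' @export
scoreStructure <- function(conf, potential = defaultPotential()) {
  if (is.null(potential) || !length(potential$pair)) return(0)
  sa <- scoreAtoms(conf)
  D <- as.matrix(stats::dist(sa$xyz))
  np <- nrow(D)
  nb <- dim(potential$pair)[3]
  e <- 0
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    if (sa$resi[i] == sa$resi[j]) next
    b <- ceiling(D[i, j] / potential$binWidth)
    if (b < 1 || b > nb) next
    ti <- match(sa$type[i], SCORE_TYPES); tj <- match(sa$type[j], SCORE_TYPES)
    e <- e + potential$pair[ti, tj, b]
  }
  pt <- pseudoTorsions(conf)
  tb <- potential$torsionBins
  bin <- function(x) pmin(tb, pmax(1, ceiling((x + pi) / (2 * pi) * tb)))
  if (length(pt$eta)) e <- e + sum(potential$etaE[bin(pt$eta)])
  if (length(pt$theta)) e <- e + sum(potential$thetaE[bin(pt$theta)])
  e
}

#' Rank cluster centroids by the knowledge-based score
#'
#' @param clusters a \code{\link{ClusterSet}}
#' @param confs the clustered conformations
#' @param potential scoring tables
#' @return list of centroid \code{Conformation}s, best (lowest score)
#'   first, with attributes \code{"scores"}, \code{"indices"} and
#'   \code{"clusterSizes"}
#' @export
rankCentroids <- function(clusters, confs, potential = defaultPotential()) {
  idx <- clusters@centroids
  scores <- vapply(confs[idx], scoreStructure, numeric(1), potential = potential)
  ord <- order(scores)
  out <- confs[idx[ord]]
  attr(out, "scores") <- scores[ord]
  attr(out, "indices") <- idx[ord]
  attr(out, "clusterSizes") <- clusters@sizes[ord]
  out
}

#' Compare a model against a reference structure
#'
#' @param pred,native \code{Conformation}s over the same sequence
#' @param atomNames optional atom subset for the RMSD
#' @return list with \code{rmsd}, \code{infWC}, \code{infStack}
#' @export
evaluateModel <- function(pred, native, atomNames = NULL) {
  common <- intersect(rownames(atomCoords(pred, atomNames = atomNames)),
                      rownames(atomCoords(native, atomNames = atomNames)))
  a <- atomCoords(pred)[common, , drop = FALSE]
  b <- atomCoords(native)[common, , drop = FALSE]
  annP <- annotateInteractions(pred)
  annN <- annotateInteractions(native)
  list(rmsd = kabsch(a, b)$rmsd,
       infWC = interactionFidelity(annP, annN, "wc"),
       infStack = interactionFidelity(annP, annN, "stack"))
}

## -------------------------------------------------- packaged potential

.pkgEnv <- new.env(parent = emptyenv())

#' Packaged default potential
#'
#' Trained once per session on deterministic synthetic fixtures (ideal
#' helices plus generated hairpin/internal-loop structures).  A documented
#' stand-in for tables trained on experimentally determined structures;
#' retrain with \code{\link{trainPotential}} on your own set for production
#' scoring.
#'
#' @return potential table list
#' @export
defaultPotential <- function() {
  if (!is.null(.pkgEnv$potential)) return(.pkgEnv$potential)
  train <- list(
    templateAsConformation(buildIdealHelix("GGCAGC", "GCUGCC")),
    templateAsConformation(buildIdealHelix("GCGCAUGC", "GCAUGCGC")),
    buildFixtureStructure("GGGCGCAAGAGCGCCC", "((((((....))))))", seed = 11),
    buildFixtureStructure("GCGCAAGCGCAAAGCGCGCGC", "((((..((((...))))))))", seed = 12))
  .pkgEnv$potential <- trainPotential(train)
  .pkgEnv$potential
}
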
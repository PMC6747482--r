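# De novo loop template generation: the bi-residue fragment method and
# distance-geometry embedding.

transformInverse <- function(tr) {
  R <- t(tr$rotation)
  list(rotation = R, translation = -as.vector(R %*% tr$translation))
}

identityTransform <- function() list(rotation = diag(3), translation = c(0, 0, 0))

# rigid transform carrying the reference sugar onto a residue's placed sugar
sugarTransform <- function(xyz) {
  nm <- rownames(.SUGAR_XYZ)
  fit <- kabsch(.SUGAR_XYZ, xyz[nm, , drop = FALSE])
  list(rotation = fit$rotation, translation = fit$translation)
}

residueSugar <- function(conf, resi) {
  a <- conf@atoms[conf@atoms$resi == resi & conf@atoms$atom %in% rownames(.SUGAR_XYZ), ]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$atom
  m
}

#' Cut a structure into bi-residue fragments
#'
#' One fragment per pair of consecutive, covalently continuous residues.
#' Each fragment stores the rigid transform from the first residue's sugar
#' frame to the second's, which is how the bi-residue builder chains them.
#' Pairs spanning a chain break (declared, or with an out-of-bounds O3'-P
#' distance) are skipped with a warning.
#'
#' @param source a \code{Conformation} with at least 2 residues
#' @return list of fragments (fields \code{delta}, \code{resi},
#'   \code{bond}: the internal O3'-P bond length)
#' @export
buildFragmentSet <- function(source) {
  n <- nResidues(source)
  frags <- list()
  skipped <- 0L
  for (i in seq_len(max(0, n - 1))) {
    if (i %in% source@breaks) { skipped <- skipped + 1L; next }
    s1 <- residueSugar(source, i)
    s2 <- residueSugar(source, i + 1)
    if (nrow(s1) < 9 || nrow(s2) < 9) { skipped <- skipped + 1L; next }
    bond <- vnorm(s2["P", ] - s1["O3'", ])
    if (bond < BOND_O3P_BOUNDS[1] || bond > BOND_O3P_BOUNDS[2]) {
      skipped <- skipped + 1L; next
    }
    t1 <- sugarTransform(s1)
    t2 <- sugarTransform(s2)
    frags[[length(frags) + 1]] <-
      list(delta = composeTransforms(transformInverse(t1), t2),
           resi = i, bond = bond)
  }
  if (skipped)
    warning(skipped, " residue pair(s) skipped (chain break or missing sugar)")
  frags
}

## ----------------------------------------------------- bi-residue builder

# Closing-end blocks of a loop node, in local numbering.  Each block is an
# ideal mini-helix over the closing pairs of one helix end, plus two
# "phantom" continuation pairs marking where the adjoining helix body
# extends (clash context only, never part of the template output).  The
# parent end (containing local residue 1) continues outward (below rung 0);
# child ends continue inward (above their last rung).
loopEndBlocks <- function(node, nodeSeq) {
  order <- nodeLocalOrder(node)
  local <- seq_along(order); names(local) <- order
  cl <- node@closingPairs
  clLocal <- cbind(local[as.character(cl[, 1])], local[as.character(cl[, 2])])
  ends <- findStems(canonicalPairs(clLocal))
  lapply(ends, function(p) {
    # p: 1-2 pairs, outer first; build an ideal helix over them
    i <- p[, 1]; j <- rev(p[, 2])
    s1 <- paste(nodeSeq[i], collapse = "")
    s2 <- paste(nodeSeq[j], collapse = "")
    tmpl <- buildIdealHelix(s1, s2)
    blockResi <- c(i, j)                    # template order -> node-local resi
    isParent <- 1 %in% blockResi
    rungs <- if (isParent) c(-1, -2) else c(nrow(p), nrow(p) + 1)
    ph <- do.call(rbind, lapply(rungs, function(r) {
      rbind(helixStepXYZ(refNucleotide("G"), r),
            helixStepXYZ(refNucleotide("C") %*% t(.STRAND2_FLIP), r))
    }))
    list(pairs = p, resi = blockResi, atoms = tmpl@atoms,
         nres = length(blockResi), phantom = unname(ph))
  })
}

# atoms matrix of one block residue (template-local index k)
blockResidueXYZ <- function(block, k) {
  a <- block$atoms[block$atoms$resi == k, ]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$atom
  m
}

#' Generate a loop template with the bi-residue fragment method
#'
#' Builds the 3D template of a loop-type SSE by chaining bi-residue
#' fragments: the closing pairs of each helix end form rigid ideal-helix
#' blocks; the parent end is fixed and each strand of unpaired residues is
#' grown from it by randomly chosen fragments, successive child-end blocks
#' riding on the growing chain.  Random fragment replacements are accepted
#' or rejected by the Metropolis rule against an energy combining chain
#' closure at the parent's far end, covalent-junction quality and a steric
#' clash term, under a geometric cooling schedule.
#'
#' @param node loop \code{SSENode} (kinds hairpin, bulge, internal,
#'   junction, exterior)
#' @param fragments list from \code{\link{buildFragmentSet}}
#' @param nodeSeq bases of the node in flattened strand order (defaults to
#'   all-A)
#' @param steps Monte Carlo steps (>= 0)
#' @param temperatures optional temperature schedule vector; default is a
#'   geometric ramp 20 -> 0.05
#' @param seed RNG seed; output is deterministic given the seed
#' @param details if TRUE also return acceptance ratio and energies
#' @return a \code{\link{Template}} (or a list when \code{details})
#' @export
biresidueBuild <- function(node, fragments, nodeSeq = NULL, steps = 300,
                           temperatures = NULL, seed = 1, details = FALSE) {
  if (steps < 0) stop("steps must be >= 0")
  if (!length(fragments)) stop("fragment set is empty")
  m <- length(node@residues)
  nodeSeq <- nodeSeq %||% rep("A", m)
  strandLens <- vapply(node@strands, length, integer(1))
  strandSeqs <- character(length(strandLens))
  off <- 0
  for (t in seq_along(strandLens)) {
    strandSeqs[t] <- paste(nodeSeq[(off + 1):(off + strandLens[t])], collapse = "")
    off <- off + strandLens[t]
  }
  blocks <- loopEndBlocks(node, nodeSeq)
  plan <- chainPlan(node, blocks)
  nstep <- length(plan$steps) + length(plan$preSteps)
  temps <- temperatures %||% (if (steps > 0)
    20 * (0.05 / 20)^(seq_len(steps) / steps) else numeric(0))
  temps <- rep_len(temps, max(steps, 1))

  build <- function(choices) ccdClose(buildChainFromChoices(plan, blocks,
                                        fragments, choices, nodeSeq), plan)
  energy <- function(st) chainEnergy(st, plan)

  withSeed(seed, {
    choices <- if (nstep) sample.int(length(fragments), nstep, replace = TRUE) else integer(0)
    st <- build(choices)
    e <- energy(st)
    e0 <- e
    acc <- 0L
    if (nstep > 0) for (s in seq_len(steps)) {
      pos <- sample.int(nstep, 1)
      cand <- choices
      cand[pos] <- sample.int(length(fragments), 1)
      st2 <- build(cand)
      e2 <- energy(st2)
      if (e2 <= e || stats::runif(1) < exp(-(e2 - e) / temps[s])) {
        choices <- cand; st <- st2; e <- e2; acc <- acc + 1L
      }
    }
    tmpl <- Template(node@kind, strandSeqs, st$atoms, closingLocal = plan$clLocal,
                     sourceId = "synthetic:biresidue")
    if (details)
      list(template = tmpl, acceptance = if (steps > 0) acc / steps else NA_real_,
           energyInitial = e0, energyFinal = e)
    else tmpl
  })
}

# Walk plan: which local residues are free (fragment-placed), where blocks
# enter and exit, and where the chain must close back onto the fixed parent
# block.
chainPlan <- function(node, blocks) {
  order <- nodeLocalOrder(node)
  local <- seq_along(order); names(local) <- order
  cl <- node@closingPairs
  clLocal <- canonicalPairs(cbind(local[as.character(cl[, 1])],
                                  local[as.character(cl[, 2])]))
  blockOf <- integer(length(order))            # 0 = unpaired
  for (bi in seq_along(blocks)) blockOf[blocks[[bi]]$resi] <- bi
  # parent block: the one containing local residue 1 (exterior nodes start
  # with either unpaired residues or a stem closing; then the first block)
  first <- if (blockOf[1] > 0) blockOf[1] else blockOf[blockOf > 0][1]
  # chain order is local order; steps are transitions between consecutive
  # local residues that are not interior to one block.  Residues before the
  # anchor block (5' dangle of an exterior element) are walked backward.
  n <- length(order)
  anchorStart <- min(which(blockOf == first))
  preSteps <- list()
  if (anchorStart > 1) for (r in (anchorStart - 1):1)
    preSteps[[length(preSteps) + 1]] <- c(from = r + 1, to = r)
  stepsL <- list()
  i <- anchorStart
  closure <- NULL
  while (i < n) {
    bi <- blockOf[i]; bj <- blockOf[i + 1]
    if (bi > 0 && bi == bj) { i <- i + 1; next }       # inside a block
    # transition i -> i+1; if the target belongs to the fixed parent block,
    # it is the closure point (chain re-entry), not a free step
    if (bj == first && bj > 0) { closure <- c(from = i, to = i + 1); break }
    stepsL[[length(stepsL) + 1]] <- c(from = i, to = i + 1)
    i <- i + 1
  }
  list(steps = stepsL, preSteps = preSteps, closure = closure,
       blockOf = blockOf, firstBlock = first, clLocal = clLocal)
}

buildChainFromChoices <- function(plan, blocks, fragments, choices, nodeSeq) {
  n <- length(plan$blockOf)
  placedT <- vector("list", n)      # sugar-frame transform per residue
  atoms <- vector("list", n)
  phantoms <- vector("list", length(blocks))
  placeBlock <- function(bi, entryResi, Tentry) {
    blk <- blocks[[bi]]
    k <- match(entryResi, blk$resi)
    Eentry <- sugarTransform(blockResidueXYZ(blk, k))
    Tblk <- composeTransforms(Tentry, transformInverse(Eentry))
    for (kk in seq_len(blk$nres)) {
      r <- blk$resi[kk]
      xyzB <- blockResidueXYZ(blk, kk)
      xyz <- applyTransform(xyzB, Tblk)
      rownames(xyz) <- rownames(xyzB)
      placedT[[r]] <<- sugarTransform(xyz)
      atoms[[r]] <<- residueAtoms(r, xyz)
    }
    phantoms[[bi]] <<- applyTransform(blk$phantom, Tblk)
  }
  # fixed parent block at its canonical pose
  blk0 <- blocks[[plan$firstBlock]]
  for (kk in seq_len(blk0$nres)) {
    r <- blk0$resi[kk]
    xyz <- blockResidueXYZ(blk0, kk)
    placedT[[r]] <- sugarTransform(xyz)
    atoms[[r]] <- residueAtoms(r, xyz)
  }
  phantoms[[plan$firstBlock]] <- blk0$phantom
  si <- 0
  for (stp in c(plan$preSteps, plan$steps)) {
    si <- si + 1
    from <- stp["from"]; to <- stp["to"]
    Tfrom <- placedT[[from]]
    delta <- fragments[[choices[si]]]$delta
    if (to < from) delta <- transformInverse(delta)   # backward 5' walk
    Tto <- composeTransforms(Tfrom, delta)
    bj <- plan$blockOf[to]
    if (bj > 0 && is.null(atoms[[to]])) {
      placeBlock(bj, to, Tto)
    } else if (is.null(atoms[[to]])) {
      ref <- refNucleotide(nodeSeq[to])
      xyz <- applyTransform(ref, Tto)
      rownames(xyz) <- rownames(ref)
      placedT[[to]] <- Tto
      atoms[[to]] <- residueAtoms(to, xyz)
    }
  }
  list(atoms = do.call(rbind, atoms), placedT = placedT,
       phantomList = phantoms)
}

# Cyclic-coordinate-descent chain closure: rigid rotations of the sub-chain
# about free-residue phosphates steer the final O3' onto its bonding
# distance from the fixed parent block's phosphate.  Rotations about a
# phosphate preserve every internal bond length exactly.
ccdClose <- function(st, plan, sweeps = 30, tol = 0.02) {
  if (is.null(plan$closure)) return(st)
  a <- st$atoms
  endRes <- plan$closure["from"]
  rowO3 <- which(a$resi == endRes & a$atom == "O3'")
  rowTP <- which(a$resi == plan$closure["to"] & a$atom == "P")
  if (!length(rowO3) || !length(rowTP)) return(st)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  tP <- xyz[rowTP, ]
  hinges <- which(plan$blockOf == 0 & seq_along(plan$blockOf) <= endRes)
  if (!length(hinges)) return(st)
  rowsOf <- lapply(hinges, function(k) which(a$resi >= k & a$resi <= endRes))
  rowP <- vapply(hinges, function(k) {
    w <- which(a$resi == k & a$atom == "P"); if (length(w)) w[1] else NA_integer_
  }, integer(1))
  blockRot <- lapply(seq_along(st$phantomList), function(bi) {
    if (bi == plan$firstBlock) return(NA_integer_)
    # hinge indices whose rotating range contains this block entirely
    resi <- which(plan$blockOf == bi)
    if (all(resi <= endRes)) min(resi) else NA_integer_
  })
  for (sw in seq_len(sweeps)) {
    E <- xyz[rowO3, ]
    if (abs(vnorm(E - tP) - BOND_O3P_IDEAL) < tol) break
    for (h in seq_along(hinges)) {
      if (is.na(rowP[h])) next
      P <- xyz[rowP[h], ]
      E <- xyz[rowO3, ]
      C <- tP + BOND_O3P_IDEAL * unitv(E - tP)
      v1 <- E - P; v2 <- C - P
      ax <- crossv(v1, v2)
      if (vnorm(ax) < 1e-9 || vnorm(v1) < 1e-9 || vnorm(v2) < 1e-9) next
      th <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2)))))
      if (th < 1e-6) next
      R <- rotationMatrix(ax, th)
      rw <- rowsOf[[h]]
      xyz[rw, ] <- sweep(sweep(xyz[rw, , drop = FALSE], 2, P) %*% t(R), 2, P, `+`)
      for (bi in seq_along(st$phantomList)) {
        if (!is.na(blockRot[[bi]]) && blockRot[[bi]] >= hinges[h])
          st$phantomList[[bi]] <-
            sweep(sweep(st$phantomList[[bi]], 2, P) %*% t(R), 2, P, `+`)
      }
    }
  }
  st$atoms[, c("x", "y", "z")] <- xyz
  st
}

chainEnergy <- function(st, plan) {
  a <- st$atoms
  e <- 0
  if (!is.null(plan$closure)) {
    o3 <- as.numeric(a[a$resi == plan$closure["from"] & a$atom == "O3'", c("x", "y", "z")])
    p  <- as.numeric(a[a$resi == plan$closure["to"] & a$atom == "P", c("x", "y", "z")])
    c3 <- as.numeric(a[a$resi == plan$closure["from"] & a$atom == "C3'", c("x", "y", "z")])
    e <- e + 4 * ((vnorm(p - o3) - BOND_O3P_IDEAL)^2 + 0.3 * (vnorm(p - c3) - 2.61)^2)
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  resi <- a$resi
  D <- as.matrix(stats::dist(xyz))
  close <- which(D < 2.6 & upper.tri(D), arr.ind = TRUE)
  if (nrow(close)) {
    dres <- abs(resi[close[, 1]] - resi[close[, 2]])
    bonded <- (a$atom[close[, 1]] == "O3'" & a$atom[close[, 2]] == "P" &
                 resi[close[, 2]] == resi[close[, 1]] + 1) |
              (a$atom[close[, 2]] == "O3'" & a$atom[close[, 1]] == "P" &
                 resi[close[, 1]] == resi[close[, 2]] + 1)
    far <- dres >= 2
    adj <- dres == 1 & !bonded & D[close] < 2.2
    ov <- c(2.6 - D[close][far], 2.2 - D[close][adj])
    if (length(ov)) e <- e + sum(ov^2)
  }
  # phantom helix continuations: keep the chain out of the adjoining stems
  if (length(st$phantomList)) {
    ph <- do.call(rbind, st$phantomList)
    D2 <- sqrt(pmax(0, outer(rowSums(xyz^2), rowSums(ph^2), `+`) -
                      2 * xyz %*% t(ph)))
    ov <- pmax(0, 2.45 - D2)
    e <- e + sum(ov^2)
  }
  e
}

## ------------------------------------------------------- distance geometry

#' Distance statistics for distance-geometry loop building
#'
#' Collects, per atom-pair class (within one nucleotide, between adjacent
#' nucleotides, between paired nucleotides, between stacked nucleotides) and
#' per atom-name pair, the observed distance range over the input
#' structures.  Pairing and stacking are taken from
#' \code{\link{annotateInteractions}}.
#'
#' @param structures list of \code{Conformation}
#' @param mode "range" (min/max observed) or "percentile" (1st/99th, more
#'   robust to outliers)
#' @return data.frame with columns class, atomA, atomB, lower, upper
#' @export
collectDistanceStats <- function(structures, mode = c("range", "percentile")) {
  mode <- match.arg(mode)
  if (is(structures, "Conformation")) structures <- list(structures)
  if (!length(structures)) {
    warning("no input structures; using default distance bounds")
    return(defaultDistanceStats())
  }
  rows <- list()
  addPair <- function(cls, resA, resB, conf, ordered) {
    xa <- atomCoords(conf, resA); xb <- atomCoords(conf, resB)
    na <- sub("^[0-9]+:", "", rownames(xa)); nb <- sub("^[0-9]+:", "", rownames(xb))
    for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
      if (cls == "intra" && j <= i) next
      a1 <- na[i]; a2 <- nb[j]
      if (!ordered && a1 > a2) { tmp <- a1; a1 <- a2; a2 <- tmp }
      rows[[length(rows) + 1]] <<- data.frame(
        class = cls, atomA = a1, atomB = a2,
        d = vnorm(xa[i, ] - xb[j, ]), stringsAsFactors = FALSE)
    }
  }
  for (conf in structures) {
    ann <- annotateInteractions(conf)
    n <- nResidues(conf)
    for (i in seq_len(n)) addPair("intra", i, i, conf, ordered = FALSE)
    for (i in seq_len(max(0, n - 1)))
      if (!(i %in% conf@breaks)) addPair("adjacent", i, i + 1, conf, ordered = TRUE)
    if (nrow(ann@wcPairs)) for (r in seq_len(nrow(ann@wcPairs)))
      addPair("paired", ann@wcPairs[r, 1], ann@wcPairs[r, 2], conf, ordered = FALSE)
    if (nrow(ann@stacks)) for (r in seq_len(nrow(ann@stacks)))
      addPair("stacked", ann@stacks[r, 1], ann@stacks[r, 2], conf, ordered = TRUE)
  }
  d <- do.call(rbind, rows)
  agg <- split(d$d, list(d$class, d$atomA, d$atomB), drop = TRUE)
  out <- do.call(rbind, lapply(names(agg), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    v <- agg[[k]]
    lim <- if (mode == "range") range(v) else stats::quantile(v, c(0.01, 0.99), names = FALSE)
    data.frame(class = parts[1], atomA = parts[2], atomB = parts[3],
               lower = lim[1], upper = lim[2], stringsAsFactors = FALSE)
  }))
  missing <- setdiff(c("intra", "adjacent", "paired", "stacked"), unique(out$class))
  if (length(missing)) {
    warning("no observations for class(es) ", paste(missing, collapse = ", "),
            "; default bounds will be used for them")
  }
  rownames(out) <- NULL
  out
}

defaultDistanceStats <- function() {
  data.frame(class = character(0), atomA = character(0), atomB = character(0),
             lower = numeric(0), upper = numeric(0), stringsAsFactors = FALSE)
}

# fallback whole-class windows when a specific atom pair was never observed
CLASS_DEFAULT_BOUNDS <- list(intra = c(1.2, 8), adjacent = c(1.2, 12),
                             paired = c(2.0, 13), stacked = c(2.5, 10),
                             other = c(2.5, 60))

#' Embed a distance (bounds) matrix into 3D
#'
#' Classical metric-matrix embedding: triangle-smooth the bounds
#' (Floyd-Warshall on the upper bounds, standard lower-bound tightening),
#' sample a distance matrix between them, embed with the top-3 eigenvector
#' decomposition (\code{stats::cmdscale}), then refine coordinates against
#' the original bounds by gradient-based violation minimisation.
#'
#' With \code{lower == upper} (exact, consistent distances) the embedding is
#' exact up to rigid motion and reflection.
#'
#' @param lower,upper symmetric bound matrices (Angstrom)
#' @param seed RNG seed for the distance sampling
#' @param refine number of refinement iterations (0 to skip)
#' @return n x 3 coordinate matrix
#' @export
embedDistances <- function(lower, upper = lower, seed = 1, refine = 200) {
  lower <- as.matrix(lower); upper <- as.matrix(upper)
  n <- nrow(lower)
  if (any(lower > upper + 1e-12)) stop("lower bound exceeds upper bound")
  U <- upper; L <- lower
  diag(U) <- 0; diag(L) <- 0
  # Floyd-Warshall smoothing
  for (k in seq_len(n)) {
    Uk <- outer(U[, k], U[k, ], `+`)
    U <- pmin(U, Uk)
    Lk <- pmax(outer(L[, k], -U[k, ], `+`), outer(-U[, k], L[k, ], `+`))
    L <- pmax(L, Lk)
  }
  if (any(L > U + 1e-9)) stop("bounds inconsistent after triangle smoothing; widen them")
  D <- withSeed(seed, {
    w <- matrix(stats::runif(n * n), n, n)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    L + w * (U - L)
  })
  diag(D) <- 0
  cm <- stats::cmdscale(stats::as.dist(D), k = min(3, n - 1), eig = TRUE)
  xyz <- cm$points
  if (ncol(xyz) < 3) {
    # up to 3 points are legitimately planar/collinear; larger systems with
    # exact (zero-width) bounds that cannot span 3D are degenerate
    if (n > 3 && max(U - L) < 1e-9)
      stop("embedding rank < 3: degenerate bounds; widen them")
    xyz <- cbind(xyz, matrix(0, n, 3 - ncol(xyz)))
  }
  if (refine > 0 && max(U - L) > 1e-9) {
    stress <- function(p) {
      x <- matrix(p, ncol = 3)
      d <- as.matrix(stats::dist(x))
      sum(pmax(0, d - upper)^2 + pmax(0, lower - d)^2) / 2
    }
    grad <- function(p) {
      x <- matrix(p, ncol = 3)
      d <- as.matrix(stats::dist(x))
      coef <- matrix(0, n, n)
      over <- d > upper; under <- d < lower & d > 1e-9
      coef[over] <- 2 * (d[over] - upper[over]) / d[over]
      coef[under] <- -2 * (lower[under] - d[under]) / d[under]
      diag(coef) <- 0
      g <- x * rowSums(coef) - coef %*% x
      as.vector(2 * g / 2)
    }
    opt <- stats::optim(as.vector(xyz), stress, grad, method = "L-BFGS-B",
                        control = list(maxit = refine))
    xyz <- matrix(opt$par, ncol = 3)
  }
  xyz
}

# signed volume of the sugar chirality tetrad C1'-C2'-C3'-C4'
sugarChirality <- function(xyz) {
  v1 <- xyz["C2'", ] - xyz["C1'", ]
  v2 <- xyz["C3'", ] - xyz["C1'", ]
  v3 <- xyz["C4'", ] - xyz["C1'", ]
  sum(crossv(v1, v2) * v3)
}

#' Fix the mirror ambiguity of an embedding
#'
#' Classical embedding is blind to reflection; this resolves it by the
#' handedness of the sugar ring (signed volume of C1'-C2'-C3'-C4'),
#' mirroring the coordinates when the majority of residues disagree with
#' the reference handedness.
#'
#' @param xyz coordinate matrix with rownames \code{"<resi>:<atom>"}
#' @param refSign reference chirality sign (default: the package's
#'   idealized sugar)
#' @return coordinate matrix with corrected handedness
#' @export
fixChirality <- function(xyz, refSign = sign(sugarChirality(.SUGAR_XYZ))) {
  nm <- rownames(xyz)
  resi <- sub(":.*", "", nm)
  signs <- c()
  for (r in unique(resi)) {
    sel <- which(resi == r)
    sub <- xyz[sel, , drop = FALSE]
    rownames(sub) <- sub("^[0-9]+:", "", nm[sel])
    if (all(c("C1'", "C2'", "C3'", "C4'") %in% rownames(sub)))
      signs <- c(signs, sign(sugarChirality(sub)))
  }
  if (length(signs) && mean(signs) * refSign < 0) xyz[, 1] <- -xyz[, 1]
  xyz
}

#' Generate a loop template by distance geometry
#'
#' Assembles lower/upper distance-bound matrices for all atoms of the loop
#' (by atom-pair class: intra-nucleotide, adjacent, paired closing pairs,
#' stacked closing pairs, generic otherwise), embeds them with
#' \code{\link{embedDistances}}, fixes the mirror ambiguity by sugar
#' chirality, and returns the loop as a template.
#'
#' @param node loop \code{SSENode}
#' @param bounds distance statistics from \code{\link{collectDistanceStats}}
#' @param nodeSeq bases in flattened strand order (default all-A)
#' @param seed RNG seed
#' @param refine refinement iterations passed to the embedder
#' @return a \code{\link{Template}}
#' @export
dgBuild <- function(node, bounds, nodeSeq = NULL, seed = 1, refine = 300) {
  m <- length(node@residues)
  nodeSeq <- nodeSeq %||% rep("A", m)
  order <- nodeLocalOrder(node)
  local <- seq_along(order); names(local) <- order
  cl <- node@closingPairs
  clLocal <- canonicalPairs(cbind(local[as.character(cl[, 1])],
                                  local[as.character(cl[, 2])]))
  strandLens <- vapply(node@strands, length, integer(1))
  strandOf <- rep(seq_along(strandLens), strandLens)
  atomsOf <- lapply(seq_len(m), function(r) {
    c(rownames(.SUGAR_XYZ), baseRingAtoms(nodeSeq[r]))
  })
  labels <- unlist(lapply(seq_len(m), function(r) paste0(r, ":", atomsOf[[r]])))
  resOf <- as.integer(sub(":.*", "", labels))
  atmOf <- sub("^[0-9]+:", "", labels)
  N <- length(labels)
  isPairOf <- function(i, j) any(clLocal[, 1] == min(i, j) & clLocal[, 2] == max(i, j))
  ends <- findStems(clLocal)
  isStackedOf <- function(i, j) {
    for (e in ends) {
      if (nrow(e) < 2) next
      same <- (abs(i - j) == 1) && all(c(i, j) %in% c(e[, 1])) ||
              (abs(i - j) == 1) && all(c(i, j) %in% c(e[, 2]))
      if (same) return(TRUE)
    }
    FALSE
  }
  lookup <- function(cls, a1, a2, orderedPair = FALSE) {
    if (!orderedPair && a1 > a2) { t <- a1; a1 <- a2; a2 <- t }
    hit <- bounds[bounds$class == cls & bounds$atomA == a1 & bounds$atomB == a2, ]
    if (nrow(hit)) c(hit$lower[1], hit$upper[1]) else CLASS_DEFAULT_BOUNDS[[cls]]
  }
  Lm <- matrix(0, N, N); Um <- matrix(0, N, N)
  maxD <- 7 * m
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    ri <- resOf[i]; rj <- resOf[j]
    b <- if (ri == rj) lookup("intra", atmOf[i], atmOf[j])
    else if (abs(ri - rj) == 1 && strandOf[ri] == strandOf[rj]) {
      if (ri < rj) lookup("adjacent", atmOf[i], atmOf[j], orderedPair = TRUE)
      else lookup("adjacent", atmOf[j], atmOf[i], orderedPair = TRUE)
    }
    else if (isPairOf(ri, rj)) lookup("paired", atmOf[i], atmOf[j])
    else if (isStackedOf(ri, rj)) {
      if (ri < rj) lookup("stacked", atmOf[i], atmOf[j], orderedPair = TRUE)
      else lookup("stacked", atmOf[j], atmOf[i], orderedPair = TRUE)
    }
    else c(CLASS_DEFAULT_BOUNDS$other[1], maxD)
    Lm[i, j] <- Lm[j, i] <- b[1]
    Um[i, j] <- Um[j, i] <- b[2]
  }
  xyz <- embedDistances(Lm, Um, seed = seed, refine = refine)
  rownames(xyz) <- labels
  xyz <- fixChirality(xyz)
  strandSeqs <- vapply(seq_along(strandLens), function(t)
    paste(nodeSeq[strandOf == t], collapse = ""), character(1))
  atoms <- data.frame(resi = resOf, atom = atmOf, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], stringsAsFactors = FALSE)
  Template(node@kind, strandSeqs, atoms, closingLocal = clLocal,
           sourceId = "synthetic:dg")
}
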
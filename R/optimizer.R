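# Restraint-guided simulated-annealing Monte Carlo refinement.

# flat-bottom windows (Angstrom)
BOND_FLAT   <- c(1.35, 1.90)    # O3'-P junction bond
SS_C1_FLAT  <- c(9.0, 11.5)     # nested pair C1'-C1'
SS_NN_FLAT  <- c(2.3, 3.5)      # nested pair WC-edge N-N
BP_C1_BOUNDS <- c(8.9, 11.9)    # base-pair restraint C1'-C1' (10.4 +- 1.5)
BP_NN_BOUNDS <- c(2.0, 3.6)     # base-pair restraint N-N (2.8 +- 0.8)
CLASH_RMIN  <- 3.0              # soft-sphere radius on the reduced atom set

#' Convert pseudoknot pairs to base-pair restraints
#'
#' One base-pair restraint per pseudoknot pair, realised as C1'-C1' bounds
#' 10.4 +- 1.5 A plus a Watson-Crick edge N-N window 2.8 +- 0.8 A (both
#' bracketing the package's ideal helix geometry), weight 1.
#'
#' @param pkPairs two-column matrix of pseudoknot pairs
#' @param weight restraint weight
#' @return restraint data.frame (columns kind, i, j, lower, upper, weight)
#' @export
restraintsFromPseudoknot <- function(pkPairs, weight = 1) {
  pkPairs <- canonicalPairs(pkPairs)
  if (!nrow(pkPairs))
    return(data.frame(kind = character(0), i = integer(0), j = integer(0),
                      lower = numeric(0), upper = numeric(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  data.frame(kind = "base_pair", i = pkPairs[, 1], j = pkPairs[, 2],
             lower = BP_C1_BOUNDS[1], upper = BP_C1_BOUNDS[2],
             weight = weight, stringsAsFactors = FALSE)
}

#' Number of coevolution restraints to keep
#'
#' The top-N rule for externally supplied coevolutionary contact
#' predictions: N = floor(0.2 x sequence length).
#'
#' @param sequenceLength RNA length in nucleotides
#' @return integer restraint count
#' @examples
#' dcaRestraintCount(75)  # 15
#' @export
dcaRestraintCount <- function(sequenceLength) {
  if (sequenceLength < 0) stop("length must be >= 0")
  as.integer(floor(0.2 * sequenceLength))
}

#' Read / write a restraint file
#'
#' Line-oriented format, 1-based residue numbers, '#' comments:
#' \preformatted{
#' PAIR i j [weight]
#' DIST i j lower upper [weight]
#' }
#' PAIR lines become base-pair restraints; DIST lines are C1'-C1' distance
#' restraints with explicit bounds.
#'
#' @param path file path
#' @return restraint data.frame
#' @export
readRestraints <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*", "", ln))
  ln <- ln[nzchar(ln)]
  rows <- lapply(seq_along(ln), function(k) {
    f <- strsplit(ln[k], "\\s+")[[1]]
    if (toupper(f[1]) == "PAIR") {
      if (length(f) < 3) stop("restraint line ", k, ": PAIR needs i j")
      data.frame(kind = "base_pair", i = as.integer(f[2]), j = as.integer(f[3]),
                 lower = BP_C1_BOUNDS[1], upper = BP_C1_BOUNDS[2],
                 weight = if (length(f) >= 4) as.numeric(f[4]) else 1,
                 stringsAsFactors = FALSE)
    } else if (toupper(f[1]) == "DIST") {
      if (length(f) < 5) stop("restraint line ", k, ": DIST needs i j lower upper")
      data.frame(kind = "distance", i = as.integer(f[2]), j = as.integer(f[3]),
                 lower = as.numeric(f[4]), upper = as.numeric(f[5]),
                 weight = if (length(f) >= 6) as.numeric(f[6]) else 1,
                 stringsAsFactors = FALSE)
    } else stop("restraint line ", k, ": unknown record '", f[1], "'")
  })
  do.call(rbind, rows)
}

#' @rdname readRestraints
#' @param restraints restraint data.frame
#' @export
writeRestraints <- function(restraints, path) {
  out <- vapply(seq_len(nrow(restraints)), function(r) {
    with(restraints[r, ], if (kind == "base_pair")
      sprintf("PAIR %d %d %g", i, j, weight)
    else sprintf("DIST %d %d %g %g %g", i, j, lower, upper, weight))
  }, character(1))
  writeLines(c("# ssefold restraints", out), path)
  invisible(path)
}

## --------------------------------------------------------- energy machinery

flatViolation <- function(d, lo, hi) pmax(0, d - hi, lo - d)

# precomputed index state for fast repeated energy evaluation
energyState <- function(conf, restraints = NULL, ss = NULL) {
  a <- conf@atoms
  n <- nResidues(conf)
  rowOf <- function(resi, atom) {
    w <- which(a$resi == resi & a$atom == atom)
    if (length(w)) w[1] else NA_integer_
  }
  bondFrom <- bondTo <- integer(0)
  for (r in seq_len(max(0, n - 1))) {
    if (r %in% conf@breaks) next
    i <- rowOf(r, "O3'"); j <- rowOf(r + 1, "P")
    if (!is.na(i) && !is.na(j)) { bondFrom <- c(bondFrom, i); bondTo <- c(bondTo, j) }
  }
  ssIdx <- NULL
  pairs <- if (!is.null(ss)) ss@pairs else NULL
  if (!is.null(pairs) && nrow(pairs)) {
    ssIdx <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      c(c1i = rowOf(i, "C1'"), c1j = rowOf(j, "C1'"),
        nni = rowOf(i, wcAtom(conf@sequence[i])),
        nnj = rowOf(j, wcAtom(conf@sequence[j])))
    }))
  }
  resIdx <- NULL
  if (!is.null(restraints) && nrow(restraints)) {
    resIdx <- do.call(rbind, lapply(seq_len(nrow(restraints)), function(k) {
      i <- restraints$i[k]; j <- restraints$j[k]
      c(c1i = rowOf(i, "C1'"), c1j = rowOf(j, "C1'"),
        nni = if (restraints$kind[k] == "base_pair")
          rowOf(i, wcAtom(conf@sequence[i])) else NA_integer_,
        nnj = if (restraints$kind[k] == "base_pair")
          rowOf(j, wcAtom(conf@sequence[j])) else NA_integer_)
    }))
  }
  sel <- which(a$atom %in% c("P", "C1'", "C4'"))
  clashResi <- a$resi[sel]
  nc <- length(sel)
  excl <- matrix(FALSE, nc, nc)
  if (nc) excl <- abs(outer(clashResi, clashResi, `-`)) < 2
  list(conf = conf, resi = a$resi, bondFrom = bondFrom, bondTo = bondTo,
       ssIdx = ssIdx, restraints = restraints, resIdx = resIdx,
       clashSel = sel, clashExcl = excl)
}

energyFromXYZ <- function(xyz, st, terms) {
  e <- 0
  if (terms@conn > 0 && length(st$bondFrom)) {
    d <- sqrt(rowSums((xyz[st$bondTo, , drop = FALSE] -
                       xyz[st$bondFrom, , drop = FALSE])^2))
    e <- e + terms@conn * sum(flatViolation(d, BOND_FLAT[1], BOND_FLAT[2])^2)
  }
  if (terms@ss > 0 && !is.null(st$ssIdx)) {
    d1 <- sqrt(rowSums((xyz[st$ssIdx[, "c1j"], , drop = FALSE] -
                        xyz[st$ssIdx[, "c1i"], , drop = FALSE])^2))
    dn <- sqrt(rowSums((xyz[st$ssIdx[, "nnj"], , drop = FALSE] -
                        xyz[st$ssIdx[, "nni"], , drop = FALSE])^2))
    e <- e + terms@ss * (sum(flatViolation(d1, SS_C1_FLAT[1], SS_C1_FLAT[2])^2) +
                         sum(flatViolation(dn, SS_NN_FLAT[1], SS_NN_FLAT[2])^2))
  }
  if (terms@restraint > 0 && !is.null(st$resIdx)) {
    r <- st$restraints
    d1 <- sqrt(rowSums((xyz[st$resIdx[, "c1j"], , drop = FALSE] -
                        xyz[st$resIdx[, "c1i"], , drop = FALSE])^2))
    v <- flatViolation(d1, r$lower, r$upper)^2
    bp <- r$kind == "base_pair" & !is.na(st$resIdx[, "nni"])
    if (any(bp)) {
      dn <- sqrt(rowSums((xyz[st$resIdx[bp, "nnj"], , drop = FALSE] -
                          xyz[st$resIdx[bp, "nni"], , drop = FALSE])^2))
      v[bp] <- v[bp] + flatViolation(dn, BP_NN_BOUNDS[1], BP_NN_BOUNDS[2])^2
    }
    e <- e + terms@restraint * sum(r$weight * v)
  }
  if (terms@clash > 0 && length(st$clashSel)) {
    D <- as.matrix(stats::dist(xyz[st$clashSel, , drop = FALSE]))
    ov <- pmax(0, CLASH_RMIN - D)
    ov[st$clashExcl] <- 0
    e <- e + terms@clash * sum(ov^2) / 2
  }
  if (terms@stat > 0) {
    tmp <- st$conf
    tmp@atoms[, c("x", "y", "z")] <- xyz
    e <- e + terms@stat * scoreStructure(tmp)
  }
  e
}

#' Optimizer energy of a conformation
#'
#' Weighted sum of squared flat-bottom violations: junction-bond
#' connectivity, soft-sphere clashes on a reduced atom set, nested
#' secondary-structure pair maintenance, restraint violations, and
#' (optionally) the knowledge-based score.
#'
#' @param conf a \code{Conformation}
#' @param terms an \code{\link{optimizerEnergy}}
#' @param restraints restraint data.frame (or NULL)
#' @param ss the \code{SecondaryStructure} whose nested pairs to maintain
#' @return scalar energy
#' @export
conformationEnergy <- function(conf, terms = optimizerEnergy(),
                               restraints = NULL, ss = NULL) {
  st <- energyState(conf, restraints, ss)
  energyFromXYZ(as.matrix(conf@atoms[, c("x", "y", "z")]), st, terms)
}

#' Per-restraint bound violations
#'
#' Reports, for every restraint, how far its measured distances fall
#' outside the bounds (0 = satisfied); for base-pair restraints the worst
#' of the C1'-C1' and N-N components is reported.
#'
#' @param conf a \code{Conformation}
#' @param restraints restraint data.frame
#' @return numeric vector of violations (Angstrom)
#' @export
restraintViolations <- function(conf, restraints) {
  if (is.null(restraints) || !nrow(restraints)) return(numeric(0))
  st <- energyState(conf, restraints)
  xyz <- as.matrix(conf@atoms[, c("x", "y", "z")])
  d1 <- sqrt(rowSums((xyz[st$resIdx[, "c1j"], , drop = FALSE] -
                      xyz[st$resIdx[, "c1i"], , drop = FALSE])^2))
  v <- flatViolation(d1, restraints$lower, restraints$upper)
  bp <- restraints$kind == "base_pair" & !is.na(st$resIdx[, "nni"])
  if (any(bp)) {
    dn <- sqrt(rowSums((xyz[st$resIdx[bp, "nnj"], , drop = FALSE] -
                        xyz[st$resIdx[bp, "nni"], , drop = FALSE])^2))
    v[bp] <- pmax(v[bp], flatViolation(dn, BP_NN_BOUNDS[1], BP_NN_BOUNDS[2]))
  }
  v
}

## ----------------------------------------------------------------- sampler

#' Simulated-annealing Monte Carlo optimization
#'
#' At each step a uniformly random movable element receives a uniformly
#' random rigid move (translation, rotation about its centroid, or rotation
#' about its anchor axis) with temperature-scaled magnitude; the move is
#' accepted with probability min(1, exp(-dE/T)).  The temperature follows
#' the two-phase schedule: geometric heating from T_low to T_high, then
#' geometric cooling back.  One conformation per temperature rung is
#' recorded (capped at 1000 samples) and the best-energy conformation is
#' tracked.  Fully deterministic under a fixed seed.
#'
#' @param c0 starting \code{Conformation}
#' @param elements movable elements (data.frame from
#'   \code{\link{movableElements}})
#' @param restraints optional restraint data.frame
#' @param schedule an \code{\link{annealSchedule}}
#' @param terms an \code{\link{optimizerEnergy}}
#' @param seed RNG seed
#' @param ss optional \code{SecondaryStructure}; its nested pairs enter the
#'   maintenance term
#' @param translationSd,rotationSd move magnitudes at T = T_high
#'   (Angstrom / radians), scaled by sqrt(T / T_high)
#' @return list: \code{trajectory} (list of \code{Conformation}),
#'   \code{best}, \code{bestEnergy}, \code{energies} (per recorded sample),
#'   \code{acceptance} (overall ratio), \code{temperatures}
#' @export
samcOptimize <- function(c0, elements, restraints = NULL,
                         schedule = annealSchedule(), terms = optimizerEnergy(),
                         seed = 1, ss = NULL, translationSd = 2,
                         rotationSd = 15 * pi / 180) {
  if (is.null(elements) || !nrow(elements)) stop("nothing to move: empty element list")
  st <- energyState(c0, restraints, ss)
  xyz <- as.matrix(c0@atoms[, c("x", "y", "z")])
  resi <- st$resi
  n <- nResidues(c0)
  temps <- c(exp(seq(log(schedule@tLow), log(schedule@tHigh),
                     length.out = schedule@heatRungs)),
             exp(seq(log(schedule@tHigh), log(schedule@tLow),
                     length.out = schedule@coolRungs)))
  o3Row <- vapply(seq_len(n), function(r) {
    w <- which(c0@atoms$resi == r & c0@atoms$atom == "O3'")
    if (length(w)) w[1] else NA_integer_ }, integer(1))
  pRow <- vapply(seq_len(n), function(r) {
    w <- which(c0@atoms$resi == r & c0@atoms$atom == "P")
    if (length(w)) w[1] else NA_integer_ }, integer(1))
  asConf <- function(m) { cc <- c0; cc@atoms[, c("x", "y", "z")] <- m; cc }

  e <- energyFromXYZ(xyz, st, terms)
  bestXYZ <- xyz; bestE <- e
  trajectory <- list(asConf(xyz))
  energies <- e
  nAcc <- 0L; nProp <- 0L
  if (schedule@sweeps == 0)
    return(list(trajectory = trajectory, best = asConf(bestXYZ),
                bestEnergy = bestE, energies = energies,
                acceptance = NA_real_, temperatures = temps))

  withSeed(seed, {
    for (rung in seq_along(temps)) {
      Tt <- temps[rung]
      scale <- sqrt(Tt / schedule@tHigh)
      nProposals <- schedule@sweeps
      for (s in seq_len(nProposals) ) {
        el <- elements[sample.int(nrow(elements), 1), ]
        rows <- which(resi >= el$start & resi <= el$end)
        mtype <- sample.int(3, 1)
        sub <- xyz[rows, , drop = FALSE]
        moved <- if (mtype == 1) {
          sweep(sub, 2, stats::rnorm(3, sd = translationSd * scale), `+`)
        } else {
          theta <- stats::rnorm(1, sd = rotationSd * scale)
          if (mtype == 2) {
            p <- colMeans(sub); ax <- stats::rnorm(3)
          } else {
            prev <- if (el$start > 1 && !is.na(o3Row[el$start - 1]))
              xyz[o3Row[el$start - 1], ] else NULL
            nxt <- if (el$end < n && !is.na(pRow[el$end + 1]))
              xyz[pRow[el$end + 1], ] else NULL
            cen <- colMeans(sub)
            if (!is.null(prev) && !is.null(nxt)) { p <- prev; ax <- nxt - prev }
            else if (!is.null(prev)) { p <- prev; ax <- cen - prev }
            else if (!is.null(nxt)) { p <- nxt; ax <- cen - nxt }
            else { p <- cen; ax <- stats::rnorm(3) }
            if (vnorm(ax) < 1e-9) ax <- c(0, 0, 1)
          }
          R <- rotationMatrix(ax, theta)
          sweep(sweep(sub, 2, p) %*% t(R), 2, p, `+`)
        }
        cand <- xyz
        cand[rows, ] <- moved
        e2 <- energyFromXYZ(cand, st, terms)
        nProp <- nProp + 1L
        dE <- e2 - e
        if (dE <= 0 || stats::runif(1) < exp(-dE / Tt)) {
          xyz <- cand; e <- e2; nAcc <- nAcc + 1L
          if (e < bestE) { bestE <- e; bestXYZ <- xyz }
        }
      }
      if (length(trajectory) < 1000) {
        trajectory[[length(trajectory) + 1]] <- asConf(xyz)
        energies <- c(energies, e)
      }
    }
  })
  list(trajectory = trajectory, best = asConf(bestXYZ), bestEnergy = bestE,
       energies = energies, acceptance = if (nProp) nAcc / nProp else NA_real_,
       temperatures = temps)
}

#' Minimum-energy member of a trajectory
#'
#' @param trajectory list of \code{Conformation}
#' @param terms energy terms
#' @param restraints optional restraints
#' @param ss optional secondary structure for the maintenance term
#' @return the minimum-energy conformation (earliest on ties)
#' @export
bestOf <- function(trajectory, terms = optimizerEnergy(), restraints = NULL,
                   ss = NULL) {
  if (!length(trajectory)) stop("empty trajectory")
  e <- vapply(trajectory, conformationEnergy, numeric(1), terms = terms,
              restraints = restraints, ss = ss)
  trajectory[[which.min(e)]]
}
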
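# Conformation-level utilities: continuity, clashes, strand walking,
# random perturbation.

#' Covalent chain continuity of a conformation
#'
#' Measures every consecutive O3'(i)-P(i+1) distance (skipping declared
#' chain breaks) and reports which fall outside the accepted bond window.
#'
#' @param conf a \code{Conformation}
#' @param bounds acceptance window in Angstrom
#' @return data.frame with columns resi, dist, ok
#' @export
chainContinuity <- function(conf, bounds = BOND_O3P_BOUNDS) {
  n <- nResidues(conf)
  res <- list()
  for (i in seq_len(max(0, n - 1))) {
    if (i %in% conf@breaks) next
    o3 <- atomCoords(conf, i, "O3'")
    p  <- atomCoords(conf, i + 1, "P")
    if (!nrow(o3) || !nrow(p)) next
    d <- vnorm(p[1, ] - o3[1, ])
    res[[length(res) + 1]] <- data.frame(resi = i, dist = d,
                                         ok = d >= bounds[1] & d <= bounds[2])
  }
  if (!length(res))
    return(data.frame(resi = integer(0), dist = numeric(0), ok = logical(0)))
  do.call(rbind, res)
}

#' @describeIn chainContinuity TRUE when every inter-residue bond is inside
#'   the window
#' @export
isContinuous <- function(conf, bounds = BOND_O3P_BOUNDS) {
  cc <- chainContinuity(conf, bounds)
  all(cc$ok)
}

#' Count steric clashes
#'
#' Number of atom pairs from different residues closer than \code{cutoff},
#' excluding the covalent O3'-P bond between consecutive residues.
#'
#' @param conf a \code{Conformation}
#' @param cutoff clash distance in Angstrom
#' @return integer clash count
#' @export
clashCount <- function(conf, cutoff = 2.2) {
  a <- conf@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(xyz))
  close <- which(D < cutoff & upper.tri(D), arr.ind = TRUE)
  if (!nrow(close)) return(0L)
  ri <- a$resi[close[, 1]]; rj <- a$resi[close[, 2]]
  ai <- a$atom[close[, 1]]; aj <- a$atom[close[, 2]]
  bad <- ri != rj &
    !((ri == rj - 1 & ai == "O3'" & aj == "P") |
      (rj == ri - 1 & aj == "O3'" & ai == "P"))
  sum(bad)
}

## ----------------------------------------------------------- strand walker

# Grow a single-stranded chain residue by residue.  Residue i+1 is placed by
# the ideal helical step and then reoriented by a rotation about its own
# phosphate, which preserves the O3'(i)-P(i+1) bond length exactly while
# allowing arbitrary chain curvature.  `bend` returns, per step, a list
# (axis, theta) or NULL for a straight helical continuation.
walkStrand <- function(sequence, startTransform = NULL, bend = NULL) {
  s <- splitSeq(sequence)
  Tcur <- startTransform %||% list(rotation = diag(3), translation = c(0, 0, 0))
  step <- list(rotation = matrix(c(cos(.HELIX_TWIST), sin(.HELIX_TWIST), 0,
                                   -sin(.HELIX_TWIST), cos(.HELIX_TWIST), 0,
                                   0, 0, 1), 3, 3),
               translation = c(0, 0, .HELIX_RISE))
  atoms <- vector("list", length(s))
  for (i in seq_along(s)) {
    if (i > 1) {
      Tcur <- composeTransforms(Tcur, step)
      if (!is.null(bend)) {
        b <- bend(i)
        if (!is.null(b)) {
          pPos <- applyTransform(matrix(.SUGAR_XYZ["P", ], 1, 3), Tcur)[1, ]
          R <- rotationMatrix(b$axis, b$theta)
          # rotate the residue frame about its own phosphate
          Tcur <- list(rotation = R %*% Tcur$rotation,
                       translation = as.vector(R %*% (Tcur$translation - pPos)) + pPos)
        }
      }
    }
    xyz <- applyTransform(refNucleotide(s[i]), Tcur)
    rownames(xyz) <- rownames(refNucleotide(s[i]))
    atoms[[i]] <- residueAtoms(i, xyz)
  }
  list(atoms = do.call(rbind, atoms), transform = Tcur)
}

# compose: apply a then b?  Here: result(x) = a(b(x)) would be wrong; we want
# the frame reached by applying `step` within the current frame:
# result(x) = cur(step(x))
composeTransforms <- function(cur, step) {
  list(rotation = cur$rotation %*% step$rotation,
       translation = as.vector(cur$rotation %*% step$translation) + cur$translation)
}

## ------------------------------------------------------------ perturbation

#' Randomly perturb a conformation by rigid element moves
#'
#' Applies \code{nMoves} random rigid moves (translation, rotation about the
#' element centroid, rotation about the anchor axis) to randomly chosen
#' movable elements.  Used to generate decoys and optimizer test starts.
#'
#' @param conf a \code{Conformation}
#' @param elements movable-element data.frame from
#'   \code{\link{movableElements}}
#' @param nMoves number of moves
#' @param translationSd,rotationSd move magnitudes (Angstrom / radians)
#' @param seed RNG seed
#' @return perturbed \code{Conformation}
#' @export
perturbConformation <- function(conf, elements, nMoves = 5,
                                translationSd = 4, rotationSd = 0.6,
                                seed = 1) {
  withSeed(seed, {
    for (m in seq_len(nMoves)) {
      e <- elements[sample.int(nrow(elements), 1), ]
      span <- c(e$start, e$end)
      type <- sample(c("translate", "rotatePoint", "rotateAxis"), 1)
      move <- switch(type,
        translate = translationMove(stats::rnorm(3, sd = translationSd)),
        rotatePoint = {
          cen <- colMeans(atomCoords(conf, span[1]:span[2]))
          pointRotationMove(cen, stats::rnorm(3), stats::rnorm(1, sd = rotationSd))
        },
        rotateAxis = axisRotationMove(stats::rnorm(1, sd = rotationSd)))
      conf <- applyMove(conf, span, move)
    }
    conf
  })
}
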
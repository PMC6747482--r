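# Synthetic data generators: fragment source, full fixture structures, and
# the pseudoknot study system used for optimizer validation.

#' Synthetic fragment-source structure
#'
#' A seeded single-stranded conformation with varied curvature (helical
#' steps reoriented by random rotations about each new phosphate, which
#' keeps the chain exactly continuous).  Its consecutive residue pairs
#' provide the bi-residue fragment pool; a real structure (e.g. a 5S rRNA
#' coordinate file read with \code{\link{readPDB}}) can be used instead.
#'
#' @param seed RNG seed
#' @param n number of residues
#' @return a \code{Conformation}
#' @export
fragmentSource <- function(seed = 1, n = 48) {
  withSeed(seed, {
    bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
    # segments of constant curvature: within each ~6-residue segment the
    # bend axis is fixed and the per-step bend angle constant (0 = straight
    # helical continuation, up to ~50 degrees = sharp turn), so consecutive
    # fragments chain into coherent arcs of many curvatures
    nseg <- ceiling(n / 6)
    segAxis <- matrix(stats::rnorm(3 * nseg), nseg, 3)
    segTheta <- stats::runif(nseg, 0, 1.35)
    segOf <- rep(seq_len(nseg), each = 6, length.out = n)
    jitter <- stats::rnorm(n, sd = 0.06)
    step <- list(rotation = rotationMatrix(c(0, 0, 1), .HELIX_TWIST),
                 translation = c(0, 0, .HELIX_RISE))
    Tcur <- identityTransform()
    atoms <- vector("list", n)
    place <- function(Tt, base) {
      ref <- refNucleotide(base)
      xyz <- applyTransform(ref, Tt)
      rownames(xyz) <- rownames(ref)
      xyz
    }
    atoms[[1]] <- residueAtoms(1, place(Tcur, bases[1]))
    prevXYZ <- place(Tcur, bases[1])
    for (i in 2:n) {
      base <- composeTransforms(Tcur, step)
      # shrink the bend if the new residue would collide with its
      # predecessor (the O3'-P bonded atoms excepted)
      for (try in 1:25) {
        shrink <- 1 - (try - 1) / 25
        theta <- segTheta[segOf[i]] * shrink + jitter[i]
        pPos <- applyTransform(matrix(.SUGAR_XYZ["P", ], 1, 3), base)[1, ]
        R <- rotationMatrix(segAxis[segOf[i], ], theta)
        Tcand <- list(rotation = R %*% base$rotation,
                      translation = as.vector(R %*% (base$translation - pPos)) + pPos)
        xyz <- place(Tcand, bases[i])
        D <- sqrt(outer(rowSums(xyz^2), rowSums(prevXYZ^2), `+`) -
                    2 * xyz %*% t(prevXYZ))
        D[rownames(xyz) == "P", rownames(prevXYZ) == "O3'"] <- Inf
        if (min(D) > 2.3) break
      }
      Tcur <- Tcand
      prevXYZ <- xyz
      atoms[[i]] <- residueAtoms(i, xyz)
    }
    Conformation(bases, do.call(rbind, atoms),
                 provenance = list(sourceId = "synthetic:fragsource"))
  })
}

#' Build a complete synthetic structure for a secondary structure
#'
#' Assembles the top-ranked model from a seeded synthetic fixture library
#' (ideal helices + generated loops).  This is the ground-truth generator
#' used by the round-trip and optimizer tests.
#'
#' @param sequence RNA sequence
#' @param db dot-bracket string (nested; pseudoknot brackets are ignored
#'   here and handled by the optimizer as restraints)
#' @param seed RNG seed
#' @param relax if TRUE run the geometric relaxation on the result
#' @return a \code{Conformation}
#' @export
buildFixtureStructure <- function(sequence, db, seed = 1, relax = FALSE) {
  ss <- parseDotBracket(db, sequence)
  lib <- buildFixtureLibrary(ss, seed = seed)
  conf <- assembleTop(ss, lib, predictionConfig(nPredictions = 1, seed = seed))[[1]]
  if (relax) conf <- relaxConformation(conf, pairs = ss@pairs)
  conf
}

#' The 28-nt pseudoknot study system
#'
#' A synthetic hairpin-type (H-type) pseudoknot: a 6-bp hairpin whose loop
#' pairs three bases with the 3' tail.  The ground truth is built by
#' assembling the nested structure from fixtures and then optimising it
#' under the pseudoknot base-pair restraints with a long annealing schedule
#' (fixed internal seed), so the returned reference satisfies every
#' restraint.  Used to measure the effect of treating pseudoknot pairs as
#' restraints.
#'
#' @param seed RNG seed for the fixture library and assembly
#' @return list with \code{ss} (the \code{SecondaryStructure}),
#'   \code{restraints} (from \code{\link{restraintsFromPseudoknot}}),
#'   \code{assembled} (the nested-only assembly), \code{groundTruth}
#'   (restraint-satisfying reference), \code{elements} (movable elements)
#' @export
buildPseudoknotFixture <- function(seed = 1) {
  sequence <- "GGCAGCAAGCGAAAGCUGCCAAAACGCA"
  db       <- "((((((..[[[...))))))....]]]."
  ss <- parseDotBracket(db, sequence)
  lib <- buildFixtureLibrary(ss, seed = seed)
  assembled <- assembleTop(ss, lib, predictionConfig(nPredictions = 1,
                                                     seed = seed))[[1]]
  restraints <- restraintsFromPseudoknot(ss@pkPairs)
  elements <- movableElements(ss)
  opt <- samcOptimize(assembled, elements, restraints = restraints,
                      seed = seed + 7919, ss = ss)
  list(ss = ss, restraints = restraints, assembled = assembled,
       groundTruth = opt$best, elements = elements)
}
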
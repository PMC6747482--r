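#' @import methods
NULL

setOldClass("data.frame")

## ---------------------------------------------------------------- secstruct

#' Secondary structure of an RNA
#'
#' Holds the sequence, the nested (crossing-free) base pairs and the
#' pseudoknot pairs (pairs that cross the nested set).  Pairs are stored as a
#' two-column integer matrix of 1-based residue indices with \code{i < j}.
#'
#' @slot sequence single string over A, C, G, U
#' @slot pairs two-column integer matrix of nested pairs
#' @slot pkPairs two-column integer matrix of pseudoknot pairs
#' @export
setClass("SecondaryStructure",
  representation(sequence = "character", pairs = "matrix", pkPairs = "matrix"))

setValidity("SecondaryStructure", function(object) {
  n <- nchar(object@sequence)
  msg <- character(0)
  if (length(object@sequence) != 1) msg <- c(msg, "sequence must be a single string")
  if (!grepl("^[ACGU]*$", object@sequence)) msg <- c(msg, "sequence must be over {A,C,G,U}")
  allp <- rbind(object@pairs, object@pkPairs)
  if (nrow(allp)) {
    if (any(allp < 1) || any(allp > n)) msg <- c(msg, "pair index out of range")
    idx <- as.vector(allp)
    if (anyDuplicated(idx)) msg <- c(msg, "a residue appears in more than one pair")
  }
  if (anyCrossing(object@pairs)) msg <- c(msg, "nested pairs must be crossing-free")
  if (length(msg)) msg else TRUE
})

#' @describeIn SecondaryStructure construct from sequence and pair matrices
#' @param sequence RNA sequence string
#' @param pairs nested pairs (two-column matrix, 1-based)
#' @param pkPairs pseudoknot pairs
#' @export
SecondaryStructure <- function(sequence, pairs = NULL, pkPairs = NULL) {
  new("SecondaryStructure",
      sequence = toupper(gsub("T", "U", sequence)),
      pairs = canonicalPairs(pairs), pkPairs = canonicalPairs(pkPairs))
}

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure: %d nt, %d nested pairs, %d pseudoknot pairs\n",
              nchar(object@sequence), nrow(object@pairs), nrow(object@pkPairs)))
  cat(" ", object@sequence, "\n ", dotBracket(object), "\n")
})

## ------------------------------------------------------------------ SSENode

#' Node of the SSE tree
#'
#' A smallest secondary element: a stem or a loop (hairpin, bulge, internal,
#' junction, exterior) with its closing base pairs and children.  Loop nodes
#' carry up to two closing pairs per connected helix end so that successive
#' templates can be assembled by overlapping the shared pairs.
#'
#' @slot kind one of stem, hairpin, bulge, internal, junction, exterior, chain
#' @slot residues integer residue indices covered by this element
#' @slot strands list of integer vectors, the element's strands 5'->3'
#' @slot closingPairs two-column matrix of closing base pairs
#' @slot children list of child \code{SSENode}s, 5'->3'
#' @export
setClass("SSENode",
  representation(kind = "character", residues = "integer", strands = "list",
                 closingPairs = "matrix", children = "list"))

setValidity("SSENode", function(object) {
  ok <- object@kind %in% c("stem", "hairpin", "bulge", "internal", "junction",
                           "exterior", "chain")
  if (!ok) return(sprintf("unknown SSE kind '%s'", object@kind))
  if (!setequal(unlist(object@strands), object@residues))
    return("strands must cover exactly the node residues")
  TRUE
})

#' @describeIn SSENode construct a node
#' @param kind,residues,strands,closingPairs,children see slots
#' @export
SSENode <- function(kind, residues, strands, closingPairs = NULL, children = list()) {
  new("SSENode", kind = kind, residues = as.integer(residues),
      strands = lapply(strands, as.integer),
      closingPairs = canonicalPairs(closingPairs), children = children)
}

setMethod("show", "SSENode", function(object) {
  cat(sseTreeFormat(object), sep = "\n")
})

## ------------------------------------------------------------- Conformation

#' All-atom model of an RNA chain
#'
#' Per-residue atom records in a reduced heavy-atom representation (sugar and
#' phosphate backbone plus base ring atoms).  Consecutive residues are
#' covalently continuous (O3'-P within bond bounds) unless listed in
#' \code{breaks}.
#'
#' @slot sequence character vector of one-letter bases, one per residue
#' @slot atoms data.frame with columns resi, atom, x, y, z
#' @slot chain single chain identifier
#' @slot breaks integer indices of residues not bonded to their successor
#' @slot provenance free-form list (template choices, seeds, ...)
#' @export
setClass("Conformation",
  representation(sequence = "character", atoms = "data.frame",
                 chain = "character", breaks = "integer", provenance = "list"))

setValidity("Conformation", function(object) {
  msg <- character(0)
  need <- c("resi", "atom", "x", "y", "z")
  if (!all(need %in% names(object@atoms))) {
    msg <- c(msg, "atoms must have columns resi, atom, x, y, z")
  } else {
    if (nrow(object@atoms) && max(object@atoms$resi) > length(object@sequence))
      msg <- c(msg, "atom resi exceeds residue count")
    if (!all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
      msg <- c(msg, "coordinates must be finite")
  }
  if (!all(object@sequence %in% c("A", "C", "G", "U")))
    msg <- c(msg, "sequence must be over {A,C,G,U}")
  if (length(msg)) msg else TRUE
})

#' @describeIn Conformation construct from a sequence and an atom table
#' @param sequence,atoms,chain,breaks,provenance see slots
#' @export
Conformation <- function(sequence, atoms, chain = "A", breaks = integer(0),
                         provenance = list()) {
  atoms <- as.data.frame(atoms)
  atoms$resi <- as.integer(atoms$resi)
  rownames(atoms) <- NULL
  new("Conformation", sequence = splitSeq(sequence), atoms = atoms,
      chain = chain, breaks = as.integer(breaks), provenance = provenance)
}

setMethod("show", "Conformation", function(object) {
  cat(sprintf("Conformation: %d residues, %d atoms, chain %s\n",
              length(object@sequence), nrow(object@atoms), object@chain))
  if (length(object@breaks))
    cat("  chain breaks after residues:", paste(object@breaks, collapse = ", "), "\n")
})

#' @describeIn Conformation number of residues
#' @param x a Conformation
#' @export
nResidues <- function(x) length(x@sequence)

#' Coordinate matrix of a conformation
#'
#' @param x a \code{Conformation}
#' @param residues optional residue indices to restrict to
#' @param atomNames optional atom-name filter (e.g. \code{"C1'"})
#' @return numeric matrix with one row per atom and rownames
#'   \code{"<resi>:<atom>"}
#' @export
atomCoords <- function(x, residues = NULL, atomNames = NULL) {
  a <- x@atoms
  if (!is.null(residues)) a <- a[a$resi %in% residues, , drop = FALSE]
  if (!is.null(atomNames)) a <- a[a$atom %in% atomNames, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- paste0(a$resi, ":", a$atom)
  m
}

## ----------------------------------------------------------------- Template

#' An SSE-shaped 3D fragment
#'
#' A template is the 3D coordinate fragment of one SSE, with its per-strand
#' sequences and the identifier of the structure it was harvested from.  Loop
#' templates include the residues of their closing base pairs (up to two per
#' helix end) so neighbouring templates can be superposed on the shared pairs.
#' Local residue numbering is 1..m in the order of the flattened strands.
#'
#' @slot kind SSE kind
#' @slot strandSeqs per-strand sequences (closing residues included)
#' @slot sequence character vector, one base per local residue
#' @slot atoms data.frame resi/atom/x/y/z with local residue numbers
#' @slot closingLocal two-column matrix of closing pairs in local numbering
#' @slot sourceId origin structure identifier, or "synthetic"
#' @export
setClass("Template",
  representation(kind = "character", strandSeqs = "character",
                 sequence = "character", atoms = "data.frame",
                 closingLocal = "matrix", sourceId = "character"))

setValidity("Template", function(object) {
  if (nchar(paste(object@strandSeqs, collapse = "")) != length(object@sequence))
    return("strand sequences must concatenate to the residue sequence")
  TRUE
})

#' @describeIn Template construct from strand sequences and an atom table
#' @param kind,strandSeqs,atoms,closingLocal,sourceId see slots
#' @export
Template <- function(kind, strandSeqs, atoms, closingLocal = NULL,
                     sourceId = "synthetic") {
  atoms <- as.data.frame(atoms)
  atoms$resi <- as.integer(atoms$resi)
  rownames(atoms) <- NULL
  new("Template", kind = kind, strandSeqs = strandSeqs,
      sequence = splitSeq(paste(strandSeqs, collapse = "")), atoms = atoms,
      closingLocal = canonicalPairs(closingLocal), sourceId = sourceId)
}

setMethod("show", "Template", function(object) {
  cat(sprintf("Template [%s] %s  strands: %s  source: %s\n", object@kind,
              shapeKeyOf(object), paste(object@strandSeqs, collapse = "/"),
              object@sourceId))
})

## ---------------------------------------------------------- TemplateLibrary

#' Indexed collection of SSE templates
#'
#' Two conceptual sub-libraries (helices and loops) share one index keyed by
#' the exact shape of the element: kind plus per-strand residue counts.
#'
#' @slot entries list of \code{Template}
#' @slot keys character vector of shape keys, parallel to \code{entries}
#' @export
setClass("TemplateLibrary",
  representation(entries = "list", keys = "character"))

#' @describeIn TemplateLibrary construct from a list of templates
#' @param entries list of \code{Template}
#' @export
TemplateLibrary <- function(entries = list()) {
  keys <- vapply(entries, shapeKeyOf, character(1))
  new("TemplateLibrary", entries = entries, keys = as.character(keys))
}

setMethod("show", "TemplateLibrary", function(object) {
  nh <- sum(grepl("^stem:", object@keys))
  cat(sprintf("TemplateLibrary: %d templates (%d helices, %d loops), %d shapes\n",
              length(object@entries), nh, length(object@entries) - nh,
              length(unique(object@keys))))
})

#' @describeIn TemplateLibrary number of stored templates
#' @param x a TemplateLibrary
#' @export
nTemplates <- function(x) length(x@entries)

## ------------------------------------------------------- parameter objects

#' Prediction configuration
#'
#' @slot nPredictions number of final predictions N (default 5)
#' @slot samplingSteps template sampling steps (default 500)
#' @slot seed RNG seed
#' @slot excludeIds template source ids to exclude
#' @slot refine run the geometric relaxation on assembled models
#' @export
setClass("PredictionConfig",
  representation(nPredictions = "numeric", samplingSteps = "numeric",
                 seed = "numeric", excludeIds = "character", refine = "logical"))

setValidity("PredictionConfig", function(object) {
  if (object@nPredictions < 1) return("nPredictions must be >= 1")
  if (object@samplingSteps < 0) return("samplingSteps must be >= 0")
  TRUE
})

#' @describeIn PredictionConfig constructor with pipeline defaults
#' @param nPredictions,samplingSteps,seed,excludeIds,refine see slots
#' @export
predictionConfig <- function(nPredictions = 5, samplingSteps = 500, seed = 1,
                             excludeIds = character(0), refine = FALSE) {
  new("PredictionConfig", nPredictions = nPredictions,
      samplingSteps = samplingSteps, seed = seed,
      excludeIds = excludeIds, refine = refine)
}

#' Simulated-annealing schedule
#'
#' Two phases: heat from \code{tLow} to \code{tHigh}, then cool back down.
#' Temperatures are geometric rungs; at each rung \code{sweeps} Monte Carlo
#' sweeps are run (one proposed move per movable element per sweep).
#'
#' @slot tLow,tHigh temperature bounds (dimensionless energy units)
#' @slot heatRungs,coolRungs number of temperature rungs per phase
#' @slot sweeps sweeps per rung
#' @export
setClass("AnnealSchedule",
  representation(tLow = "numeric", tHigh = "numeric", heatRungs = "numeric",
                 coolRungs = "numeric", sweeps = "numeric"))

setValidity("AnnealSchedule", function(object) {
  if (object@tLow >= object@tHigh) return("tLow must be < tHigh")
  if (object@heatRungs < 1 || object@coolRungs < 1)
    return("rung counts must be >= 1")
  if (object@sweeps < 0) return("sweeps must be >= 0")
  TRUE
})

#' @describeIn AnnealSchedule constructor; defaults give a T_high/T_low
#'   ratio of 100, 10 heating rungs, and a longer cooling phase (25 rungs)
#'   so junction bonds stretched at high temperature anneal back into their
#'   windows
#' @param tLow,tHigh,heatRungs,coolRungs,sweeps see slots
#' @export
annealSchedule <- function(tLow = 0.02, tHigh = 2, heatRungs = 10,
                           coolRungs = 25, sweeps = 150) {
  new("AnnealSchedule", tLow = tLow, tHigh = tHigh, heatRungs = heatRungs,
      coolRungs = coolRungs, sweeps = sweeps)
}

#' Energy term weights for the optimizer
#'
#' @slot conn weight of squared O3'-P junction-bond violations
#' @slot clash weight of squared soft-sphere overlaps
#' @slot ss weight of squared nested base-pair deviations
#' @slot restraint global multiplier on restraint violations
#' @slot stat weight of the knowledge-based score (0 = off)
#' @export
setClass("OptimizerEnergy",
  representation(conn = "numeric", clash = "numeric", ss = "numeric",
                 restraint = "numeric", stat = "numeric"))

setValidity("OptimizerEnergy", function(object) {
  w <- c(object@conn, object@clash, object@ss, object@restraint, object@stat)
  if (any(w < 0)) return("all weights must be >= 0")
  TRUE
})

#' @describeIn OptimizerEnergy constructor with default weights
#' @param conn,clash,ss,restraint,stat see slots
#' @export
optimizerEnergy <- function(conn = 10, clash = 1, ss = 5, restraint = 10, stat = 0) {
  new("OptimizerEnergy", conn = conn, clash = clash, ss = ss,
      restraint = restraint, stat = stat)
}

## ----------------------------------------------------------------- analysis

#' Result of RMSD k-medoid clustering
#'
#' The centroid of each cluster is the member with the smallest sum of RMSD
#' distances to all other members of its cluster.
#'
#' @slot assignment integer cluster label per conformation
#' @slot centroids integer conformation index per cluster
#' @slot distMatrix pairwise RMSD matrix (Angstrom)
#' @slot sizes cluster sizes
#' @export
setClass("ClusterSet",
  representation(assignment = "integer", centroids = "integer",
                 distMatrix = "matrix", sizes = "integer"))

setValidity("ClusterSet", function(object) {
  k <- length(object@centroids)
  if (!all(object@assignment %in% seq_len(k)))
    return("assignments must reference existing clusters")
  if (!all(tabulate(object@assignment, k) == object@sizes))
    return("sizes inconsistent with assignment")
  TRUE
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d conformations in %d clusters (sizes %s)\n",
              length(object@assignment), length(object@centroids),
              paste(object@sizes, collapse = ", ")))
})

#' Annotated base interactions of a 3D model
#'
#' @slot wcPairs two-column matrix of canonical (incl. G-U) pairs
#' @slot stacks two-column matrix of stacked residue pairs
#' @export
setClass("BaseInteractions",
  representation(wcPairs = "matrix", stacks = "matrix"))

#' @describeIn BaseInteractions construct from pair matrices
#' @param wcPairs,stacks two-column residue-pair matrices
#' @export
BaseInteractions <- function(wcPairs = NULL, stacks = NULL) {
  new("BaseInteractions", wcPairs = canonicalPairs(wcPairs),
      stacks = canonicalPairs(stacks))
}

setMethod("show", "BaseInteractions", function(object) {
  cat(sprintf("BaseInteractions: %d WC pairs, %d stacks\n",
              nrow(object@wcPairs), nrow(object@stacks)))
})
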
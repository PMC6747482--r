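# Reference nucleotide geometry and the ideal-helix fixture generator.

# proper rotation taking a strand-1 nucleotide to its strand-2 pairing site
.STRAND2_FLIP <- diag(c(-1, 1, -1))

# helical step operator: rotate by twist about z, advance by rise
helixStepXYZ <- function(xyz, k = 1) {
  if (k == 0) return(xyz)
  th <- .HELIX_TWIST * k
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  sweep(as.matrix(xyz) %*% t(R), 2, c(0, 0, .HELIX_RISE * k), `+`)
}

#' Reference nucleotide coordinates
#'
#' Returns the atoms of one nucleotide of the given base in the package's
#' idealized base-pair frame (5' strand site): sugar + phosphate backbone
#' plus the base ring.  See \code{R/nucgeom-data.R} for how the geometry is
#' derived.
#'
#' @param base one of "A", "C", "G", "U"
#' @return numeric matrix, one row per atom, rownames = atom names
#' @export
refNucleotide <- function(base) {
  ring <- if (isPurine(base)) .PURINE_XYZ else .PYRIMIDINE_XYZ
  rbind(.SUGAR_XYZ, ring)
}

# atoms data.frame for one residue given a placed coordinate matrix
residueAtoms <- function(resi, xyz) {
  data.frame(resi = as.integer(resi), atom = rownames(xyz),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build an ideal A-form helix template
#'
#' Constructs a double helix from the package's idealized nucleotide
#' geometry by successive helical steps (twist 32.7 degrees, rise 2.81 A).
#' Strand 1 pairs antiparallel with strand 2; base k of \code{sequence}
#' pairs base L+1-k of \code{pairSequence}.
#'
#' @param sequence 5'->3' sequence of strand 1
#' @param pairSequence 5'->3' sequence of strand 2 (complementary,
#'   Watson-Crick or G-U wobble)
#' @param sourceId source identifier recorded on the template
#' @return a \code{\link{Template}} of kind "stem"
#' @export
buildIdealHelix <- function(sequence, pairSequence, sourceId = "synthetic") {
  s1 <- splitSeq(sequence); s2 <- splitSeq(pairSequence)
  if (!length(s1)) stop("empty sequence")
  if (length(s1) != length(s2)) stop("strands must have equal length")
  L <- length(s1)
  partner <- rev(s2)                       # partner[k] pairs s1[k]
  ok <- isComplementary(s1, partner)
  if (any(!ok))
    stop("strands not complementary at pair position ", which(!ok)[1],
         " (", s1[which(!ok)[1]], " vs ", partner[which(!ok)[1]], ")")
  atoms <- vector("list", 2 * L)
  for (k in seq_len(L))
    atoms[[k]] <- residueAtoms(k, helixStepXYZ(refNucleotide(s1[k]), k - 1))
  for (m in seq_len(L)) {
    rung <- L + 1 - m                      # strand-2 residue m sits at rung L+1-m
    xyz <- helixStepXYZ(refNucleotide(s2[m]) %*% t(.STRAND2_FLIP), rung - 1)
    atoms[[L + m]] <- residueAtoms(L + m, xyz)
  }
  closing <- cbind(seq_len(L), 2 * L + 1 - seq_len(L))
  Template("stem", c(paste(s1, collapse = ""), paste(s2, collapse = "")),
           do.call(rbind, atoms), closingLocal = closing, sourceId = sourceId)
}

#' Conformation view of a template
#'
#' Presents a template's coordinate fragment as a standalone
#' \code{\link{Conformation}} (local residue numbering, chain breaks between
#' strands).
#'
#' @param tmpl a \code{Template}
#' @return a \code{Conformation}
#' @export
templateAsConformation <- function(tmpl) {
  lens <- nchar(tmpl@strandSeqs)
  breaks <- cumsum(lens)
  breaks <- breaks[-length(breaks)]
  Conformation(tmpl@sequence, tmpl@atoms, breaks = breaks,
               provenance = list(sourceId = tmpl@sourceId))
}
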
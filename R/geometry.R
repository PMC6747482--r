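# Rigid-body mathematics: Kabsch superposition, RMSD, rigid moves.

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' \code{mobile} onto \code{target}, via SVD of the covariance matrix with
#' the usual sign correction of the smallest singular vector so that
#' \code{det(rotation) = +1} (no reflections).
#'
#' Degenerate inputs are handled explicitly: fewer than 3 atoms, or
#' (near-)collinear sets, fall back to a translation-only fit and the result
#' carries \code{degenerate = TRUE}.
#'
#' @param mobile,target numeric n x 3 matrices with matching row order; if
#'   both have rownames they must agree
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3),
#'   \code{rmsd} (Angstrom) and \code{degenerate} flag.  The fitted
#'   coordinates are \code{mobile \%*\% t(rotation) + translation}.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch(a, a)
#' fit$rmsd  # 0
#' @export
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target))
    stop("kabsch: atom counts differ (", nrow(mobile), " vs ", nrow(target), ")")
  if (!is.null(rownames(mobile)) && !is.null(rownames(target)) &&
      !identical(rownames(mobile), rownames(target))) {
    bad <- which(rownames(mobile) != rownames(target))[1]
    stop("kabsch: atom labels mismatch at position ", bad, ": '",
         rownames(mobile)[bad], "' vs '", rownames(target)[bad], "'")
  }
  n <- nrow(mobile)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  degenerate <- FALSE
  if (n < 3) {
    R <- diag(3)
    degenerate <- TRUE
  } else {
    H <- t(A) %*% B
    sv <- svd(H)
    # collinear/degenerate: rank < 2 leaves a rotation axis unconstrained
    if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-30)) degenerate <- TRUE
    d <- sign(det(sv$v %*% t(sv$u)))
    if (d == 0) d <- 1
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  tr <- ct - as.vector(R %*% cm)
  fitted <- A %*% t(R)
  rmsd <- sqrt(sum((fitted - B)^2) / n)
  list(rotation = R, translation = tr, rmsd = rmsd, degenerate = degenerate)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix
#' @param transform list with \code{rotation} and \code{translation} as
#'   returned by \code{\link{kabsch}}
#' @return transformed n x 3 matrix
#' @export
applyTransform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Root-mean-square deviation between matched coordinate sets
#'
#' @param a,b n x 3 matrices with matching rows (labels checked when both
#'   are rownamed)
#' @param superpose if TRUE (default) return the Kabsch-minimised RMSD,
#'   otherwise the raw coordinate RMSD
#' @return RMSD in Angstrom
#' @export
rmsd <- function(a, b, superpose = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (superpose) return(kabsch(a, b)$rmsd)
  if (nrow(a) != nrow(b)) stop("rmsd: atom counts differ")
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b))) {
    bad <- which(rownames(a) != rownames(b))[1]
    stop("rmsd: atom labels mismatch at position ", bad, ": '",
         rownames(a)[bad], "' vs '", rownames(b)[bad], "'")
  }
  sqrt(sum((a - b)^2) / nrow(a))
}

## ----------------------------------------------------------------- moves

#' Rigid move constructors
#'
#' Build move descriptors for \code{\link{applyMove}}: a translation by
#' vector \code{v}; a rotation by \code{theta} about an axis through a point;
#' or a rotation about the axis through the moved element's anchor atoms (the
#' backbone attachment points), computed at application time.
#'
#' @param v translation vector (Angstrom)
#' @param point,axis rotation point and axis direction
#' @param theta rotation angle (radians)
#' @return a move descriptor list
#' @export
translationMove <- function(v) list(type = "translate", v = as.numeric(v))

#' @rdname translationMove
#' @export
pointRotationMove <- function(point, axis, theta)
  list(type = "rotatePoint", point = as.numeric(point),
       axis = as.numeric(axis), theta = theta)

#' @rdname translationMove
#' @export
axisRotationMove <- function(theta)
  list(type = "rotateAxis", theta = theta)

# anchor atoms of a residue span: O3' of the preceding residue and P of the
# following residue (whichever exist)
spanAnchors <- function(conf, span) {
  out <- list()
  if (span[1] > 1)
    out$prev <- as.vector(atomCoords(conf, span[1] - 1, "O3'"))
  if (span[2] < nResidues(conf))
    out$nxt <- as.vector(atomCoords(conf, span[2] + 1, "P"))
  out
}

#' Apply a rigid move to a residue span of a conformation
#'
#' Only atoms of residues in \code{span} move; the motion is rigid, so all
#' intra-span distances are preserved.  For \code{axisRotationMove} the axis
#' runs through the two anchor atoms for an internal element; for a chain-end
#' element it runs through the single anchor and the element centroid.
#'
#' @param conf a \code{Conformation}
#' @param span length-2 integer vector, first and last residue of the element
#' @param move a move descriptor (see \code{\link{translationMove}})
#' @return the moved \code{Conformation}
#' @export
applyMove <- function(conf, span, move) {
  span <- as.integer(span)
  if (span[1] < 1 || span[2] > nResidues(conf) || span[1] > span[2])
    stop("applyMove: span out of range")
  sel <- conf@atoms$resi >= span[1] & conf@atoms$resi <= span[2]
  xyz <- as.matrix(conf@atoms[sel, c("x", "y", "z")])
  moved <- switch(move$type,
    translate = sweep(xyz, 2, move$v, `+`),
    rotatePoint = {
      R <- rotationMatrix(move$axis, move$theta)
      sweep(sweep(xyz, 2, move$point) %*% t(R), 2, move$point, `+`)
    },
    rotateAxis = {
      anch <- spanAnchors(conf, span)
      cen <- colMeans(xyz)
      if (length(anch) == 2) {
        p <- anch$prev; ax <- anch$nxt - anch$prev
      } else if (length(anch) == 1) {
        p <- anch[[1]]; ax <- cen - anch[[1]]
      } else {                       # whole molecule: axis through centroid
        p <- cen; ax <- c(0, 0, 1)
      }
      if (vnorm(ax) < 1e-9) ax <- c(0, 0, 1)
      R <- rotationMatrix(ax, move$theta)
      sweep(sweep(xyz, 2, p) %*% t(R), 2, p, `+`)
    },
    stop("unknown move type '", move$type, "'"))
  conf@atoms[sel, c("x", "y", "z")] <- moved
  conf
}
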
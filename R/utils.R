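# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a temporary RNG state seeded from `seed`; restores the
# caller's RNG so seeded helpers do not disturb the session stream
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation matrix about unit axis
rotationMatrix <- function(axis, theta) {
  u <- unitv(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, uz, -uy, -uz, 0, ux, uy, -ux, 0), 3, 3)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# complement table incl. wobble acceptance checks
RNA_COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

isComplementary <- function(a, b, wobble = TRUE) {
  wc <- (RNA_COMPLEMENT[a] == b)
  if (wobble) wc | (a == "G" & b == "U") | (a == "U" & b == "G") else wc
}

isPurine <- function(base) base %in% c("A", "G")

# glycosidic / Watson-Crick edge atom per base
glycAtom <- function(base) ifelse(isPurine(base), "N9", "N1")
wcAtom   <- function(base) ifelse(isPurine(base), "N1", "N3")

baseRingAtoms <- function(base) {
  if (isPurine(base)) c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6")
  else c("N1", "C2", "N3", "C4", "C5", "C6")
}

BACKBONE_ATOMS <- c("P", "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "C1'")

# O3'(i)-P(i+1) covalent bond: ideal length and acceptance window (Angstrom)
BOND_O3P_IDEAL  <- 1.60
BOND_O3P_BOUNDS <- c(1.25, 2.30)

splitSeq <- function(sequence) {
  if (length(sequence) == 1) strsplit(sequence, "")[[1]]
  else as.character(sequence)
}

# canonical unordered pair matrix: two integer columns, i < j, ordered rows
canonicalPairs <- function(pairs) {
  if (is.null(pairs) || length(pairs) == 0)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  m <- matrix(as.integer(pairs), ncol = 2)
  sw <- m[, 1] > m[, 2]
  if (any(sw)) m[sw, ] <- m[sw, 2:1]
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("i", "j"))
  m
}

pairsEqual <- function(a, b) {
  a <- canonicalPairs(a); b <- canonicalPairs(b)
  nrow(a) == nrow(b) && all(a == b)
}

# do pairs (i,j) and (k,l) cross?  (i<j, k<l)
pairsCross <- function(i, j, k, l) (i < k & k < j & j < l) | (k < i & i < l & l < j)

anyCrossing <- function(pairs) {
  pairs <- canonicalPairs(pairs)
  n <- nrow(pairs)
  if (n < 2) return(FALSE)
  for (a in seq_len(n - 1)) {
    cr <- pairsCross(pairs[a, 1], pairs[a, 2],
                     pairs[(a + 1):n, 1], pairs[(a + 1):n, 2])
    if (any(cr)) return(TRUE)
  }
  FALSE
}
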
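# Shared fixtures, generated in code and cached for the test session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# assign a complementary G-C sequence to any dot-bracket string (loops = A)
designSeq <- function(db) {
  n <- nchar(db)
  ss0 <- parseDotBracket(db, paste(rep("A", n), collapse = ""))
  s <- rep("A", n)
  allp <- rbind(ss0@pairs, ss0@pkPairs)
  if (nrow(allp)) for (k in seq_len(nrow(allp))) {
    if (k %% 2 == 1) { s[allp[k, 1]] <- "G"; s[allp[k, 2]] <- "C" }
    else             { s[allp[k, 1]] <- "C"; s[allp[k, 2]] <- "G" }
  }
  paste(s, collapse = "")
}

HAIRPIN_DB  <- "((((((....))))))"
HAIRPIN_SEQ <- "GGGCGCAAGAGCGCCC"

hairpinSS <- function() parseDotBracket(HAIRPIN_DB, HAIRPIN_SEQ)

hairpinFixture <- function()
  cached("hairpin", buildFixtureStructure(HAIRPIN_SEQ, HAIRPIN_DB, seed = 42))

idealHelix6 <- function()
  cached("helix6", templateAsConformation(buildIdealHelix("GGCAGC", "GCUGCC")))

fragmentPool <- function()
  cached("frags", buildFragmentSet(fragmentSource(seed = 11)))

pkFixture <- function()
  cached("pk", buildPseudoknotFixture(seed = 1))

# fully extended, unstacked chain: residues strung along x at 7 A spacing
extendedChain <- function(n = 6) {
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    xyz <- sweep(refNucleotide("A"), 2, c(7 * (i - 1), 0, 0), `+`)
    data.frame(resi = i, atom = rownames(xyz), x = xyz[, 1], y = xyz[, 2],
               z = xyz[, 3], stringsAsFactors = FALSE)
  }))
  Conformation(rep("A", n), atoms, breaks = seq_len(n - 1))
}

allAtomRMSD <- function(a, b) kabsch(atomCoords(a), atomCoords(b))$rmsd
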
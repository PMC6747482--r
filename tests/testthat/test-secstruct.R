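# Dot-bracket parsing, pseudoknot separation, SSE decomposition and
# movable elements.

test_that("bracket matching recovers nested and crossing pairs", {
  ss <- parseDotBracket("((((....))))", "GGGGAAAACCCC")
  expect_equal(ss@pairs, canonicalPairs(cbind(1:4, 12:9)))
  expect_equal(nrow(ss@pkPairs), 0)

  ss2 <- parseDotBracket("....", "ACGU")
  expect_equal(nrow(ss2@pairs), 0)

  # crossing pairs from a second alphabet land in the pseudoknot set
  ss3 <- parseDotBracket("((..[[..))..]]", "GGAAGGAACCAACC")
  expect_equal(ss3@pairs, canonicalPairs(rbind(c(1, 10), c(2, 9))))
  expect_equal(ss3@pkPairs, canonicalPairs(rbind(c(5, 14), c(6, 13))))
})

test_that("parse errors name the offending position", {
  expect_error(parseDotBracket("((..)", "GGAAC"), "position")
  expect_error(parseDotBracket("((..", "GGAA"), "position")
  expect_error(parseDotBracket("(((.)))", "GGGACC"), "length")
  expect_error(parseDotBracket("..x.", "ACGU"), "position 3")
})

test_that("pseudoknot split maximises the nested set with the 5'-most tie-break", {
  sp <- splitPseudoknots(rbind(c(1, 10), c(2, 9), c(5, 14), c(6, 13)))
  expect_equal(sp$nested, canonicalPairs(rbind(c(1, 10), c(2, 9))))
  expect_equal(sp$pk, canonicalPairs(rbind(c(5, 14), c(6, 13))))

  # nested-only input is returned unchanged
  p <- canonicalPairs(rbind(c(1, 12), c(2, 11), c(4, 8)))
  sp2 <- splitPseudoknots(p)
  expect_equal(sp2$nested, p)
  expect_equal(nrow(sp2$pk), 0)

  # single crossing, tie on size: keep the 5'-most opening
  sp3 <- splitPseudoknots(rbind(c(1, 6), c(3, 8)))
  expect_equal(sp3$nested, canonicalPairs(rbind(c(1, 6))))
  expect_equal(sp3$pk, canonicalPairs(rbind(c(3, 8))))
})

test_that("pseudoknot split partitions the input and is crossing-free", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    idx <- sample(n, 2 * sample(2:min(8, n %/% 2), 1))
    pairs <- matrix(idx, ncol = 2)
    sp <- splitPseudoknots(pairs)
    merged <- canonicalPairs(rbind(sp$nested, sp$pk))
    expect_equal(merged, canonicalPairs(pairs))
    expect_false(anyCrossing(sp$nested))
    # maximality against exhaustive search over subsets
    m <- nrow(pairs)
    best <- 0
    for (mask in 0:(2^m - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
      if (!anyCrossing(pairs[sel, , drop = FALSE])) best <- max(best, length(sel))
    }
    expect_equal(nrow(sp$nested), best)
  }
})

test_that("dot-bracket serialisation round-trips", {
  for (db in c("((((....))))", "..((..))..", "((..[[..))..]]",
               "((((((..[[[...))))))....]]].", "....")) {
    ss <- parseDotBracket(db, designSeq(db))
    ss2 <- parseDotBracket(dotBracket(ss), ss@sequence)
    expect_equal(ss2@pairs, ss@pairs)
    expect_equal(ss2@pkPairs, ss@pkPairs)
  }
})

test_that("SSE decomposition follows the loop taxonomy", {
  # stem + hairpin
  t1 <- decomposeSSE(parseDotBracket("((((....))))", "GGGGAAAACCCC"))
  n1 <- sseNodes(t1)
  expect_equal(vapply(n1, function(x) x@kind, ""), c("stem", "hairpin"))
  expect_equal(length(n1[[1]]@strands[[1]]), 4)

  # stem -> internal loop -> stem -> hairpin
  t2 <- decomposeSSE(parseDotBracket("((..((....))..))", designSeq("((..((....))..))")))
  expect_equal(vapply(sseNodes(t2), function(x) x@kind, ""),
               c("stem", "internal", "stem", "hairpin"))

  # stem -> 3-way junction -> two stems with hairpins
  db3 <- "((.((...)).((...)).))"
  t3 <- decomposeSSE(parseDotBracket(db3, designSeq(db3)))
  expect_equal(vapply(sseNodes(t3), function(x) x@kind, ""),
               c("stem", "junction", "stem", "hairpin", "stem", "hairpin"))

  # bulge: unpaired on one strand only
  db4 <- "((..((....))))"
  t4 <- decomposeSSE(parseDotBracket(db4, designSeq(db4)))
  expect_true("bulge" %in% vapply(sseNodes(t4), function(x) x@kind, ""))

  # empty structure degenerates to a single free chain
  t5 <- decomposeSSE(parseDotBracket("....", "ACGU"))
  expect_equal(t5@kind, "chain")
  expect_equal(t5@residues, 1:4)
})

test_that("decomposition covers all residues and reconstructs the pairing", {
  set.seed(3)
  dbs <- c("((((....))))", "((..((....))..))", "((.((...)).((...)).))",
           "..((((....))))..((((....))))..", "((..((....))))",
           "(((((....)))..))")
  for (db in dbs) {
    ss <- parseDotBracket(db, designSeq(db))
    nodes <- sseNodes(decomposeSSE(ss))
    covered <- sort(unique(unlist(lapply(nodes, function(n) n@residues))))
    expect_equal(covered, seq_len(nchar(db)))
    # union of stem pairs reconstructs the input pairing
    stems <- nodes[vapply(nodes, function(n) n@kind == "stem", TRUE)]
    rebuilt <- canonicalPairs(do.call(rbind, lapply(stems, function(s) s@closingPairs)))
    expect_equal(rebuilt, ss@pairs)
  }
})

test_that("isolated length-1 helices are treated as stems", {
  db <- "..(....)..."
  tree <- decomposeSSE(parseDotBracket(db, designSeq(db)))
  kinds <- vapply(sseNodes(tree), function(x) x@kind, "")
  expect_true("stem" %in% kinds)
  stem <- sseNodes(tree)[[which(kinds == "stem")[1]]]
  expect_equal(nrow(stem@closingPairs), 1)
})

test_that("movable elements agree with the brute-force helix predicate", {
  bruteForce <- function(ss) {
    n <- nchar(ss@sequence)
    stems <- findStems(ss@pairs)
    out <- NULL
    for (a in seq_len(n)) for (b in a:n) {
      ok <- all(vapply(stems, function(s) {
        res <- c(s[, 1], s[, 2])
        inside <- sum(res >= a & res <= b)
        inside == 0 || inside == length(res)
      }, TRUE))
      if (ok) out <- rbind(out, c(a, b))
    }
    out
  }
  for (db in c("((((....))))", "(((())))", "....", "((.((...)).))",
               "..((..))..((..))..")) {
    ss <- parseDotBracket(db, designSeq(db))
    me <- movableElements(ss)
    expect_equal(unname(as.matrix(me[, c("start", "end")])), unname(bruteForce(ss)),
                 info = db)
  }
  # hairpin loop sub-spans qualify; no span may split the helix
  me <- movableElements(parseDotBracket("((((....))))", "GGGGAAAACCCC"))
  expect_true(any(me$start == 5 & me$end == 8))
  expect_true(any(me$start == 1 & me$end == 12))
  expect_false(any(me$start == 1 & me$end == 7))
  # fully paired duplex: only the whole molecule
  me2 <- movableElements(parseDotBracket("(((())))", designSeq("(((())))")))
  expect_equal(nrow(me2), 1)
  expect_equal(c(me2$start, me2$end), c(1, 8))
})

test_that("DBN files read and write in single and batch layouts", {
  f <- tempfile(fileext = ".dbn")
  ss <- hairpinSS()
  writeDBN(ss, f, name = "hp")
  d <- readDBN(f)
  expect_equal(d$name, "hp")
  expect_equal(d$sequences, HAIRPIN_SEQ)
  expect_equal(d$structures, HAIRPIN_DB)

  writeLines(c(HAIRPIN_SEQ, "((((((....))))))", "((((........))))"), f)
  d2 <- readDBN(f)
  expect_equal(length(d2$sequences), 1)
  expect_equal(length(d2$structures), 2)

  writeLines(c(HAIRPIN_SEQ, HAIRPIN_SEQ, "((((((....))))))"), f)
  expect_error(readDBN(f), "same number")
})
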
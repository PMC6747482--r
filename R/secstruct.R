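# Dot-bracket parsing, pseudoknot separation, SSE tree decomposition and
# movable-element enumeration.

# bracket alphabets in pairing priority order
BRACKET_OPEN  <- c("(", "[", "{", "<", LETTERS)
BRACKET_CLOSE <- c(")", "]", "}", ">", letters)

#' Parse a dot-bracket string
#'
#' Matches brackets per alphabet (\code{()[]{}<>} plus \code{Aa..Zz}), pools
#' all pairs, and separates them into a maximal crossing-free nested set and
#' the remaining pseudoknot pairs via \code{\link{splitPseudoknots}}.
#'
#' @param db dot-bracket string (dots for unpaired)
#' @param sequence RNA sequence of the same length
#' @return a \code{\link{SecondaryStructure}}
#' @examples
#' ss <- parseDotBracket("((..[[..))..]]", "GGAAGGAACCAACC")
#' ss@pairs    # nested
#' ss@pkPairs  # crossing pairs
#' @export
parseDotBracket <- function(db, sequence) {
  if (nchar(db) != nchar(sequence))
    stop("input error: structure length (", nchar(db),
         ") != sequence length (", nchar(sequence), ")")
  ch <- strsplit(db, "")[[1]]
  known <- c(".", "-", BRACKET_OPEN, BRACKET_CLOSE)
  bad <- which(!(ch %in% known))
  if (length(bad))
    stop("parse error: unknown character '", ch[bad[1]], "' at position ", bad[1])
  pairs <- NULL
  for (a in seq_along(BRACKET_OPEN)) {
    op <- BRACKET_OPEN[a]; cl <- BRACKET_CLOSE[a]
    stack <- integer(0)
    for (p in seq_along(ch)) {
      if (ch[p] == op) stack <- c(stack, p)
      else if (ch[p] == cl) {
        if (!length(stack))
          stop("parse error: unmatched '", cl, "' at position ", p)
        pairs <- rbind(pairs, c(stack[length(stack)], p))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop("parse error: unmatched '", op, "' at position ", stack[length(stack)])
  }
  sp <- splitPseudoknots(pairs)
  SecondaryStructure(sequence, sp$nested, sp$pk)
}

#' Separate pseudoknot pairs from a pairing
#'
#' Finds a maximum-cardinality crossing-free subset of the input pairs (exact
#' interval dynamic program); everything else is classified as pseudoknot.
#' Ties between equal-size crossing-free subsets are broken by preferring to
#' keep the pair whose opening index is most 5'.
#'
#' @param pairs two-column matrix of pairs (1-based, each index in at most
#'   one pair)
#' @return list with elements \code{nested} and \code{pk} (pair matrices)
#' @export
splitPseudoknots <- function(pairs) {
  pairs <- canonicalPairs(pairs)
  empty <- canonicalPairs(NULL)
  if (!nrow(pairs)) return(list(nested = empty, pk = empty))
  idx <- as.vector(pairs)
  if (anyDuplicated(idx)) stop("input is not a one-to-one pairing")
  if (!anyCrossing(pairs)) return(list(nested = pairs, pk = empty))
  n <- max(pairs)
  partner <- integer(n)
  partner[pairs[, 1]] <- pairs[, 2]
  # M[i,j]: max pairs fully inside [i, j]; windows by increasing length
  M <- matrix(0L, n + 1, n + 1)   # index shift: M[i, j+1]
  for (len in 2:n) {
    for (i in 1:(n - len + 1)) {
      j <- i + len - 1
      best <- M[i + 1, j + 1]
      k <- partner[i]
      if (k > 0 && k <= j) {
        with_i <- 1L + M[i + 1, k] + M[k + 1, j + 1]
        if (with_i >= best) best <- with_i   # ties: keep the 5'-most opening
      }
      M[i, j + 1] <- best
    }
  }
  keep <- logical(nrow(pairs))
  recurse <- function(i, j) {
    while (i < j) {
      k <- if (i <= n) partner[i] else 0L
      if (k > 0 && k <= j &&
          1L + M[i + 1, k] + M[k + 1, j + 1] >= M[i + 1, j + 1]) {
        keep[which(pairs[, 1] == i)] <<- TRUE
        recurse(i + 1, k - 1)
        i <- k + 1
      } else i <- i + 1
    }
  }
  recurse(1L, n)
  list(nested = canonicalPairs(pairs[keep, , drop = FALSE]),
       pk = canonicalPairs(pairs[!keep, , drop = FALSE]))
}

#' Serialise a secondary structure to dot-bracket notation
#'
#' Nested pairs use \code{()}; pseudoknot pairs are split into mutually
#' non-crossing groups, each written with the next bracket alphabet.
#'
#' @param ss a \code{SecondaryStructure}
#' @return dot-bracket string
#' @export
dotBracket <- function(ss) {
  n <- nchar(ss@sequence)
  out <- rep(".", n)
  put <- function(pairs, a) {
    out[pairs[, 1]] <<- BRACKET_OPEN[a]
    out[pairs[, 2]] <<- BRACKET_CLOSE[a]
  }
  if (nrow(ss@pairs)) put(ss@pairs, 1)
  pk <- ss@pkPairs
  a <- 2
  while (nrow(pk)) {
    grp <- logical(nrow(pk))
    for (r in seq_len(nrow(pk))) {
      sel <- which(grp)
      ok <- !length(sel) || !any(pairsCross(pk[sel, 1], pk[sel, 2], pk[r, 1], pk[r, 2]))
      if (ok) grp[r] <- TRUE
    }
    put(pk[grp, , drop = FALSE], a)
    pk <- pk[!grp, , drop = FALSE]
    a <- a + 1
  }
  paste(out, collapse = "")
}

## ------------------------------------------------------------ stems / tree

# group nested pairs into maximal helices (stems); returns list of pair
# matrices, each sorted outer -> inner
findStems <- function(pairs) {
  pairs <- canonicalPairs(pairs)
  if (!nrow(pairs)) return(list())
  stems <- list()
  cur <- pairs[1, , drop = FALSE]
  if (nrow(pairs) > 1) for (r in 2:nrow(pairs)) {
    prev <- cur[nrow(cur), ]
    if (pairs[r, 1] == prev[1] + 1 && pairs[r, 2] == prev[2] - 1) {
      cur <- rbind(cur, pairs[r, ])
    } else {
      stems[[length(stems) + 1]] <- cur
      cur <- pairs[r, , drop = FALSE]
    }
  }
  stems[[length(stems) + 1]] <- cur
  stems
}

# closing residues contributed by a helix end: the last one or two stacked
# pairs (two when the helix has length >= 2)
stemClosing <- function(stem, end = c("inner", "outer")) {
  end <- match.arg(end)
  L <- nrow(stem)
  take <- if (end == "inner") L:max(1, L - 1) else 1:min(2, L)
  canonicalPairs(stem[take, , drop = FALSE])
}

#' Decompose a secondary structure into its SSE tree
#'
#' Stems are maximal helices; each stem's innermost pair closes a loop node
#' (hairpin, bulge, internal or junction by the standard taxonomy), whose
#' children are the stems emerging from it.  Loop nodes include the residues
#' of up to two closing pairs per helix end, shared with the adjoining stems,
#' which later serve as superposition overlap during assembly.  The root is
#' the SSE containing the 5'-terminal residue; when the molecule does not
#' start and end with one outermost helix, an "exterior" node holding the
#' unpaired termini and top-level stems is the root.  A structure with no
#' pairs at all yields a single "chain" node.
#'
#' @param ss a \code{SecondaryStructure} (nested pairs only are used)
#' @return the root \code{\link{SSENode}}
#' @export
decomposeSSE <- function(ss) {
  n <- nchar(ss@sequence)
  stems <- findStems(ss@pairs)
  if (!length(stems)) {
    return(SSENode("chain", seq_len(n), list(seq_len(n))))
  }
  outer <- t(vapply(stems, function(s) s[1, ], numeric(2)))

  between <- function(x, y) if (x + 1 <= y - 1) (x + 1):(y - 1) else integer(0)

  stemNode <- function(si) {
    s <- stems[[si]]
    L <- nrow(s)
    strands <- list(s[1, 1]:s[L, 1], s[L, 2]:s[1, 2])
    inner <- s[L, ]
    kids <- list()
    if (inner[2] - inner[1] > 1)
      kids <- list(loopNode(si))
    SSENode("stem", unlist(strands), strands, closingPairs = s, children = kids)
  }

  # loop closed by the innermost pair of stem si
  loopNode <- function(si) {
    s <- stems[[si]]
    i2 <- s[nrow(s), 1]; j2 <- s[nrow(s), 2]
    inside <- which(outer[, 1] > i2 & outer[, 2] < j2)
    direct <- inside[!vapply(inside, function(a)
      any(outer[inside, 1] < outer[a, 1] & outer[inside, 2] > outer[a, 2]),
      logical(1))]
    direct <- direct[order(outer[direct, 1])]
    b <- length(direct)
    closing <- stemClosing(s, "inner")
    close5 <- sort(closing[, 1])            # {i2-1, i2} or {i2}
    close3 <- sort(closing[, 2])            # {j2, j2+1} or {j2}
    cp <- closing
    strands <- list()
    if (b == 0) {
      strands[[1]] <- c(close5, between(i2, j2), close3)
    } else {
      left <- close5; attachL <- i2
      for (ci in direct) {
        chClose <- stemClosing(stems[[ci]], "outer")
        cp <- rbind(cp, chClose)
        strands[[length(strands) + 1]] <-
          c(left, between(attachL, outer[ci, 1]), sort(chClose[, 1]))
        left <- sort(chClose[, 2])
        attachL <- outer[ci, 2]
      }
      strands[[length(strands) + 1]] <- c(left, between(attachL, j2), close3)
    }
    kind <- if (b == 0) "hairpin"
      else if (b == 1) {
        u1 <- outer[direct, 1] - i2 - 1
        u2 <- j2 - outer[direct, 2] - 1
        if (u1 > 0 && u2 > 0) "internal" else "bulge"
      } else "junction"
    SSENode(kind, sort(unique(unlist(strands))), strands,
            closingPairs = canonicalPairs(cp), children = lapply(direct, stemNode))
  }

  # top-level stems
  top <- which(!vapply(seq_len(nrow(outer)), function(a)
    any(outer[, 1] < outer[a, 1] & outer[, 2] > outer[a, 2]), logical(1)))
  top <- top[order(outer[top, 1])]
  if (length(top) == 1 && outer[top, 1] == 1 && outer[top, 2] == n)
    return(stemNode(top))
  # exterior node: unpaired termini and linkers plus top-level stem closings
  strands <- list(); cp <- NULL
  left <- integer(0); prevEnd <- 0
  for (ci in top) {
    chClose <- stemClosing(stems[[ci]], "outer")
    cp <- rbind(cp, chClose)
    strands[[length(strands) + 1]] <-
      c(left, between(prevEnd, outer[ci, 1]), sort(chClose[, 1]))
    left <- sort(chClose[, 2])
    prevEnd <- outer[ci, 2]
  }
  tail <- if (prevEnd < n) (prevEnd + 1):n else integer(0)
  strands[[length(strands) + 1]] <- c(left, tail)
  resid <- sort(unique(unlist(strands)))
  SSENode("exterior", resid, strands, closingPairs = canonicalPairs(cp),
          children = lapply(top, stemNode))
}

#' Flatten an SSE tree in pre-order
#'
#' @param node root \code{SSENode}
#' @return list of nodes, parent before children, children 5'->3'
#' @export
sseNodes <- function(node) {
  out <- list(node)
  for (ch in node@children) out <- c(out, sseNodes(ch))
  out
}

sseTreeFormat <- function(node, indent = 0) {
  strandLens <- paste(vapply(node@strands, length, integer(1)), collapse = ",")
  line <- sprintf("%s%s [%s] residues %s", strrep("  ", indent), node@kind,
                  strandLens, paste(range(node@residues), collapse = "-"))
  c(line, unlist(lapply(node@children, sseTreeFormat, indent = indent + 1)))
}

#' Enumerate movable elements
#'
#' A movable element is a contiguous residue span whose rigid motion cannot
#' break any helix: for every stem (maximal helix) of the nested structure,
#' the stem's residues are either entirely inside or entirely outside the
#' span.  All qualifying spans, from single residues to the whole molecule,
#' are returned.
#'
#' @param ss a \code{SecondaryStructure}
#' @return data.frame with columns start, end, anchor ("internal",
#'   "5end", "3end" or "whole": which sides connect to fixed structure)
#' @export
movableElements <- function(ss) {
  n <- nchar(ss@sequence)
  stems <- findStems(ss@pairs)
  inStem <- lapply(stems, function(s) {
    v <- logical(n); v[c(s[, 1], s[, 2])] <- TRUE
    cumsum(v)   # prefix counts
  })
  sizes <- vapply(stems, function(s) 2L * nrow(s), integer(1))
  res <- list()
  for (a in seq_len(n)) for (b in a:n) {
    ok <- TRUE
    for (k in seq_along(stems)) {
      cnt <- inStem[[k]][b] - if (a > 1) inStem[[k]][a - 1] else 0L
      if (cnt != 0L && cnt != sizes[k]) { ok <- FALSE; break }
    }
    if (ok) {
      anchor <- if (a == 1 && b == n) "whole"
        else if (a == 1) "5end" else if (b == n) "3end" else "internal"
      res[[length(res) + 1]] <- c(a, b, anchor)
    }
  }
  out <- as.data.frame(do.call(rbind, res), stringsAsFactors = FALSE)
  names(out) <- c("start", "end", "anchor")
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  out
}

## ----------------------------------------------------------------- DBN I/O

#' Read a DBN (dot-bracket notation) file
#'
#' Layout: an optional \code{>name} line, then sequence line(s) and
#' structure line(s).  Batch layouts are supported: one sequence with many
#' structures, or equal numbers of sequences and structures.
#'
#' @param path file path
#' @return list with \code{name}, \code{sequences}, \code{structures}
#' @export
readDBN <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln)]
  name <- NULL
  if (length(ln) && startsWith(ln[1], ">")) {
    name <- sub("^>\\s*", "", ln[1]); ln <- ln[-1]
  }
  isSeq <- grepl("^[ACGUTacgut]+$", ln)
  seqs <- toupper(gsub("T", "U", ln[isSeq]))
  strs <- ln[!isSeq]
  if (!length(seqs) || !length(strs))
    stop("DBN file must contain at least one sequence and one structure line")
  if (length(seqs) > 1 && length(seqs) != length(strs))
    stop("sequence and structure sections should contain the same number of lines")
  list(name = name, sequences = seqs, structures = strs)
}

#' Write a secondary structure as a DBN file
#'
#' @param ss a \code{SecondaryStructure}
#' @param path output path
#' @param name optional header name
#' @export
writeDBN <- function(ss, path, name = NULL) {
  out <- c(if (!is.null(name)) paste0(">", name), ss@sequence, dotBracket(ss))
  writeLines(out, path)
  invisible(path)
}
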
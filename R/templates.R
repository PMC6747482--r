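# SSE template library: harvesting, shape-keyed queries, persistence, and
# the synthetic fixture library.

#' Shape key of a template or SSE node
#'
#' Templates match query nodes by exact shape: the SSE kind plus the ordered
#' per-strand residue counts (closing-pair residues included).
#'
#' @param x a \code{Template} or \code{SSENode}
#' @return character key, e.g. \code{"stem:4"} or \code{"hairpin:8"}
#' @export
shapeKeyOf <- function(x) {
  if (is(x, "Template")) {
    lens <- nchar(x@strandSeqs)
  } else if (is(x, "SSENode")) {
    lens <- vapply(x@strands, length, integer(1))
  } else stop("shapeKeyOf: unsupported type")
  kind <- if (is(x, "Template")) x@kind else x@kind
  if (kind == "stem") sprintf("stem:%d", lens[1])
  else sprintf("%s:%s", kind, paste(lens, collapse = ","))
}

# node residues in canonical (flattened-strand) order; local index mapping
nodeLocalOrder <- function(node) unlist(node@strands)

# cut one node's template out of a conformation
templateFromNode <- function(conf, node, sourceId) {
  order <- nodeLocalOrder(node)
  local <- seq_along(order)
  names(local) <- order
  a <- conf@atoms[conf@atoms$resi %in% order, , drop = FALSE]
  a$resi <- local[as.character(a$resi)]
  a <- a[order(a$resi), , drop = FALSE]
  strandSeqs <- vapply(node@strands, function(s)
    paste(conf@sequence[s], collapse = ""), character(1))
  cl <- node@closingPairs
  if (nrow(cl)) {
    cl <- cbind(local[as.character(cl[, 1])], local[as.character(cl[, 2])])
  } else cl <- NULL
  Template(node@kind, strandSeqs, a, closingLocal = cl, sourceId = sourceId)
}

#' Harvest SSE templates from annotated structures
#'
#' Decomposes each structure's base pairing into its SSE tree and cuts every
#' stem and loop (with its closing pairs) into a \code{\link{Template}}
#' tagged with the structure's identifier.  The pairing is taken from the
#' \code{pairs} argument when given, otherwise detected geometrically with
#' \code{\link{annotateInteractions}}.
#'
#' @param structures list of \code{Conformation}
#' @param ids character vector of source identifiers (defaults to S1, S2, ...)
#' @param pairs optional list of base-pair matrices, parallel to
#'   \code{structures}
#' @return a \code{\link{TemplateLibrary}}
#' @export
harvestTemplates <- function(structures, ids = NULL, pairs = NULL) {
  if (is(structures, "Conformation")) structures <- list(structures)
  ids <- ids %||% paste0("S", seq_along(structures))
  entries <- list()
  for (s in seq_along(structures)) {
    conf <- structures[[s]]
    p <- if (!is.null(pairs)) pairs[[s]] else annotateInteractions(conf)@wcPairs
    ssOk <- tryCatch({
      sp <- splitPseudoknots(p)
      ss <- SecondaryStructure(paste(conf@sequence, collapse = ""), sp$nested)
      tree <- decomposeSSE(ss)
      for (node in sseNodes(tree)) {
        if (node@kind == "chain") next
        entries[[length(entries) + 1]] <- templateFromNode(conf, node, ids[s])
      }
      TRUE
    }, error = function(e) {
      warning("skipping structure ", ids[s], ": ", conditionMessage(e))
      FALSE
    })
  }
  TemplateLibrary(entries)
}

# fraction of identical aligned positions over all strands
sequenceIdentity <- function(a, b) {
  if (length(a) != length(b)) return(0)
  mean(a == b)
}

#' Query the template library
#'
#' Returns up to \code{n} templates whose shape matches the query node
#' exactly, excluding templates whose source is in \code{excludeIds}, ranked
#' by sequence identity to the node's sequence (ties broken by source id,
#' then insertion order).  An empty result signals that a missing template
#' must be generated de novo (see \code{\link{biresidueBuild}} and
#' \code{\link{dgBuild}}).
#'
#' @param lib a \code{TemplateLibrary}
#' @param node query \code{SSENode}
#' @param nodeSeq character vector of the node's bases in flattened strand
#'   order (from the query sequence)
#' @param excludeIds source ids to exclude
#' @param n maximum number of templates
#' @return list of \code{Template}, best first
#' @export
queryTemplates <- function(lib, node, nodeSeq, excludeIds = character(0),
                           n = Inf) {
  key <- shapeKeyOf(node)
  hit <- which(lib@keys == key)
  if (!length(hit)) return(list())
  src <- vapply(lib@entries[hit], function(t) t@sourceId, character(1))
  hit <- hit[!(src %in% excludeIds)]
  if (!length(hit)) return(list())
  ident <- vapply(lib@entries[hit], function(t)
    sequenceIdentity(t@sequence, nodeSeq), numeric(1))
  src <- vapply(lib@entries[hit], function(t) t@sourceId, character(1))
  ord <- order(-ident, src, seq_along(hit))
  out <- lib@entries[hit[ord]]
  if (is.finite(n)) out <- out[seq_len(min(n, length(out)))]
  out
}

#' Merge template libraries
#'
#' @param ... \code{TemplateLibrary} objects
#' @return combined library (insertion order preserved)
#' @export
mergeLibraries <- function(...) {
  libs <- list(...)
  TemplateLibrary(do.call(c, lapply(libs, function(l) l@entries)))
}

## -------------------------------------------------------------- persistence

#' Save / load a template library
#'
#' One PDB coordinate file plus a JSON sidecar (kind, strand sequences,
#' closing pairs, source id) per template, grouped in per-kind
#' subdirectories.
#'
#' @param lib a \code{TemplateLibrary}
#' @param dir library directory
#' @return \code{saveLibrary} the directory, \code{loadLibrary} a
#'   \code{TemplateLibrary}
#' @export
saveLibrary <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(lib@entries)) {
    t <- lib@entries[[i]]
    sub <- file.path(dir, t@kind)
    dir.create(sub, showWarnings = FALSE)
    base <- file.path(sub, sprintf("t%04d", i))
    writePDB(templateAsConformation(t), paste0(base, ".pdb"))
    meta <- list(kind = t@kind, strandSeqs = t@strandSeqs,
                 closingLocal = t@closingLocal, sourceId = t@sourceId)
    jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname saveLibrary
#' @export
loadLibrary <- function(dir) {
  metas <- sort(list.files(dir, pattern = "\\.json$", recursive = TRUE,
                           full.names = TRUE))
  entries <- lapply(metas, function(m) {
    meta <- jsonlite::read_json(m, simplifyVector = TRUE)
    conf <- readPDB(sub("\\.json$", ".pdb", m))[[1]]
    cl <- if (length(meta$closingLocal)) matrix(meta$closingLocal, ncol = 2) else NULL
    Template(meta$kind, meta$strandSeqs, conf@atoms, closingLocal = cl,
             sourceId = meta$sourceId)
  })
  TemplateLibrary(entries)
}

## ---------------------------------------------------------- fixture library

#' Build a synthetic template library for a secondary structure
#'
#' A deterministic, seeded stand-in for an experimentally derived library:
#' every stem of the structure gets an ideal A-form helix with the query's
#' own sequence, and every loop (hairpin, bulge, internal, junction,
#' exterior) is generated de novo with the bi-residue fragment method.
#' \code{nAlternatives > 1} adds extra loop templates built from different
#' derived seeds (distinct synthetic source ids), which gives the sampling
#' task genuine template diversity.
#'
#' @param ss a \code{SecondaryStructure}
#' @param seed RNG seed; the library is bit-identical for equal seeds
#' @param nAlternatives number of templates per loop shape
#' @param steps Monte Carlo steps per generated loop
#' @return a \code{\link{TemplateLibrary}}
#' @export
buildFixtureLibrary <- function(ss, seed = 1, nAlternatives = 1, steps = 300) {
  tree <- decomposeSSE(ss)
  seqv <- splitSeq(ss@sequence)
  frags <- buildFragmentSet(fragmentSource(seed))
  entries <- list()
  for (node in sseNodes(tree)) {
    nodeSeq <- seqv[nodeLocalOrder(node)]
    if (node@kind == "stem") {
      s1 <- paste(seqv[node@strands[[1]]], collapse = "")
      s2 <- paste(seqv[node@strands[[2]]], collapse = "")
      key <- shapeKeyOf(node)
      if (!any(vapply(entries, function(e) shapeKeyOf(e) == key &&
                        identical(e@strandSeqs[1], s1), logical(1)))) {
        entries[[length(entries) + 1]] <-
          buildIdealHelix(s1, s2, sourceId = "synthetic:helix")
      }
    } else if (node@kind != "chain") {
      for (alt in seq_len(nAlternatives)) {
        t <- biresidueBuild(node, frags, nodeSeq = nodeSeq, steps = steps,
                            seed = seed + 1000 * alt + min(node@residues))
        t@sourceId <- sprintf("synthetic:loop%d", alt)
        entries[[length(entries) + 1]] <- t
      }
    } else {
      t <- chainTemplate(node, nodeSeq, seed = seed)
      entries[[length(entries) + 1]] <- t
    }
  }
  TemplateLibrary(entries)
}

# free-chain template (structure with no pairs): a gently curved strand
chainTemplate <- function(node, nodeSeq, seed = 1) {
  withSeed(seed, {
    w <- walkStrand(nodeSeq, bend = function(i)
      list(axis = stats::rnorm(3), theta = stats::rnorm(1, sd = 0.15)))
    Template("chain", paste(nodeSeq, collapse = ""), w$atoms,
             sourceId = "synthetic:chain")
  })
}
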
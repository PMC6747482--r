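# Tree-traversal assembly of full conformations from per-SSE templates,
# template sampling, and geometric relaxation.

# replace base ring atoms so a placed template fragment matches the target
# base at each residue (templates chosen by homology may differ in sequence)
remodelBases <- function(atoms, targetSeq) {
  out <- list()
  for (r in unique(atoms$resi)) {
    a <- atoms[atoms$resi == r, , drop = FALSE]
    sug <- as.matrix(a[a$atom %in% rownames(.SUGAR_XYZ), c("x", "y", "z")])
    rownames(sug) <- a$atom[a$atom %in% rownames(.SUGAR_XYZ)]
    want <- baseRingAtoms(targetSeq[r])
    have <- setdiff(a$atom, rownames(.SUGAR_XYZ))
    if (setequal(have, want) || nrow(sug) < 9) {
      out[[length(out) + 1]] <- a
      next
    }
    tr <- sugarTransform(sug)
    ring <- if (isPurine(targetSeq[r])) .PURINE_XYZ else .PYRIMIDINE_XYZ
    placedRing <- applyTransform(ring, tr)
    rownames(placedRing) <- rownames(ring)
    keep <- a[a$atom %in% rownames(.SUGAR_XYZ), , drop = FALSE]
    out[[length(out) + 1]] <- rbind(keep, residueAtoms(r, placedRing))
  }
  do.call(rbind, out)
}

#' Assemble a conformation from per-node templates
#'
#' Walks the SSE tree in pre-order.  The root template is placed as is;
#' every other template is rigid-body superposed onto the already-placed
#' structure using all atoms of the closing base pairs it shares with its
#' parent (Kabsch fit), and duplicated residues keep the parent's copy.
#' Template residues whose base differs from the target sequence get their
#' base ring rebuilt on the placed sugar.
#'
#' @param ss the target \code{SecondaryStructure}
#' @param choices list of \code{Template}, parallel to
#'   \code{sseNodes(decomposeSSE(ss))}
#' @return a \code{Conformation} with per-node provenance
#' @export
assembleStructure <- function(ss, choices) {
  tree <- decomposeSSE(ss)
  nodes <- sseNodes(tree)
  if (length(choices) != length(nodes))
    stop("need one template per node (", length(nodes), "), got ", length(choices))
  seqv <- splitSeq(ss@sequence)
  placed <- matrix(NA_real_, 0, 3)
  placedMeta <- data.frame(resi = integer(0), atom = character(0))
  atomsList <- list()
  provenance <- list()
  for (ni in seq_along(nodes)) {
    node <- nodes[[ni]]
    tmpl <- choices[[ni]]
    if (is.null(tmpl))
      stop("missing template for node ", ni, " (", shapeKeyOf(node),
           ", residues ", paste(range(node@residues), collapse = "-"), ")")
    if (shapeKeyOf(tmpl) != shapeKeyOf(node))
      stop("template shape ", shapeKeyOf(tmpl), " does not match node ",
           shapeKeyOf(node))
    order <- nodeLocalOrder(node)
    a <- tmpl@atoms
    a$resi <- order[a$resi]                      # local -> global numbering
    a <- remodelBases(a, seqv)
    key <- paste0(a$resi, ":", a$atom)
    if (ni == 1) {
      new <- a
    } else {
      placedKey <- paste0(placedMeta$resi, ":", placedMeta$atom)
      shared <- intersect(key, placedKey)
      if (length(shared) < 3)
        stop("too few shared closing-pair atoms (", length(shared),
             ") to superpose node ", ni)
      mob <- unname(as.matrix(a[match(shared, key), c("x", "y", "z")]))
      tgt <- unname(placed[match(shared, placedKey), , drop = FALSE])
      fit <- kabsch(mob, tgt)
      a[, c("x", "y", "z")] <- applyTransform(as.matrix(a[, c("x", "y", "z")]), fit)
      new <- a[!(key %in% placedKey), , drop = FALSE]   # parent's copy wins
    }
    atomsList[[ni]] <- new
    placed <- rbind(placed, as.matrix(new[, c("x", "y", "z")]))
    placedMeta <- rbind(placedMeta, new[, c("resi", "atom")])
    provenance[[ni]] <- list(node = shapeKeyOf(node), source = tmpl@sourceId)
  }
  atoms <- do.call(rbind, atomsList)
  atoms <- atoms[order(atoms$resi, match(atoms$atom, c(BACKBONE_ATOMS,
             baseRingAtoms("A"), baseRingAtoms("C")))), , drop = FALSE]
  Conformation(seqv, atoms, provenance = list(templates = provenance))
}

# resolve one template per node: query the library, fall back to the
# bi-residue generator for missing shapes
resolveTemplates <- function(ss, lib, excludeIds = character(0), rank = "top",
                             seed = 1, fragments = NULL) {
  tree <- decomposeSSE(ss)
  nodes <- sseNodes(tree)
  seqv <- splitSeq(ss@sequence)
  out <- vector("list", length(nodes))
  for (ni in seq_along(nodes)) {
    node <- nodes[[ni]]
    nodeSeq <- seqv[nodeLocalOrder(node)]
    hits <- queryTemplates(lib, node, nodeSeq, excludeIds = excludeIds)
    if (!length(hits)) {
      if (node@kind == "chain") {
        out[[ni]] <- chainTemplate(node, nodeSeq, seed = seed + ni)
      } else {
        fragments <- fragments %||% buildFragmentSet(fragmentSource(seed))
        out[[ni]] <- biresidueBuild(node, fragments, nodeSeq = nodeSeq,
                                    steps = 300, seed = seed + ni)
      }
    } else if (rank == "top") {
      out[[ni]] <- hits[[1]]
    } else {
      out[[ni]] <- hits[[sample.int(length(hits), 1)]]
    }
  }
  out
}

#' Assemble the top-ranked model and N-1 random-template variants
#'
#' The first model uses the highest-homology template of every SSE; the
#' remaining \code{nPredictions - 1} models draw each node's template at
#' random (seeded) from the matching library entries.
#'
#' @param ss target \code{SecondaryStructure}
#' @param lib a \code{TemplateLibrary}
#' @param cfg a \code{\link{predictionConfig}}
#' @return list of \code{Conformation}
#' @export
assembleTop <- function(ss, lib, cfg = predictionConfig()) {
  out <- vector("list", cfg@nPredictions)
  frags <- NULL
  withSeed(cfg@seed, {
    for (m in seq_len(cfg@nPredictions)) {
      choices <- resolveTemplates(ss, lib, excludeIds = cfg@excludeIds,
                                  rank = if (m == 1) "top" else "random",
                                  seed = cfg@seed + 17 * m, fragments = frags)
      conf <- assembleStructure(ss, choices)
      conf@provenance$model <- m
      if (cfg@refine) conf <- relaxConformation(conf, pairs = ss@pairs)
      out[[m]] <- conf
    }
  })
  out
}

#' Template-sampling ensemble (the sampling task)
#'
#' Starts from the top-ranked assembly; at each step one randomly chosen
#' node's template is replaced by a randomly chosen library alternative and
#' the structure re-assembled.  All sampled conformations (including the
#' start) are returned for clustering.
#'
#' @param ss target \code{SecondaryStructure}
#' @param lib a \code{TemplateLibrary}
#' @param steps number of sampling steps
#' @param cfg a \code{\link{predictionConfig}}
#' @return list of \code{Conformation} of length \code{steps + 1}
#' @export
sampleTemplates <- function(ss, lib, steps = 500, cfg = predictionConfig()) {
  if (steps < 0) stop("steps must be >= 0")
  tree <- decomposeSSE(ss)
  nodes <- sseNodes(tree)
  seqv <- splitSeq(ss@sequence)
  withSeed(cfg@seed, {
    choices <- resolveTemplates(ss, lib, excludeIds = cfg@excludeIds,
                                rank = "top", seed = cfg@seed)
    confs <- vector("list", steps + 1)
    confs[[1]] <- assembleStructure(ss, choices)
    if (steps > 0) for (s in seq_len(steps)) {
      ni <- sample.int(length(nodes), 1)
      nodeSeq <- seqv[nodeLocalOrder(nodes[[ni]])]
      hits <- queryTemplates(lib, nodes[[ni]], nodeSeq,
                             excludeIds = cfg@excludeIds)
      if (length(hits))
        choices[[ni]] <- hits[[sample.int(length(hits), 1)]]
      conf <- assembleStructure(ss, choices)
      conf@provenance$step <- s
      confs[[s + 1]] <- conf
    }
    confs
  })
}

#' Geometric relaxation of a conformation
#'
#' Gradient-free cleanup pass replacing an external force-field
#' minimisation: per-residue rigid translations iteratively restore
#' stretched or compressed O3'-P junction bonds, relieve steric clashes
#' (moves that would increase the clash count are rejected), and hold
#' secondary-structure pairs inside Watson-Crick distance bounds.
#'
#' @param conf a \code{Conformation}
#' @param iterations relaxation sweeps
#' @param pairs optional nested-pair matrix to maintain
#' @return relaxed \code{Conformation}
#' @export
relaxConformation <- function(conf, iterations = 60, pairs = NULL) {
  n <- nResidues(conf)
  resIdx <- split(seq_len(nrow(conf@atoms)), conf@atoms$resi)
  xyz <- as.matrix(conf@atoms[, c("x", "y", "z")])
  atom <- conf@atoms$atom
  o3Of <- vapply(seq_len(n), function(r) {
    i <- resIdx[[as.character(r)]]; w <- i[atom[i] == "O3'"]
    if (length(w)) w[1] else NA_integer_ }, integer(1))
  pOf <- vapply(seq_len(n), function(r) {
    i <- resIdx[[as.character(r)]]; w <- i[atom[i] == "P"]
    if (length(w)) w[1] else NA_integer_ }, integer(1))
  c1Of <- vapply(seq_len(n), function(r) {
    i <- resIdx[[as.character(r)]]; w <- i[atom[i] == "C1'"]
    if (length(w)) w[1] else NA_integer_ }, integer(1))
  shift <- function(r, v) xyz[resIdx[[as.character(r)]], ] <<-
    sweep(xyz[resIdx[[as.character(r)]], , drop = FALSE], 2, v, `+`)
  clashesOf <- function(m) {
    D <- as.matrix(stats::dist(m))
    cl <- which(D < 2.2 & upper.tri(D), arr.ind = TRUE)
    if (!nrow(cl)) return(cl)
    ri <- conf@atoms$resi[cl[, 1]]; rj <- conf@atoms$resi[cl[, 2]]
    ai <- atom[cl[, 1]]; aj <- atom[cl[, 2]]
    ok <- ri != rj & !((ri == rj - 1 & ai == "O3'" & aj == "P") |
                       (rj == ri - 1 & aj == "O3'" & ai == "P"))
    cl[ok, , drop = FALSE]
  }
  bondPass <- function() {
    moved <- FALSE
    for (r in seq_len(n - 1)) {
      if (r %in% conf@breaks || is.na(o3Of[r]) || is.na(pOf[r + 1])) next
      v <- xyz[pOf[r + 1], ] - xyz[o3Of[r], ]
      d <- vnorm(v)
      if (d < BOND_O3P_BOUNDS[1] || d > BOND_O3P_BOUNDS[2]) {
        corr <- (BOND_O3P_IDEAL - d) * v / max(d, 1e-6)
        shift(r + 1, 0.4 * corr)
        shift(r, -0.4 * corr)
        moved <- TRUE
      }
    }
    moved
  }
  for (it in seq_len(iterations)) {
    moved <- FALSE
    cl <- clashesOf(xyz)
    if (nrow(cl)) {
      before <- nrow(cl)
      trial <- xyz
      for (q in seq_len(nrow(cl))) {
        i <- cl[q, 1]; j <- cl[q, 2]
        v <- xyz[j, ] - xyz[i, ]
        d <- max(vnorm(v), 1e-6)
        push <- 0.2 * (2.2 - d) * v / d
        ri <- conf@atoms$resi[i]; rj <- conf@atoms$resi[j]
        trial[resIdx[[as.character(rj)]], ] <-
          sweep(trial[resIdx[[as.character(rj)]], , drop = FALSE], 2, push, `+`)
        trial[resIdx[[as.character(ri)]], ] <-
          sweep(trial[resIdx[[as.character(ri)]], , drop = FALSE], 2, -push, `+`)
      }
      if (nrow(clashesOf(trial)) <= before) { xyz <- trial; moved <- TRUE }
    }
    if (!is.null(pairs) && nrow(pairs)) for (pr in seq_len(nrow(pairs))) {
      i <- pairs[pr, 1]; j <- pairs[pr, 2]
      if (is.na(c1Of[i]) || is.na(c1Of[j])) next
      v <- xyz[c1Of[j], ] - xyz[c1Of[i], ]
      d <- vnorm(v)
      if (d < 9.0 || d > 11.5) {
        corr <- (10.4 - d) * v / max(d, 1e-6)
        shift(j, 0.3 * corr); shift(i, -0.3 * corr)
        moved <- TRUE
      }
    }
    # bond restoration last, so clash pushes never leave a torn junction
    if (bondPass()) moved <- TRUE
    if (!moved) break
  }
  for (it in seq_len(40)) if (!bondPass()) break
  conf@atoms[, c("x", "y", "z")] <- xyz
  conf
}
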
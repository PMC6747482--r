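# PDB I/O (via bio3d), the four task types, batch mode, and manifests.

RNA_RESID_MAP <- c(A = "A", C = "C", G = "G", U = "U",
                   RA = "A", RC = "C", RG = "G", RU = "U",
                   ADE = "A", CYT = "C", GUA = "G", URA = "U", URI = "U")

#' Read RNA conformations from a PDB file
#'
#' Parses ATOM records with \pkg{bio3d}; residues are renumbered 1..n in
#' file order, two- and three-letter RNA residue names are mapped to one
#' letter, old-style atom names (\code{C1*}) are normalised, and chain
#' breaks are detected from the O3'-P distance.  Each MODEL block becomes
#' one conformation.
#'
#' @param path PDB file
#' @return list of \code{Conformation} (one per model)
#' @export
readPDB <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  resid <- toupper(trimws(at$resid))
  isRNA <- resid %in% names(RNA_RESID_MAP) & at$type == "ATOM"
  if (!any(isRNA)) stop("no RNA chain found in '", path, "'")
  at <- at[isRNA, , drop = FALSE]
  resid <- resid[isRNA]
  elety <- gsub("\\*", "'", trimws(at$elety))
  resKey <- paste(at$chain, at$resno, at$insert %||% "")
  ures <- unique(resKey)
  resiNew <- match(resKey, ures)
  sequence <- RNA_RESID_MAP[resid[match(ures, resKey)]]
  nModels <- nrow(pdb$xyz)
  xyzIdx <- which(isRNA)
  lapply(seq_len(nModels), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)[xyzIdx, , drop = FALSE]
    atoms <- data.frame(resi = resiNew, atom = elety,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        stringsAsFactors = FALSE)
    conf <- Conformation(sequence, atoms,
                         chain = at$chain[1] %||% "A")
    cc <- chainContinuity(conf)
    conf@breaks <- as.integer(cc$resi[!cc$ok])
    conf
  })
}

#' Write conformations to a PDB file
#'
#' A single conformation gives a plain PDB; a list is written as MODEL /
#' ENDMDL blocks.  Coordinates are written to 3 decimals (PDB convention).
#'
#' @param conf a \code{Conformation} or list of them
#' @param path output file
#' @return the path, invisibly
#' @export
writePDB <- function(conf, path) {
  confs <- if (is(conf, "Conformation")) list(conf) else conf
  renderOne <- function(cc) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    a <- cc@atoms
    bio3d::write.pdb(file = tmp,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$resi, resid = cc@sequence[a$resi],
                     eleno = seq_len(nrow(a)), elety = a$atom,
                     chain = rep(cc@chain, nrow(a)))
    ln <- readLines(tmp, warn = FALSE)
    ln[grepl("^(ATOM|HETATM|TER)", ln)]
  }
  if (length(confs) == 1) {
    writeLines(c(renderOne(confs[[1]]), "END"), path)
  } else {
    out <- character(0)
    for (m in seq_along(confs))
      out <- c(out, sprintf("MODEL     %4d", m), renderOne(confs[[m]]), "ENDMDL")
    writeLines(c(out, "END"), path)
  }
  invisible(path)
}

## -------------------------------------------------------------- tasks

#' Describe a prediction task
#'
#' The four task types: \code{"assemble"} (template assembly only),
#' \code{"sample"} (assembly + template sampling + clustering),
#' \code{"optimize"} (assembly + restraint-guided annealing; pseudoknot
#' pairs in the input become restraints automatically) and \code{"refine"}
#' (standalone optimization of an uploaded model).
#'
#' @param taskType one of assemble, sample, optimize, refine
#' @param sequence,db RNA sequence and dot-bracket (required except for
#'   refine)
#' @param modelFile PDB model to refine (refine only)
#' @param config a \code{\link{predictionConfig}}
#' @param restraintsFile optional restraint file (see
#'   \code{\link{readRestraints}})
#' @param library optional \code{TemplateLibrary} or library directory; the
#'   synthetic fixture library is built when omitted
#' @param outDir output directory
#' @return a TaskSpec list
#' @export
taskSpec <- function(taskType = c("assemble", "sample", "optimize", "refine"),
                     sequence = NULL, db = NULL, modelFile = NULL,
                     config = predictionConfig(), restraintsFile = NULL,
                     library = NULL, outDir = tempfile("ssefold_")) {
  taskType <- match.arg(taskType)
  if (taskType == "refine") {
    if (is.null(modelFile)) stop("refine task requires a model file")
  } else if (is.null(sequence) || is.null(db)) {
    stop(taskType, " task requires sequence and secondary structure")
  }
  structure(list(taskType = taskType, sequence = sequence, db = db,
                 modelFile = modelFile, config = config,
                 restraintsFile = restraintsFile, library = library,
                 outDir = outDir), class = "TaskSpec")
}

resolveLibrary <- function(spec, ss) {
  if (is(spec$library, "TemplateLibrary")) return(spec$library)
  if (is.character(spec$library)) return(loadLibrary(spec$library))
  buildFixtureLibrary(ss, seed = spec$config@seed, nAlternatives = 2)
}

#' Run a prediction task
#'
#' Dispatches the pipeline for the task type, writes the ranked models as
#' PDB files plus a JSON manifest into the output directory, and returns
#' the manifest.
#'
#' @param spec a \code{\link{taskSpec}}
#' @return manifest list (invisibly identical to the written JSON)
#' @export
runTask <- function(spec) {
  cfg <- spec$config
  dir.create(spec$outDir, showWarnings = FALSE, recursive = TRUE)
  restraints <- if (!is.null(spec$restraintsFile))
    readRestraints(spec$restraintsFile) else NULL
  autoRestraints <- 0L
  ss <- NULL
  if (!is.null(spec$sequence)) {
    ss <- parseDotBracket(spec$db, spec$sequence)
    if (nrow(ss@pkPairs)) {
      if (spec$taskType %in% c("optimize", "refine")) {
        pk <- restraintsFromPseudoknot(ss@pkPairs)
        restraints <- rbind(restraints, pk)
        autoRestraints <- nrow(pk)
      } else {
        warning("pseudoknot pairs present but ignored by the '",
                spec$taskType, "' task; use the optimization task")
      }
    }
  }
  models <- NULL; scores <- NULL; sizes <- NULL; prov <- NULL
  if (spec$taskType == "assemble") {
    lib <- resolveLibrary(spec, ss)
    models <- assembleTop(ss, lib, cfg)
    scores <- vapply(models, scoreStructure, numeric(1))
    prov <- lapply(models, function(m) m@provenance$templates)
  } else if (spec$taskType == "sample") {
    lib <- resolveLibrary(spec, ss)
    confs <- sampleTemplates(ss, lib, cfg@samplingSteps, cfg)
    k <- min(cfg@nPredictions, length(confs))
    cl <- kmeansRMSD(confs, k, seed = cfg@seed, atomNames = "C1'")
    ranked <- rankCentroids(cl, confs)
    models <- ranked
    scores <- attr(ranked, "scores")
    sizes <- attr(ranked, "clusterSizes")
  } else {
    if (spec$taskType == "optimize") {
      lib <- resolveLibrary(spec, ss)
      start <- assembleTop(ss, lib, predictionConfig(nPredictions = 1,
                                                     seed = cfg@seed,
                                                     excludeIds = cfg@excludeIds))[[1]]
    } else {
      start <- readPDB(spec$modelFile)[[1]]
      if (is.null(ss)) {
        ann <- annotateInteractions(start)
        sp <- splitPseudoknots(ann@wcPairs)
        ss <- SecondaryStructure(paste(start@sequence, collapse = ""), sp$nested)
        if (nrow(sp$pk)) {
          pk <- restraintsFromPseudoknot(sp$pk)
          restraints <- rbind(restraints, pk)
          autoRestraints <- autoRestraints + nrow(pk)
        }
      }
    }
    elements <- movableElements(ss)
    opt <- samcOptimize(start, elements, restraints = restraints,
                        seed = cfg@seed, ss = ss)
    k <- min(cfg@nPredictions, length(opt$trajectory))
    cl <- kmeansRMSD(opt$trajectory, k, seed = cfg@seed, atomNames = "C1'")
    ranked <- rankCentroids(cl, opt$trajectory)
    models <- ranked
    scores <- attr(ranked, "scores")
    sizes <- attr(ranked, "clusterSizes")
  }
  if (cfg@refine && !is.null(ss))
    models <- lapply(models, relaxConformation, pairs = ss@pairs)
  files <- character(length(models))
  for (m in seq_along(models)) {
    files[m] <- file.path(spec$outDir, sprintf("model_%d.pdb", m))
    writePDB(models[[m]], files[m])
  }
  manifest <- list(
    task = spec$taskType,
    sequence = if (!is.null(ss)) ss@sequence else paste(models[[1]]@sequence, collapse = ""),
    structure = if (!is.null(ss)) dotBracket(ss) else NULL,
    seed = cfg@seed,
    nPredictions = cfg@nPredictions,
    samplingSteps = cfg@samplingSteps,
    models = basename(files),
    scores = as.numeric(scores),
    clusterSizes = if (!is.null(sizes)) as.integer(sizes) else NULL,
    restraints = list(
      n = if (!is.null(restraints)) nrow(restraints) else 0L,
      autoFromPseudoknot = autoRestraints,
      records = if (!is.null(restraints))
        restraints[, c("kind", "i", "j", "lower", "upper", "weight")] else NULL),
    provenance = prov)
  manifest <- manifest[!vapply(manifest, is.null, logical(1))]
  jsonlite::write_json(manifest, file.path(spec$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Validate a task manifest
#'
#' Checks a manifest (list or JSON file) against the shipped schema
#' (required fields and types, \code{inst/schema/manifest-schema.json}).
#'
#' @param manifest manifest list or path to a manifest JSON
#' @return TRUE, or a character vector of problems
#' @export
validateManifest <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  schema <- jsonlite::read_json(system.file("schema", "manifest-schema.json",
                                            package = "ssefold"),
                                simplifyVector = TRUE)
  problems <- character(0)
  for (f in schema$required)
    if (is.null(manifest[[f]])) problems <- c(problems, paste("missing field:", f))
  typeOk <- function(x, type) switch(type,
    string = is.character(x), number = is.numeric(x),
    integer = is.numeric(x) && all(x == round(x)),
    array = is.vector(x) || is.list(x), object = is.list(x), TRUE)
  for (f in names(schema$properties)) {
    if (is.null(manifest[[f]])) next
    if (!typeOk(manifest[[f]], schema$properties[[f]]$type))
      problems <- c(problems, paste("wrong type for field:", f))
  }
  if (length(problems)) problems else TRUE
}

#' Run predictions in batch
#'
#' Two modes: one sequence with several secondary structures, or equal
#' numbers of sequences and structures paired line by line.  Each pairing
#' runs as an independent task with a seed derived from the master seed.
#'
#' @param sequences character vector of sequences (length 1 or m)
#' @param structures character vector of dot-bracket strings (length m)
#' @param taskType task type applied to every pairing
#' @param config master \code{\link{predictionConfig}}; job i uses seed
#'   \code{seed + i - 1}
#' @param outDir parent output directory (one subdirectory per job)
#' @return list of manifests
#' @export
runBatch <- function(sequences, structures, taskType = "assemble",
                     config = predictionConfig(), outDir = tempfile("batch_")) {
  m <- length(structures)
  if (length(sequences) == 1) sequences <- rep(sequences, m)
  if (length(sequences) != m)
    stop("sequence and structure sections should contain the same number of lines")
  lapply(seq_len(m), function(i) {
    cfg <- config
    cfg@seed <- config@seed + i - 1
    runTask(taskSpec(taskType, sequence = sequences[i], db = structures[i],
                     config = cfg,
                     outDir = file.path(outDir, sprintf("job_%d", i))))
  })
}
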
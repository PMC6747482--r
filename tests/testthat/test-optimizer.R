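# Restraints and simulated-annealing Monte Carlo refinement.

test_that("pseudoknot pairs map one-to-one onto base-pair restraints", {
  expect_equal(nrow(restraintsFromPseudoknot(NULL)), 0)
  r <- restraintsFromPseudoknot(rbind(c(5, 14), c(6, 13)))
  expect_equal(nrow(r), 2)
  expect_equal(r$kind, rep("base_pair", 2))
  expect_equal(r$i, c(5, 6)); expect_equal(r$j, c(14, 13))

  # the restraint bounds bracket the C1'-C1' distance of the ideal helix
  helix <- idealHelix6()
  d <- vnorm(atomCoords(helix, 1, "C1'")[1, ] - atomCoords(helix, 12, "C1'")[1, ])
  expect_gte(d, r$lower[1]); expect_lte(d, r$upper[1])
})

test_that("the coevolution top-N rule floors 0.2 x length", {
  expect_equal(dcaRestraintCount(75), 15L)
  expect_equal(dcaRestraintCount(0), 0L)
  expect_equal(dcaRestraintCount(78), 15L)   # floor(15.6)
  expect_error(dcaRestraintCount(-1), ">= 0")
})

test_that("restraint files round-trip and reject malformed records", {
  r <- rbind(restraintsFromPseudoknot(rbind(c(2, 9)), weight = 2),
             data.frame(kind = "distance", i = 3, j = 8, lower = 8, upper = 12,
                        weight = 1.5, stringsAsFactors = FALSE))
  f <- tempfile(fileext = ".rst")
  writeRestraints(r, f)
  r2 <- readRestraints(f)
  expect_equal(r2$kind, r$kind)
  expect_equal(r2$i, r$i); expect_equal(r2$j, r$j)
  expect_equal(r2$weight, r$weight)
  expect_equal(r2$lower[2], 8); expect_equal(r2$upper[2], 12)

  writeLines("BOND 1 2", f)
  expect_error(readRestraints(f), "unknown record")
  writeLines("DIST 1 2", f)
  expect_error(readRestraints(f), "DIST needs")
})

test_that("the energy is a flat-bottomed weighted sum", {
  helix <- idealHelix6()
  ss <- SecondaryStructure("GGCAGCGCUGCC", cbind(1:6, 12:7))
  terms <- optimizerEnergy(stat = 0)

  # clean fixture: connectivity + clash + secondary-structure terms vanish
  expect_equal(conformationEnergy(helix, terms, ss = ss), 0)

  # satisfied restraint scores exactly zero (flat bottom)
  d <- vnorm(atomCoords(helix, 1, "C1'")[1, ] - atomCoords(helix, 12, "C1'")[1, ])
  sat <- data.frame(kind = "distance", i = 1, j = 12, lower = d - 1,
                    upper = d + 1, weight = 1, stringsAsFactors = FALSE)
  expect_equal(conformationEnergy(helix, terms, restraints = sat), 0)

  # violated restraint contributes weight * delta^2
  delta <- 2.5
  viol <- data.frame(kind = "distance", i = 1, j = 12, lower = d + delta,
                     upper = d + delta + 1, weight = 1.3, stringsAsFactors = FALSE)
  expect_equal(conformationEnergy(helix, terms, restraints = viol),
               terms@restraint * 1.3 * delta^2, tolerance = 1e-9)
  expect_equal(restraintViolations(helix, viol), delta, tolerance = 1e-9)
})

test_that("the sampler honours its degenerate and limiting cases", {
  fx <- pkFixture()
  el <- fx$elements

  # zero sweeps: trajectory is just the start
  z <- samcOptimize(fx$assembled, el, schedule = annealSchedule(sweeps = 0), seed = 1)
  expect_equal(length(z$trajectory), 1)
  expect_identical(z$trajectory[[1]]@atoms, fx$assembled@atoms)

  # empty element list is an error
  expect_error(samcOptimize(fx$assembled, el[0, ], seed = 1), "nothing to move")

  # near-zero temperature rejects uphill proposals: starting from a clean
  # optimum, energy can only stay put
  cold <- annealSchedule(tLow = 1e-8, tHigh = 1e-7, heatRungs = 2,
                         coolRungs = 2, sweeps = 50)
  r <- samcOptimize(fx$groundTruth, el, restraints = fx$restraints,
                    schedule = cold, seed = 3, ss = fx$ss)
  e0 <- conformationEnergy(fx$groundTruth, optimizerEnergy(),
                           restraints = fx$restraints, ss = fx$ss)
  expect_lte(r$bestEnergy, e0 + 1e-9)
  expect_lt(r$acceptance, 0.5)
})

test_that("a flat energy accepts everything with symmetric displacements", {
  fx <- pkFixture()
  flat <- new("OptimizerEnergy", conn = 0, clash = 0, ss = 0, restraint = 0,
              stat = 0)
  sched <- annealSchedule(heatRungs = 2, coolRungs = 2, sweeps = 500)
  r <- samcOptimize(fx$assembled, fx$elements, terms = flat, schedule = sched,
                    seed = 11)
  expect_equal(r$acceptance, 1)
  # net drift of the centroid stays small relative to the path length
  d0 <- colMeans(atomCoords(fx$assembled))
  d1 <- colMeans(atomCoords(r$trajectory[[length(r$trajectory)]]))
  expect_lt(vnorm(d1 - d0), 30)
})

test_that("nested pairs stay within Watson-Crick bounds along the trajectory", {
  fx <- pkFixture()
  sched <- annealSchedule(heatRungs = 5, coolRungs = 5, sweeps = 40)
  r <- samcOptimize(fx$assembled, fx$elements, restraints = fx$restraints,
                    schedule = sched, seed = 5, ss = fx$ss)
  for (conf in r$trajectory) {
    for (k in seq_len(nrow(fx$ss@pairs))) {
      i <- fx$ss@pairs[k, 1]; j <- fx$ss@pairs[k, 2]
      d <- vnorm(atomCoords(conf, i, "C1'")[1, ] - atomCoords(conf, j, "C1'")[1, ])
      expect_gte(d, 9.0); expect_lte(d, 11.5)
    }
  }
})

test_that("a fixed seed reproduces the trajectory bit for bit", {
  fx <- pkFixture()
  sched <- annealSchedule(heatRungs = 4, coolRungs = 4, sweeps = 30)
  a <- samcOptimize(fx$assembled, fx$elements, restraints = fx$restraints,
                    schedule = sched, seed = 99, ss = fx$ss)
  b <- samcOptimize(fx$assembled, fx$elements, restraints = fx$restraints,
                    schedule = sched, seed = 99, ss = fx$ss)
  expect_identical(lapply(a$trajectory, function(c) c@atoms),
                   lapply(b$trajectory, function(c) c@atoms))
  expect_identical(a$energies, b$energies)
  c <- samcOptimize(fx$assembled, fx$elements, restraints = fx$restraints,
                    schedule = sched, seed = 100, ss = fx$ss)
  expect_false(identical(a$energies, c$energies))
})

test_that("restraint violations shrink as cooling proceeds", {
  fx <- pkFixture()
  # median best-violation over seeds is non-increasing across the cooling
  # phase, measured at three checkpoints of the recorded trajectory
  sched <- annealSchedule(heatRungs = 5, coolRungs = 15, sweeps = 60)
  atStart <- atMid <- atEnd <- numeric(0)
  for (sd in 1:10) {
    r <- samcOptimize(fx$assembled, fx$elements, restraints = fx$restraints,
                      schedule = sched, seed = 300 + sd, ss = fx$ss)
    v <- vapply(r$trajectory, function(cf)
      max(restraintViolations(cf, fx$restraints)), numeric(1))
    cool <- v[(5 + 1):length(v)]
    best <- cummin(cool)
    atStart <- c(atStart, best[1])
    atMid <- c(atMid, best[ceiling(length(best) / 2)])
    atEnd <- c(atEnd, best[length(best)])
  }
  expect_lte(median(atMid), median(atStart))
  expect_lte(median(atEnd), median(atMid))
})

test_that("the energy minimum of a trajectory is found by exhaustive scan", {
  fx <- pkFixture()
  sched <- annealSchedule(heatRungs = 3, coolRungs = 3, sweeps = 20)
  r <- samcOptimize(fx$assembled, fx$elements, restraints = fx$restraints,
                    schedule = sched, seed = 8, ss = fx$ss)
  best <- bestOf(r$trajectory, restraints = fx$restraints, ss = fx$ss)
  e <- vapply(r$trajectory, conformationEnergy, numeric(1),
              terms = optimizerEnergy(), restraints = fx$restraints, ss = fx$ss)
  expect_identical(best@atoms, r$trajectory[[which.min(e)]]@atoms)
  expect_identical(bestOf(r$trajectory[1])@atoms, r$trajectory[[1]]@atoms)
  expect_error(bestOf(list()), "empty")
})
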
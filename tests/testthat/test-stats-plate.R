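test_that("edge-effect report uses the 36/60 plate partition", {
  g <- generatePlate(plateScenario(nPerWellLambda = 30, seed = 201L))
  sp <- summarizePlate(g$plate, traits = "tof")
  rep <- edgeEffectTest(sp, trait = "tof")
  expect_length(rep@edgeWells, 36L)
  expect_length(rep@centerWells, 60L)
  res <- rep@results
  expect_equal(res$n_edge, 36L)
  expect_equal(res$n_center, 60L)
  expect_true(res$testable)
})

test_that("a strong edge gradient is detected", {
  g <- generatePlate(plateScenario(nPerWellLambda = 30, edgeEffect = 5,
                                   seed = 202L))
  sp <- summarizePlate(g$plate, traits = "tof")
  rep <- edgeEffectTest(sp, trait = "tof")
  expect_lt(rep@results$p, 0.01)
})

test_that("testing all traits reports untestable ones instead of failing", {
  g <- generatePlate(plateScenario(nPerWellLambda = 10, seed = 203L))
  p <- g$plate
  p@observations$green <- NA_real_  # a trait with no data anywhere
  sp <- summarizePlate(p, traits = c("tof", "ext", "green"))
  rep <- edgeEffectTest(sp, trait = "all")
  res <- rep@results
  expect_setequal(res$trait, c("n", "tof", "ext", "green"))
  expect_false(res$testable[res$trait == "green"])
  expect_true(all(res$testable[res$trait != "green"]))
  # single-trait mode errors on the same degenerate trait
  expect_error(edgeEffectTest(sp, trait = "green"), "insufficient data")
  # BH adjustment is monotone and off by default
  repBH <- edgeEffectTest(sp, trait = "all", adjust = "BH")
  expect_true(all(repBH@results$p_adjusted >= repBH@results$p,
                  na.rm = TRUE))
  expect_equal(res$p_adjusted, res$p)
})

test_that("two-ring edge definition widens the edge population", {
  g <- generatePlate(plateScenario(nPerWellLambda = 10, seed = 204L))
  sp <- summarizePlate(g$plate, traits = "tof")
  rep <- edgeEffectTest(sp, trait = "tof", edgeDepth = 2L)
  expect_length(rep@edgeWells, 64L)
  expect_equal(rep@results$n_edge, 64L)
})

test_that("correlation matrices match a naive two-pass Pearson oracle", {
  set.seed(211)
  for (i in 1:5) {
    g <- generatePlate(plateScenario(nPerWellLambda = 8,
                                     seed = 2100L + i))
    sp <- summarizePlate(normalizePlate(g$plate))
    cm <- correlationMatrix(sp)
    co <- cm@coefficients
    expect_equal(co, t(co))
    expect_equal(unname(diag(co)), rep(1, ncol(co)))
    d <- wellData(sp)
    picks <- expand.grid(a = sample(rownames(co), 4),
                         b = sample(colnames(co), 4),
                         stringsAsFactors = FALSE)
    for (k in seq_len(nrow(picks))) {
      a <- picks$a[k]; b <- picks$b[k]
      if (a == b) next
      expect_equal(co[a, b], naivePearson(d[[a]], d[[b]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("affinely related traits correlate at exactly +/- 1", {
  g <- generatePlate(plateScenario(nPerWellLambda = 10, seed = 221L))
  sp <- summarizePlate(g$plate, traits = "tof")
  d <- wellData(sp)
  d$fake <- -2 * d$mean_tof + 3
  sp@data <- d
  cm <- correlationMatrix(sp, traits = c("mean_tof", "fake"))
  expect_equal(cm@coefficients["mean_tof", "fake"], -1, tolerance = 1e-12)
  d$fake2 <- 0.5 * d$mean_tof + 10
  sp@data <- d
  cm2 <- correlationMatrix(sp, traits = c("mean_tof", "fake2"))
  expect_equal(cm2@coefficients["mean_tof", "fake2"], 1,
               tolerance = 1e-12)
})

test_that("sparse pairs are missing and all-sparse input errors", {
  g <- generatePlate(plateScenario(nPerWellLambda = 20, seed = 231L))
  sp <- summarizePlate(g$plate, traits = c("tof", "ext"))
  d <- wellData(sp)
  d$rare <- NA_real_
  d$rare[1:2] <- c(1, 2)  # only two complete pairs possible
  sp@data <- d
  cm <- correlationMatrix(sp, traits = c("mean_tof", "rare"))
  expect_true(is.na(cm@coefficients["mean_tof", "rare"]))
  expect_equal(cm@pairCounts["mean_tof", "rare"], 2L)
  d$rare[1:2] <- NA_real_
  sp@data <- d
  expect_error(correlationMatrix(sp, traits = "rare"),
               "insufficient data")
})

test_that("between-plate mode pairs trait columns across matched wells", {
  ga <- generatePlate(plateScenario(nPerWellLambda = 10, seed = 241L))
  gb <- generatePlate(plateScenario(nPerWellLambda = 10, seed = 242L))
  sa <- summarizePlate(ga$plate, traits = "tof")
  sb <- summarizePlate(gb$plate, traits = "tof")
  cm <- correlationMatrix(sa, sb, traits = c("mean_tof", "n"))
  expect_equal(dim(cm@coefficients), c(2L, 2L))
  expect_equal(cm@mode, "between")
  da <- wellData(sa); db <- wellData(sb)
  shared <- intersect(da$well, db$well)
  want <- naivePearson(da$mean_tof[match(shared, da$well)],
                       db$n[match(shared, db$well)])
  expect_equal(unname(cm@coefficients[1, 2]), want, tolerance = 1e-9)
})

test_that("dose-response groups wells by (strain, dose) with exact means", {
  # four strains x five doses in column blocks; known per-group constants
  strains <- rep(paste0("S", 1:4), each = 24)
  doses <- rep(rep(c(0, 1, 5, 10, 50), length.out = 24), 4)
  base <- outer(1:4, c(10, 20, 30, 40, 50))  # value for (strain, dose)
  wellVal <- numeric(96)
  for (i in 1:96) {
    s <- match(strains[i], paste0("S", 1:4))
    k <- match(doses[i], c(0, 1, 5, 10, 50))
    wellVal[i] <- base[s, k]
  }
  p <- newRawPlate(well = rep(allWells(), each = 2),
                   tof = rep(wellVal, each = 2), ext = 1)
  sp <- summarizePlate(p, traits = "tof")
  tab <- doseResponseTable(sp, strains, doses, trait = "tof")
  expect_equal(nrow(tab@groups), 20L)
  for (k in seq_len(nrow(tab@groups))) {
    s <- match(tab@groups$strain[k], paste0("S", 1:4))
    dIdx <- match(tab@groups$dose[k], c(0, 1, 5, 10, 50))
    expect_equal(tab@groups$mean[k], base[s, dIdx])
  }
  # every (strain, dose) group mean equals the mean of its well points
  pts <- tab@points
  for (k in seq_len(nrow(tab@groups))) {
    sel <- pts$strain == tab@groups$strain[k] &
      pts$dose == tab@groups$dose[k]
    expect_equal(mean(pts$value[sel]), tab@groups$mean[k])
    expect_equal(sum(sel), tab@groups$n_wells[k])
  }
})

test_that("constant traits give constant group means", {
  p <- newRawPlate(well = allWells(), tof = 7, ext = 1)
  sp <- summarizePlate(p, traits = "tof")
  tab <- doseResponseTable(sp, rep("S1", 96), rep(1:4, 24), trait = "tof")
  expect_true(all(tab@groups$mean == 7))
})

test_that("all-missing groups stay present with zero wells", {
  p <- newRawPlate(well = allWells(), tof = 1:96, ext = 1)
  sp <- summarizePlate(p, traits = "tof")
  sp <- suppressWarnings(removeWells(sp, allWells()[1:12], mode = "na"))
  strains <- c(rep("gone", 12), rep("S1", 84))
  doses <- rep(1, 96)
  tab <- doseResponseTable(sp, strains, doses, trait = "tof")
  gone <- tab@groups[tab@groups$strain == "gone", ]
  expect_equal(nrow(gone), 1L)
  expect_equal(gone$n_wells, 0L)
  expect_true(is.na(gone$mean))
  expect_error(doseResponseTable(sp, strains[-1], doses, trait = "tof"),
               "invalid metadata")
})

test_that("the all-traits map equals individually computed tables", {
  g <- generatePlate(plateScenario(nPerWellLambda = 10, seed = 251L))
  sp <- summarizePlate(normalizePlate(g$plate))
  strains <- rep(paste0("S", 1:4), each = 24)
  doses <- rep(1:6, 16)
  suppressMessages(maps <- doseResponseAllTraits(sp, strains, doses))
  expect_setequal(names(maps), c("n", plateTraits(sp)))
  for (tr in c("n", "tof", "norm_ext")) {
    solo <- doseResponseTable(sp, strains, doses, trait = tr)
    expect_equal(maps[[tr]]@groups, solo@groups)
    expect_equal(maps[[tr]]@points, solo@points)
  }
  # an all-missing trait is skipped with a log message
  p <- g$plate
  p@observations$red <- NA_real_
  sp2 <- summarizePlate(p, traits = c("tof", "red"))
  expect_message(maps2 <- doseResponseAllTraits(sp2, strains, doses),
                 "skipping trait red")
  expect_false("red" %in% names(maps2))
})
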
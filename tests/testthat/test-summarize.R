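test_that("normalization divides channels by length and guards tof = 0", {
  p <- handPlate()
  np <- normalizePlate(p)
  obs <- observations(np)
  expect_equal(obs$norm_ext[1], 1 / 10 * 1)
  expect_equal(obs$norm_ext[3], 3 / 30)
  expect_equal(obs$norm_green[2], 0.2 / 20)
  # tof = 0 gives missing norm values and is reported
  expect_true(is.na(obs$norm_ext[5]))
  expect_equal(parseReport(np)$zeroTof, 1L)
  # original fields untouched
  expect_equal(obs$ext, observations(p)$ext)
})

test_that("norm_x * tof reproduces x wherever tof > 0", {
  set.seed(31)
  for (i in 1:10) {
    g <- generatePlate(plateScenario(nPerWellLambda = 5,
                                     seed = 3000L + i))
    obs <- observations(normalizePlate(g$plate))
    pos <- obs$tof > 0
    for (tr in c("ext", "green", "yellow", "red")) {
      got <- obs[[paste0("norm_", tr)]][pos] * obs$tof[pos]
      expect_equal(got, obs[[tr]][pos], tolerance = 1e-9)
    }
  }
})

test_that("per-well statistics match forced arithmetic on small wells", {
  p <- newRawPlate(well = c(rep("A1", 10), "C3"),
                   tof = c(1:10, 42), ext = 1)
  sp <- summarizePlate(p)
  d <- wellData(sp)
  a1 <- d[d$well == "A1", ]
  expect_equal(a1$n, 10L)
  expect_equal(a1$mean_tof, 5.5)
  expect_equal(a1$median_tof, 5.5)
  expect_equal(a1$min_tof, 1)
  expect_equal(a1$max_tof, 10)
  expect_equal(a1$var_tof, var(1:10))
  # single observation: var missing, all quantiles equal the value
  c3 <- d[d$well == "C3", ]
  expect_equal(c3$n, 1L)
  expect_true(is.na(c3$var_tof))
  expect_equal(unlist(c3[c("min_tof", "q10_tof", "q25_tof",
                           "median_tof", "q75_tof", "q90_tof",
                           "max_tof")], use.names = FALSE),
               rep(42, 7))
})

test_that("summaries match a naive sort-and-scan oracle on random plates", {
  set.seed(41)
  for (i in 1:10) {
    g <- generatePlate(plateScenario(nPerWellLambda = 8,
                                     bubbleFraction = 0.1,
                                     seed = 4000L + i))
    np <- normalizePlate(g$plate)
    sp <- summarizePlate(np)
    d <- wellData(sp)
    obs <- observations(np)
    wl <- paste0(obs$row, obs$col)
    for (w in sample(d$well, 8)) {
      for (tr in c("tof", "ext", "norm_ext", "green")) {
        want <- naiveStats(obs[[tr]][wl == w])
        got <- unlist(d[d$well == w,
                        paste0(names(want), "_", tr)],
                      use.names = FALSE)
        expect_equal(got, unname(want), tolerance = 1e-9)
      }
    }
  }
})

test_that("summarization is invariant to observation order", {
  g <- generatePlate(plateScenario(nPerWellLambda = 6, seed = 51L))
  p <- g$plate
  perm <- p
  set.seed(52)
  ord <- sample(nrow(observations(p)))
  perm@observations <- observations(p)[ord, ]
  rownames(perm@observations) <- NULL
  expect_equal(wellData(summarizePlate(perm)),
               wellData(summarizePlate(p)))
})

test_that("quantile ordering invariant holds on random wells", {
  set.seed(61)
  for (i in 1:20) {
    g <- generatePlate(plateScenario(nPerWellLambda = 7,
                                     seed = 6000L + i))
    d <- wellData(summarizePlate(g$plate, traits = "tof"))
    ok <- !is.na(d$median_tof)
    expect_true(all(d$min_tof[ok] <= d$q10_tof[ok] + 1e-12))
    expect_true(all(d$q10_tof[ok] <= d$q25_tof[ok] + 1e-12))
    expect_true(all(d$q25_tof[ok] <= d$median_tof[ok] + 1e-12))
    expect_true(all(d$median_tof[ok] <= d$q75_tof[ok] + 1e-12))
    expect_true(all(d$q75_tof[ok] <= d$q90_tof[ok] + 1e-12))
    expect_true(all(d$q90_tof[ok] <= d$max_tof[ok] + 1e-12))
  }
})

test_that("log statistics use positive values only and count exclusions", {
  p <- newRawPlate(well = rep("A1", 4), tof = c(1, 2, 4, 8),
                   ext = c(0, 1, exp(1), exp(2)))
  sp <- summarizePlate(p, withLog = TRUE, traits = "ext")
  d <- wellData(sp)
  expect_equal(d$nlogexcl_ext, 1L)
  expect_equal(d$log_mean_ext, mean(c(0, 1, 2)))
  expect_equal(d$log_max_ext, 2)
  # tof has no non-positive values
  sp2 <- summarizePlate(p, withLog = TRUE, traits = "tof")
  expect_equal(wellData(sp2)$nlogexcl_tof, 0L)
  expect_equal(wellData(sp2)$log_mean_tof, mean(log(c(1, 2, 4, 8))))
})

test_that("strain vectors attach positionally and are validated", {
  strains <- paste0("S", rep(1:8, each = 12))
  g <- generatePlate(plateScenario(nPerWellLambda = 3, seed = 71L))
  sp <- summarizePlate(g$plate, strains = strains)
  d <- wellData(sp)
  expect_equal(d$strain[d$well == "A5"], "S1")
  expect_equal(d$strain[d$well == "H12"], "S8")
  expect_error(summarizePlate(g$plate, strains = strains[-1]),
               "invalid metadata")
})

test_that("removeWells supports na and drop modes on both data kinds", {
  g <- generatePlate(plateScenario(nPerWellLambda = 5, seed = 81L))
  sp <- fillWells(summarizePlate(g$plate))
  dropped <- removeWells(sp, "A1", mode = "drop")
  expect_equal(nrow(wellData(dropped)), 95L)
  expect_false("A1" %in% wells(dropped))
  naed <- removeWells(sp, c("A1", "b02"), mode = "na")
  d <- wellData(naed)
  expect_equal(nrow(d), 96L)
  expect_true(all(is.na(unlist(d[d$well %in% c("A1", "B2"),
                                 setdiff(names(d),
                                         c("well", "strain", "dose"))]))))
  # untouched elsewhere
  expect_equal(d[d$well == "C3", ], wellData(sp)[wellData(sp)$well == "C3", ])
  # raw plate variant
  pr <- removeWells(g$plate, "A1", mode = "drop")
  expect_false("A1" %in% wells(pr))
  prna <- removeWells(g$plate, "A1", mode = "na")
  obs <- observations(prna)
  expect_equal(nrow(obs), nrow(observations(g$plate)))
  expect_true(all(is.na(obs$tof[obs$row == "A" & obs$col == 1])))
  # absent well is a warning, not an error; invalid label errors
  expect_warning(removeWells(dropped, "A1"), "not present")
  expect_error(removeWells(sp, "A13"), "invalid well")
})

test_that("drop-mode removal commutes with summarization", {
  g <- generatePlate(plateScenario(nPerWellLambda = 5, seed = 91L))
  kill <- c("A1", "D6", "H12")
  a <- wellData(summarizePlate(
    suppressWarnings(removeWells(g$plate, kill, mode = "drop"))))
  b <- wellData(suppressWarnings(
    removeWells(summarizePlate(g$plate), kill, mode = "drop")))
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("fillWells completes to 96 row-major entries and is idempotent", {
  g <- generatePlate(plateScenario(
    nPerWellLambda = 50,
    emptyWells = allWells()[seq(2, 96, by = 3)], seed = 101L))
  sp <- summarizePlate(g$plate)
  expect_lt(nrow(wellData(sp)), 96L)
  filled <- fillWells(sp)
  d <- wellData(filled)
  expect_equal(nrow(d), 96L)
  expect_equal(d$well, allWells())
  added <- setdiff(allWells(), wells(sp))
  statCols <- setdiff(names(d), c("well", "strain", "dose"))
  expect_true(all(is.na(unlist(d[d$well %in% added, statCols]))))
  expect_equal(d[d$well %in% wells(sp), ][order(wellOrder(wells(sp))), ],
               wellData(sp)[order(wellOrder(wells(sp))), ],
               ignore_attr = TRUE)
  # idempotence and identity on complete input
  expect_equal(wellData(fillWells(filled)), d)
  # duplicates are corrupt
  dup <- sp
  dup@data <- rbind(wellData(sp), wellData(sp)[1, ])
  expect_error(fillWells(dup), "corrupt summary")
})

test_that("summaries round-trip through delimited export", {
  g <- generatePlate(plateScenario(nPerWellLambda = 4, seed = 111L))
  sp <- fillWells(summarizePlate(normalizePlate(g$plate),
                                 strains = rep(paste0("S", 1:8),
                                               each = 12)))
  for (ext in c(".tsv", ".csv")) {
    f <- tempfile(fileext = ext)
    writeSummary(sp, f)
    # missing values export as empty fields, not literal "NA"
    expect_false(any(grepl("NA", readLines(f)[1:2], fixed = TRUE)))
    back <- readSummary(f)
    expect_equal(wellData(back)$well, wellData(sp)$well)
    expect_equal(wellData(back)$n, wellData(sp)$n)
    expect_equal(wellData(back)$mean_tof, wellData(sp)$mean_tof,
                 tolerance = 1e-9)
    expect_equal(wellData(back)$strain, wellData(sp)$strain)
  }
})
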
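test_that("oxygenation classification is reversible except for necrosis", {
  lat <- newLattice(c(12L, 4L, 4L))
  lat <- addCells(lat, list(0:3, 4:7, 8:11), "NORMAL")
  mk <- function(vals) {
    cf <- newChemField("CELLULAR_PO2", lat, c(MEDIUM = 0))
    for (i in 1:3) cf@grid[(i - 1) * 4 + 1:4] <- vals[i]
    cf
  }
  thr <- outcomeThresholds()
  # 90 -> normoxic, 4.9 -> hypoxic, 0.5 -> necrotic
  r1 <- classifyCells(lat, mk(c(90, 4.9, 0.5)), thr)
  expect_identical(unname(r1$counts), c(1L, 1L, 1L))
  st1 <- cellRegistry(r1$lattice)$oxygenState
  expect_identical(st1, c("NORMOXIC", "HYPOXIC", "NECROTIC"))
  # recovery: hypoxic cell returns to normoxic, necrotic stays necrotic
  r2 <- classifyCells(r1$lattice, mk(c(90, 5.1, 50)), thr)
  st2 <- cellRegistry(r2$lattice)$oxygenState
  expect_identical(st2, c("NORMOXIC", "NORMOXIC", "NECROTIC"))
  # necrotic cells stop consuming oxygen
  rates <- mrtvasc:::.uptakeRates(r2$lattice, mk(c(90, 90, 90))@grid,
                                  oxygenParams())
  expect_true(all(rates[9:12] == 0))
  expect_true(all(rates[1:4] > 0))
})

test_that("uniformity statistic measures the spread of local densities", {
  lat <- newLattice(c(16L, 16L, 16L))
  g <- expand.grid(x = 0:15, y = 0:15, z = 0:15)
  # uniform half-density everywhere: SD must be 0
  sel <- (g$x + g$y + g$z) %% 2 == 0
  latU <- addCells(lat, list(voxelIndex0(lat, g$x[sel], g$y[sel],
                                         g$z[sel])), "VASCULAR")
  resU <- uniformityStatistic(latU, subregionEdge = 4L)
  expect_equal(resU$sd, 0)
  # half the subregions at density d, half empty: SD = d / 2
  selH <- g$x < 8
  latH <- addCells(lat, list(voxelIndex0(lat, g$x[selH], g$y[selH],
                                         g$z[selH])), "VASCULAR")
  resH <- uniformityStatistic(latH, subregionEdge = 4L)
  expect_equal(resH$sd, 0.5)
  expect_null(resH$uniformityDecrease)
  withRef <- uniformityStatistic(latH, subregionEdge = 4L,
                                 referenceSD = 0.25)
  expect_equal(withRef$uniformityDecrease, 1)
  # permutation invariance: the statistic is a set function of densities
  expect_equal(sd(resH$densities) * sqrt(1 - 1 / length(resH$densities)),
               resH$sd, tolerance = 1e-12)
  expect_error(uniformityStatistic(latH, subregionEdge = 32L), "larger")
  expect_error(uniformityStatistic(latH, subregionEdge = 5L), "tile")
})

test_that("unperfused fraction counts depleted surviving vascular cells", {
  lat <- tubeLattice(20L)
  vasc <- newChemField("VASCULAR_PO2", lat, c(VASCULAR = 0),
                       boundary = "clamped_cells")
  vox <- which(lat@grid > 0L)
  vasc@grid[vox] <- 50
  thr <- outcomeThresholds()
  expect_equal(unperfusedFraction(lat, vasc, thr), 0)
  vasc@grid[vox] <- 0.2
  expect_equal(unperfusedFraction(lat, vasc, thr), 1)
  # threshold 0 means nothing can count as depleted
  expect_equal(unperfusedFraction(lat, vasc,
                                  outcomeThresholds(unperfusedPO2 = 0)), 0)
  empty <- newLattice(c(4L, 4L, 4L))
  expect_error(unperfusedFraction(empty, vasc), "no surviving")
})

test_that("scenario summary computes depletion and rank correlation", {
  tab <- data.frame(scenario = c("NORMAL", "D20"),
                    meanPre = c(20, 10), meanPost = c(20, 2),
                    uniformityDecrease = c(0, 0.2))
  s <- summarizeRun(tab)
  expect_equal(s$table$depletion, c(0, 0.8))
  expect_equal(s$rankCorrelation, 1)
  tab3 <- data.frame(scenario = c("a", "b", "c"),
                     meanPre = c(20, 16, 12), meanPost = c(16, 8, 2),
                     uniformityDecrease = c(0.05, 0.10, 0.18))
  expect_equal(summarizeRun(tab3)$rankCorrelation, 1)
  expect_error(summarizeRun(tab[1, , drop = FALSE]))
})

test_that("outcome fractions partition the initial population", {
  lat <- newLattice(c(12L, 4L, 4L))
  lat <- addCells(lat, list(0:3, 4:7, 8:11, 12:15), "NORMAL")
  cf <- newChemField("CELLULAR_PO2", lat, c(MEDIUM = 0))
  cf@grid[1:4] <- 90
  cf@grid[5:8] <- 3
  cf@grid[9:12] <- 0.2
  res <- classifyCells(lat, cf, outcomeThresholds())
  lat <- res$lattice
  # cell 4 was removed by radiation before classification
  lat@cells$alive[4] <- FALSE
  fr <- mrtvasc:::.outcomeFractions(lat, nInitial = 4L, nRadiationDead = 1L)
  expect_equal(sum(fr[c("normoxic", "hypoxic", "necrotic",
                        "radiationDead")]), 1)
  expect_equal(unname(fr["totalDead"]),
               unname(fr["necrotic"] + fr["radiationDead"]))
})
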
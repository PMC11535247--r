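test_that("tumor seeding places one cell of the initial volume at center", {
  lat <- newLattice(rep(48L, 3))
  lat <- seedTumor(lat)
  reg <- cellRegistry(lat)
  tum <- reg[reg$type == "TUMOR", ]
  expect_identical(nrow(tum), 1L)
  # 3375 um^3 at 6 um voxels = 15.625 voxels
  expect_equal(tum$targetVolume, 3375 / 216)
  expect_identical(tum$volume, 16) # ceiling to whole voxels
  ctr <- (48 - 1) / 2
  expect_lt(max(abs(c(tum$cx, tum$cy, tum$cz) - ctr)), 1)
  expect_error(seedTumor(lat), "already")
})

test_that("tumor seeding avoids vascular voxels", {
  lat <- newLattice(rep(32L, 3))
  # vascular slab through the center
  g <- expand.grid(x = 14:17, y = 0:31, z = 14:17)
  lat <- addCells(lat, list(voxelIndex0(lat, g$x, g$y, g$z)), "VASCULAR")
  nVasc <- sum(lat@grid > 0L)
  lat <- seedTumor(lat)
  reg <- cellRegistry(lat)
  vid <- reg$id[reg$type == "VASCULAR"]
  expect_identical(sum(lat@grid %in% vid), nVasc)
})

test_that("growth increments follow Michaelis-Menten kinetics", {
  lat <- newLattice(rep(24L, 3))
  lat <- seedTumor(lat)
  params <- tumorGrowthParams(maxGrowthRate = 6.75, growthKm = 5)
  tv0 <- cellRegistry(lat)$targetVolume[1]
  mk <- function(v) newChemField("CELLULAR_PO2", lat, c(MEDIUM = 0),
                                 init = v)
  # zero oxygen: no growth
  out <- growthUpdate(lat, mk(0), params)
  expect_equal(cellRegistry(out)$targetVolume[1], tv0)
  # at half-saturation: half the maximum rate (in voxels)
  out <- growthUpdate(lat, mk(5), params)
  expect_equal(cellRegistry(out)$targetVolume[1],
               tv0 + 6.75 / 216 / 2)
  # far above Km the increment saturates: time from 3375 to 6750 um^3 is
  # ~ 3375 / maxGrowthRate steps of the saturated increment
  inc <- cellRegistry(growthUpdate(lat, mk(5000), params))$targetVolume[1] -
    tv0
  expect_equal(inc * 3375 / 6.75, 3375 / 216, tolerance = 2e-3)
})

test_that("division splits a symmetric cell into equal contiguous halves", {
  lat <- newLattice(rep(16L, 3))
  g <- expand.grid(x = 4:11, y = 7:8, z = 7:8) # 2 x 2 x 8 along x
  lat <- addCells(lat, list(voxelIndex0(lat, g$x, g$y, g$z)), "TUMOR",
                  targetVolume = 6750 / 216)
  set.seed(2)
  res <- divideCell(lat, 1L)
  reg <- cellRegistry(res$lattice)
  expect_identical(nrow(reg), 2L)
  expect_true(all(reg$volume == 16))
  expect_true(all(reg$type == "TUMOR"))
  expect_true(all(reg$targetVolume == 3375 / 216))
  # the split plane is orthogonal to x: each daughter spans half the rod
  xs <- voxelCoords(res$lattice, which(res$lattice@grid == 1L) - 1L)[, 1]
  expect_identical(length(unique(xs)), 4L)
})

test_that("division conserves voxels and respects the imbalance bound", {
  set.seed(33)
  for (rep in 1:40) {
    lat <- newLattice(rep(20L, 3))
    # random compact blob by surface-tension-weighted accretion: frontier
    # sites with more occupied face neighbors are strongly preferred, the
    # shape class of adhesive cells reaching the division volume
    vox <- c(voxelIndex0(lat, 10L, 10L, 10L))
    while (length(vox) < 32L) {
      xyz <- voxelCoords(lat, vox)
      cand <- unique(c(
        voxelIndex0(lat, pmin(xyz[, 1] + 1L, 19L), xyz[, 2], xyz[, 3]),
        voxelIndex0(lat, pmax(xyz[, 1] - 1L, 0L), xyz[, 2], xyz[, 3]),
        voxelIndex0(lat, xyz[, 1], pmin(xyz[, 2] + 1L, 19L), xyz[, 3]),
        voxelIndex0(lat, xyz[, 1], pmax(xyz[, 2] - 1L, 0L), xyz[, 3]),
        voxelIndex0(lat, xyz[, 1], xyz[, 2], pmin(xyz[, 3] + 1L, 19L)),
        voxelIndex0(lat, xyz[, 1], xyz[, 2], pmax(xyz[, 3] - 1L, 0L))))
      cand <- setdiff(cand, vox)
      cc <- voxelCoords(lat, cand)
      w <- vapply(seq_along(cand), function(i) {
        sum(abs(xyz[, 1] - cc[i, 1]) + abs(xyz[, 2] - cc[i, 2]) +
              abs(xyz[, 3] - cc[i, 3]) == 1L)
      }, numeric(1))^3
      vox <- c(vox, cand[sample(length(cand), 1L, prob = w)])
    }
    lat <- addCells(lat, list(vox), "TUMOR", targetVolume = 6750 / 216)
    res <- divideCell(lat, 1L)
    reg <- cellRegistry(res$lattice)
    expect_identical(sum(reg$volume), 32)
    imb <- abs(diff(reg$volume)) / max(reg$volume)
    expect_lte(imb, 0.2 + 1e-9)
  }
})

test_that("staged growth is monotone and conserves the vasculature", {
  set.seed(5)
  net <- generateCapillaryNetwork(vesselNetworkParams(), dims = rep(32L, 3))
  net <- clusterVascularCells(net)
  net <- remodelVasculature(net, nMcs = 20)
  lat <- seedNormalTissue(net)
  lat <- seedTumor(lat)
  nVasc <- sum(cellRegistry(lat)$type == "VASCULAR")
  gr <- growToStage(lat, tumorGrowthParams(maxGrowthRate = 67.5),
                    oxygenParams(secondsPerMcs = 0.25),
                    stages = c(D12 = 0.055, D14 = 0.135), maxMcs = 1500)
  expect_identical(names(gr$snapshots), c("D12", "D14"))
  # tumor volume fraction grows monotonically up to small Potts
  # fluctuations (strictly monotone across the staged snapshots)
  tf <- gr$series$tumorFraction
  expect_true(all(tf >= cummax(tf) - 0.02))
  expect_gt(tail(tf, 1), tf[1])
  # tumor cell count never decreases (no death before irradiation)
  expect_true(all(diff(gr$series$nTumorCells) >= 0L))
  # no vascular cell created or destroyed; volume fraction ~ conserved
  for (s in gr$snapshots) {
    expect_identical(sum(cellRegistry(s)$type == "VASCULAR"), nVasc)
    expect_lt(abs(vascularFraction(s) - vascularFraction(lat)), 0.012)
  }
  expect_silent(auditLattice(gr$lattice))
})

test_that("with oxygen clamped high the tumor radius grows steadily", {
  set.seed(6)
  lat <- newLattice(rep(28L, 3))
  lat <- seedTumor(lat)
  oxy <- oxygenParams(donorPO2 = 90, secondsPerMcs = 0.05)
  # no vasculature: fake saturation by an always-high clamp via a vascular
  # shell far from the tumor would be artificial; instead drive growth with
  # a high uniform field through growthUpdate + MCS directly
  params <- tumorGrowthParams(maxGrowthRate = 67.5)
  ham <- growthParams()
  cf <- newChemField("CELLULAR_PO2", lat, c(MEDIUM = 0), init = 90)
  radius <- function(l) {
    reg <- cellRegistry(l)
    tum <- reg[reg$type == "TUMOR", ]
    (sum(tum$volume) * 3 / (4 * pi))^(1 / 3)
  }
  rs <- numeric(3)
  for (k in 1:3) {
    for (i in 1:60) {
      lat <- runMCS(lat, ham, 1L)
      lat <- growthUpdate(lat, cf, params)
      divVox <- 6750 / 216
      repeat {
        ready <- with(cellRegistry(lat),
                      id[type == "TUMOR" & alive & volume >= divVox])
        if (!length(ready)) break
        for (cid in ready) lat <- divideCell(lat, cid, params)$lattice
      }
    }
    rs[k] <- radius(lat)
  }
  expect_true(all(diff(rs) > 0))
})
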
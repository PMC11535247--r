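test_that("death probability interpolates, extrapolates and clamps", {
  tab <- defaultDoseResponse()
  expect_equal(deathProbability(0, tab), 0)
  expect_equal(deathProbability(25, tab), 0.47)
  # midway between support points: arithmetic mean of their probabilities
  expect_equal(deathProbability(7.5, tab), (0.12 + 0.25) / 2)
  expect_equal(deathProbability(12.5, tab), (0.25 + 0.35) / 2)
  # beyond the measured range: line through the two highest points
  slope <- (0.47 - 0.42) / 5
  expect_equal(deathProbability(30, tab), 0.47 + slope * 5)
  # ablative doses clamp at 1 for any non-decreasing table
  expect_equal(deathProbability(350, tab), 1)
  expect_error(deathProbability(-1, tab), ">= 0")
  # vectorized
  expect_length(deathProbability(c(0, 10, 400), tab), 3L)
})

test_that("table validity enforces monotone, bounded support points", {
  expect_error(doseResponseTable(c(0, 5, 5), c(0, 0.1, 0.2)), "increasing")
  expect_error(doseResponseTable(c(0, 5), c(0.3, 0.1)), "non-decreasing")
  expect_error(doseResponseTable(c(1, 5), c(0, 0.1)), "start at 0")
  expect_error(doseResponseTable(c(0, 5), c(0, 1.2)), "\\[0, 1\\]")
})

test_that("vascular deaths follow the per-cell probabilities", {
  # 10^4 single-voxel vascular cells at a dose with p = 0.5
  lat <- newLattice(c(50L, 40L, 10L))
  vox <- as.list(seq_len(10000L) - 1L)
  lat <- addCells(lat, vox, "VASCULAR")
  tab <- doseResponseTable(c(0, 10), c(0, 1)) # p = dose/10
  md <- setNames(rep(5, 10000L), seq_len(10000L))
  set.seed(12)
  res <- applyVascularDeaths(lat, md, tab)
  frac <- mean(res$report$died)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(frac - 0.5), 3 * se)
  # dead cells leave medium voxels and a consistent registry
  expect_silent(auditLattice(res$lattice))
  deadIds <- res$report$id[res$report$died]
  expect_identical(sum(res$lattice@grid %in% deadIds), 0L)
  # zero dose with a zero-baseline table kills nobody
  res0 <- applyVascularDeaths(lat, setNames(rep(0, 10000L),
                                            seq_len(10000L)), tab)
  expect_identical(sum(res0$report$died), 0L)
})

test_that("death decisions are reproducible under a fixed seed", {
  lat <- newLattice(c(20L, 20L, 5L))
  lat <- addCells(lat, as.list(seq_len(400L) - 1L), "VASCULAR")
  md <- setNames(rep(15, 400L), seq_len(400L))
  set.seed(42)
  a <- applyVascularDeaths(lat, md)
  set.seed(42)
  b <- applyVascularDeaths(lat, md)
  expect_identical(a$report$died, b$report$died)
})

test_that("vascular death fraction is monotone in the dose scaling", {
  lat <- newLattice(c(50L, 40L, 10L))
  lat <- addCells(lat, as.list(seq_len(10000L) - 1L), "VASCULAR")
  fracs <- sapply(c(0.5, 1, 2), function(s) {
    md <- setNames(rep(10 * s, 10000L), seq_len(10000L))
    set.seed(3)
    mean(applyVascularDeaths(lat, md)$report$died)
  })
  expect_true(all(diff(fracs) > 0))
})

test_that("beam-path ablation removes cells by centroid band membership", {
  # single cell straddling a band edge: removed iff centroid < edge
  spec <- beamSpec(nBeams = 1L, fwhm = 54, ctc = 200) # edges at +-27 um
  lat <- newLattice(c(20L, 9L, 9L), voxelSize = 6)
  # beam center at 60 um; upper band edge at 87 um = center of voxel 14
  # (0-based): exactly-on-edge is kept (half-open band), one voxel below
  # (center 81 um) is removed
  lat <- addCells(lat, list(voxelIndex0(lat, 14L, 2L, 2L),
                            voxelIndex0(lat, 13L, 6L, 6L)),
                  "NORMAL")
  res <- ablateBeamPathCells(lat, spec)
  expect_identical(res$report$removed, c(FALSE, TRUE))
  # vascular cells are never ablated by this rule
  lat2 <- newLattice(c(20L, 9L, 9L), voxelSize = 6)
  lat2 <- addCells(lat2, list(voxelIndex0(lat2, 10L, 4L, 4L)), "VASCULAR")
  res2 <- ablateBeamPathCells(lat2, spec)
  expect_identical(nrow(res2$report), 0L)
  # zero beams: nothing removed
  res3 <- ablateBeamPathCells(lat, beamSpec(nBeams = 0L))
  expect_identical(sum(res3$report$removed), 0L)
})

test_that("ablation is set-based: enumeration order cannot matter", {
  set.seed(9)
  lat <- newLattice(c(40L, 12L, 12L), voxelSize = 6)
  vox <- sample(prod(c(40, 12, 12)), 300L) - 1L
  lat <- addCells(lat, as.list(vox), "NORMAL")
  spec <- beamSpec(nBeams = 1L)
  a <- ablateBeamPathCells(lat, spec)
  # same lattice with registry rows in reversed order
  lat2 <- lat
  lat2@cells <- lat2@cells[rev(seq_len(nrow(lat2@cells))), ]
  b <- ablateBeamPathCells(lat2, spec)
  expect_identical(sort(a$report$id[a$report$removed]),
                   sort(b$report$id[b$report$removed]))
})
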
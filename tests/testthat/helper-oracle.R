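# Independent full-Hamiltonian oracle and small lattice builders.
# The oracle recomputes the total energy from scratch in plain R (its own
# neighbor enumeration and an eigen()-based axis length), so it shares no
# code path with the compiled incremental kernel.

# 26- or 6-neighborhood offsets
oracleOffsets <- function(neighborhood) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (neighborhood == "vonneumann")
    off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  off
}

# total H = adhesion + volume + elongation (chemotaxis is a move work
# term, not a state energy); non-periodic lattices only
oracleHamiltonian <- function(lattice, params) {
  g <- lattice@grid
  d <- dim(g)
  cells <- cellRegistry(lattice)
  typeOf <- integer(max(cells$id, 1L))
  typeOf[cells$id] <- match(cells$type, c("MEDIUM", "VASCULAR", "NORMAL",
                                          "TUMOR", "DONOR", "ACCEPTOR")) - 1L
  off <- oracleOffsets(params@neighborhood)
  H <- 0
  idx <- which(g >= 0L)
  coords <- arrayInd(idx, d)
  for (k in seq_len(nrow(off))) {
    nb <- sweep(coords, 2, off[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1 + d[2] * (nb[ok, 3] - 1))
    a <- g[idx[ok]]
    b <- g[lin]
    ta <- ifelse(a > 0L, typeOf[pmax(a, 1L)], 0L) + 1L
    tb <- ifelse(b > 0L, typeOf[pmax(b, 1L)], 0L) + 1L
    H <- H + sum(params@J[cbind(ta, tb)] * (a != b)) / 2 # each pair twice
  }
  for (i in seq_len(nrow(cells))) {
    if (cells$type[i] %in% c("DONOR", "ACCEPTOR")) next
    vox <- which(g == cells$id[i])
    v <- length(vox)
    H <- H + params@lambdaVolume * (v - cells$targetVolume[i])^2
    ta <- cells$targetAxis[i]
    if (!is.na(ta) && ta > 0 && params@lambdaLength > 0) {
      len <- oracleAxisLength(arrayInd(vox, d))
      H <- H + params@lambdaLength * (len - ta)^2
    }
  }
  H
}

# major-axis length from the coordinate covariance via eigen()
oracleAxisLength <- function(xyz) {
  if (nrow(xyz) == 1L) return(1)
  C <- cov(xyz) * (nrow(xyz) - 1) / nrow(xyz) # population covariance
  sqrt(12 * max(eigen(C, symmetric = TRUE, only.values = TRUE)$values) + 1)
}

# lattice with a straight 1-voxel-thick vascular tube along x
tubeLattice <- function(len, cross = 5L, gapAt = integer(0)) {
  lat <- newLattice(c(len, cross, cross), voxelSize = 6)
  mid <- cross %/% 2L
  xs <- setdiff(seq_len(len) - 1L, gapAt - 1L)
  vox <- voxelIndex0(lat, xs, rep(mid, length(xs)), rep(mid, length(xs)))
  addCells(lat, list(vox), "VASCULAR")
}

# small lattice with two touching cells for copy-attempt tests
twoCellLattice <- function(n = 4L) {
  lat <- newLattice(rep(n, 3L))
  half <- as.integer(n %/% 2)
  g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  left <- g[g$x < half, ]
  right <- g[g$x >= half, ]
  addCells(lat, list(voxelIndex0(lat, left$x, left$y, left$z),
                     voxelIndex0(lat, right$x, right$y, right$z)),
           c("VASCULAR", "NORMAL"))
}
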
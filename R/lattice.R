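.emptyRegistry <- function() {
  data.frame(id = integer(), type = character(),
             targetVolume = numeric(), targetAxis = numeric(),
             oxygenState = character(), alive = logical(),
             volume = numeric(), axisLength = numeric(),
             cx = numeric(), cy = numeric(), cz = numeric(),
             stringsAsFactors = FALSE)
}

#' Create an empty voxel lattice
#'
#' @param dims integer length-3 lattice dimensions (voxels).
#' @param voxelSize voxel edge length, micrometres.
#' @param periodic logical scalar or length-3: per-axis periodicity used by
#'   the Potts neighborhoods.  The cellular pO2 field is always stepped with
#'   periodic wrap regardless of this flag.
#' @return a [VoxelLattice-class] with all voxels medium.
#' @export
newLattice <- function(dims, voxelSize = 6, periodic = FALSE) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  if (length(periodic) == 1L) periodic <- rep(periodic, 3L)
  new("VoxelLattice",
      grid = array(0L, dim = dims), voxelSize = voxelSize,
      periodic = as.logical(periodic), cells = .emptyRegistry(),
      boundary = list())
}

#' @rdname VoxelLattice-class
#' @export
setMethod("latticeDims", "VoxelLattice", function(x) dim(x@grid))

#' @rdname VoxelLattice-class
#' @export
setMethod("voxelSize", "VoxelLattice", function(x) x@voxelSize)

#' @rdname VoxelLattice-class
#' @export
setMethod("cellRegistry", "VoxelLattice", function(x) x@cells)

#' @rdname VoxelLattice-class
#' @export
setMethod("cellRegistry<-", "VoxelLattice", function(x, value) {
  x@cells <- value
  x
})

#' @rdname VoxelLattice-class
#' @export
setMethod("nCells", "VoxelLattice",
          function(x) sum(!x@cells$type %in% c("DONOR", "ACCEPTOR")))

#' @rdname VoxelLattice-class
#' @export
setMethod("vascularFraction", "VoxelLattice", function(x) {
  vid <- x@cells$id[x@cells$type == "VASCULAR"]
  if (!length(vid)) return(0)
  sum(x@grid %in% vid) / length(x@grid)
})

setMethod("show", "VoxelLattice", function(object) {
  d <- dim(object@grid)
  cat(sprintf("VoxelLattice %dx%dx%d voxels (%.0f um each)\n",
              d[1], d[2], d[3], object@voxelSize))
  tab <- table(object@cells$type)
  if (length(tab))
    cat("  cells:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = ", "), "\n")
  cat(sprintf("  occupied voxels: %d / %d (vascular fraction %.3f)\n",
              sum(object@grid > 0L), length(object@grid),
              vascularFraction(object)))
  if (length(object@boundary))
    cat(sprintf("  perfusion boundary: %d donor / %d acceptor voxels\n",
                nrow(object@boundary$donor), nrow(object@boundary$acceptor)))
})

# ---- voxel index helpers (0-based linear, column-major, x fastest) ----

#' Convert between 0-based linear voxel indices and coordinates
#'
#' @param lattice a VoxelLattice.
#' @param index0 0-based linear voxel indices.
#' @return `voxelCoords`: an n x 3 matrix of 0-based (x, y, z) coordinates;
#'   `voxelIndex0`: 0-based linear indices.
#' @export
voxelCoords <- function(lattice, index0) {
  d <- dim(lattice@grid)
  x <- index0 %% d[1]
  y <- (index0 %/% d[1]) %% d[2]
  z <- index0 %/% (d[1] * d[2])
  cbind(x = x, y = y, z = z)
}

#' @rdname voxelCoords
#' @param x,y,z 0-based voxel coordinates.
#' @export
voxelIndex0 <- function(lattice, x, y, z) {
  d <- dim(lattice@grid)
  stopifnot(all(x >= 0 & x < d[1]), all(y >= 0 & y < d[2]),
            all(z >= 0 & z < d[3]))
  as.integer(x + d[1] * (y + d[2] * z))
}

# ---- registry maintenance ----

#' Register new cells and claim their voxels
#'
#' Appends cells to the registry with fresh identifiers and labels their
#' voxels on the grid (overwriting whatever occupied them).
#'
#' @param lattice a VoxelLattice.
#' @param voxels0 list of 0-based linear voxel index vectors, one per cell.
#' @param type cell type (recycled).
#' @param targetVolume target volume in voxels (NA: use the actual count).
#' @param targetAxis target major-axis length in voxels (0: no elongation
#'   constraint).
#' @return the updated lattice.
#' @export
addCells <- function(lattice, voxels0, type, targetVolume = NA_real_,
                     targetAxis = 0) {
  n <- length(voxels0)
  ids <- if (nrow(lattice@cells)) max(lattice@cells$id) + seq_len(n)
         else seq_len(n)
  g <- lattice@grid
  for (i in seq_len(n)) {
    v <- voxels0[[i]]
    if (length(v)) g[v + 1L] <- ids[i]
  }
  lattice@grid <- g
  tv <- rep_len(targetVolume, n)
  vol <- vapply(voxels0, length, 1L)
  tv[is.na(tv)] <- vol[is.na(tv)]
  rows <- data.frame(id = as.integer(ids), type = rep_len(type, n),
                     targetVolume = tv,
                     targetAxis = rep_len(targetAxis, n),
                     oxygenState = "NORMOXIC", alive = TRUE,
                     volume = as.numeric(vol), axisLength = NA_real_,
                     cx = NA_real_, cy = NA_real_, cz = NA_real_,
                     stringsAsFactors = FALSE)
  lattice@cells <- rbind(lattice@cells, rows)
  syncRegistry(lattice)
}

#' Refresh cached per-cell shape statistics from the grid
#'
#' Recomputes volume, major-axis length and centroid for every registered
#' cell.  Cells whose voxel count has dropped to zero (and that are not
#' donor/acceptor boundary devices) are removed when `drop = TRUE`.
#'
#' @param lattice a VoxelLattice.
#' @param drop remove registry rows for cells with no voxels left.
#' @export
syncRegistry <- function(lattice, drop = FALSE) {
  cells <- lattice@cells
  if (!nrow(cells)) return(lattice)
  maxId <- max(cells$id)
  st <- cell_shape_stats(as.vector(lattice@grid), dim(lattice@grid), maxId)
  i <- cells$id
  bdry <- cells$type %in% c("DONOR", "ACCEPTOR")
  cells$volume[!bdry] <- st$volume[i[!bdry]]
  cells$axisLength[!bdry] <- st$axisLength[i[!bdry]]
  cells$cx[!bdry] <- st$cx[i[!bdry]]
  cells$cy[!bdry] <- st$cy[i[!bdry]]
  cells$cz[!bdry] <- st$cz[i[!bdry]]
  if (drop) cells <- cells[bdry | cells$volume > 0, , drop = FALSE]
  lattice@cells <- cells
  lattice
}

#' Audit registry/grid consistency
#'
#' Deep invariant check: every nonzero grid identifier has a registry row,
#' every cached volume equals the actual voxel count, and cell volumes plus
#' medium voxels account for every lattice voxel.
#'
#' @param lattice a VoxelLattice.
#' @return TRUE invisibly; stops with a diagnostic on violation.
#' @export
auditLattice <- function(lattice) {
  g <- lattice@grid
  cells <- lattice@cells
  ids <- tabulate(g[g > 0L], nbins = if (nrow(cells)) max(cells$id) else 0L)
  present <- which(ids > 0L)
  if (length(setdiff(present, cells$id)))
    stop("grid identifiers missing from registry: ",
         paste(head(setdiff(present, cells$id)), collapse = ", "))
  body <- cells[!cells$type %in% c("DONOR", "ACCEPTOR"), , drop = FALSE]
  actual <- if (length(ids)) ids[body$id] else integer()
  bad <- which(body$volume != actual)
  if (length(bad))
    stop("cached volumes out of sync for ids: ",
         paste(head(body$id[bad]), collapse = ", "))
  if (sum(actual) + sum(g == 0L) != length(g))
    stop("volume conservation violated")
  invisible(TRUE)
}

# ---- snapshot I/O ----

#' Write / read a lattice snapshot
#'
#' The grid is stored as a multi-page 16-bit grayscale TIFF label image
#' (one page per z slice; identifiers must stay below 65536) and the cell
#' registry plus lattice metadata as a JSON sidecar next to it.
#'
#' @param lattice a VoxelLattice.
#' @param path TIFF file path; the sidecar uses `<path>.json`.
#' @return `readLatticeSnapshot` returns the reconstructed VoxelLattice.
#' @export
writeLatticeSnapshot <- function(lattice, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("snapshot I/O needs the 'tiff' package")
  g <- lattice@grid
  if (max(g) > 65535L) stop("cell identifiers exceed 16-bit TIFF range")
  pages <- lapply(seq_len(dim(g)[3]),
                  function(z) t(g[, , z]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(dims = dim(g), voxelSize = lattice@voxelSize,
               periodic = lattice@periodic, cells = lattice@cells,
               boundary = lattice@boundary)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeLatticeSnapshot
#' @param path TIFF file written by `writeLatticeSnapshot`.
#' @export
readLatticeSnapshot <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("snapshot I/O needs the 'tiff' package")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dims)
  g <- array(0L, d)
  for (z in seq_len(d[3]))
    g[, , z] <- as.integer(round(t(pages[[z]]) * 65535))
  cells <- as.data.frame(meta$cells)
  bdry <- meta$boundary
  if (length(bdry)) bdry <- lapply(bdry, as.data.frame)
  new("VoxelLattice", grid = g, voxelSize = meta$voxelSize,
      periodic = as.logical(meta$periodic), cells = cells,
      boundary = if (length(bdry)) bdry else list())
}
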
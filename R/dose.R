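#' Construct a microbeam array specification
#'
#' @param nBeams,fwhm,ctc,beamLength,peakDose,valleyDose,penumbraSigma,lateralAxis,depthInWater
#'   see [BeamSpec-class].  Defaults: three 50 micrometre beams, 200
#'   micrometre spacing, 350 Gy peak / 6 Gy valley.
#' @return a [BeamSpec-class].
#' @export
beamSpec <- function(nBeams = 3L, fwhm = 50, ctc = 200, beamLength = 1200,
                     peakDose = 350, valleyDose = 6, penumbraSigma = 8,
                     lateralAxis = 1L, depthInWater = 5.5) {
  new("BeamSpec", nBeams = as.integer(nBeams), fwhm = fwhm, ctc = ctc,
      beamLength = beamLength, peakDose = peakDose,
      valleyDose = valleyDose, penumbraSigma = penumbraSigma,
      lateralAxis = as.integer(lateralAxis), depthInWater = depthInWater)
}

# beam center positions (micrometres) for beams centered on the lattice
.beamCenters <- function(spec, widthUm) {
  widthUm / 2 + (seq_len(spec@nBeams) - (spec@nBeams + 1) / 2) * spec@ctc
}

# flat-top-plus-Gaussian-penumbra bump with FWHM exactly `fwhm`
.beamletBump <- function(x, fwhm, sigma) {
  hw <- fwhm / 2 - sigma * sqrt(2 * log(2))
  a <- abs(x)
  ifelse(a <= hw, 1, exp(-(a - hw)^2 / (2 * sigma^2)))
}

#' Build the parametric microbeam dose grid
#'
#' A one-dimensional lateral profile -- valley floor plus one
#' flat-top/Gaussian-penumbra bump per beam, with FWHM exactly the nominal
#' beam width -- is normalized so the maximum voxel equals the peak dose and
#' then replicated along the other two axes (the depth-dose variation over
#' the sub-millimetre lattice is neglected).
#'
#' @param spec a [beamSpec()].
#' @param dims integer length-3 lattice dimensions.
#' @param voxelSize voxel edge, micrometres.
#' @return a [DoseGrid-class] matching the lattice geometry.
#' @export
buildParametricDose <- function(spec, dims, voxelSize = 6) {
  dims <- as.integer(dims)
  ax <- spec@lateralAxis
  n <- dims[ax]
  widthUm <- n * voxelSize
  centers <- .beamCenters(spec, widthUm)
  if (any(centers - spec@fwhm / 2 < 0 | centers + spec@fwhm / 2 > widthUm))
    warning("beam array exceeds the lattice laterally; truncated")
  if (spec@beamLength < max(dims[-ax]) * voxelSize)
    warning("beam length shorter than the lattice; beams truncated to ",
            "the lattice extent")
  xc <- (seq_len(n) - 0.5) * voxelSize
  bump <- rowSums(vapply(centers,
                         function(c0) .beamletBump(xc - c0, spec@fwhm,
                                                   spec@penumbraSigma),
                         numeric(n)))
  profile <- spec@valleyDose +
    (spec@peakDose - spec@valleyDose) * bump / max(bump)
  g <- array(0, dims)
  idx <- slice.index(g, ax)
  g[] <- profile[idx]
  new("DoseGrid", grid = g, voxelSize = voxelSize)
}

#' Write / read a dose grid as a scorer-style CSV
#'
#' Plain-text dialect compatible with voxelized scorer output: comment
#' header lines declaring the binning (`# X in <n> bins of <h> um`), then
#' one `x, y, z, dose` row per voxel with 0-based bin indices.
#'
#' @param dose a [DoseGrid-class].
#' @param path CSV file path.
#' @export
writeDoseGrid <- function(dose, path) {
  d <- dim(dose@grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# Dose scorer output",
               sprintf("# X in %d bins of %g um", d[1], dose@voxelSize),
               sprintf("# Y in %d bins of %g um", d[2], dose@voxelSize),
               sprintf("# Z in %d bins of %g um", d[3], dose@voxelSize),
               "# x, y, z, dose_Gy"), con)
  idx <- arrayInd(seq_along(dose@grid), d) - 1L
  writeLines(sprintf("%d, %d, %d, %.17g", idx[, 1], idx[, 2], idx[, 3],
                     as.vector(dose@grid)), con)
  invisible(path)
}

#' @rdname writeDoseGrid
#' @param path CSV file to read.
#' @param dims expected lattice dimensions (geometry mismatch is an error).
#' @param voxelSize expected voxel edge, micrometres.
#' @return `importDoseGrid` returns a [DoseGrid-class].
#' @export
importDoseGrid <- function(path, dims, voxelSize = 6) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  bins <- regmatches(hdr, regexec(
    "([XYZ]) in ([0-9]+) bins of ([0-9.]+) um", hdr))
  bins <- Filter(function(m) length(m) == 4L, bins)
  if (length(bins) != 3L) stop("malformed header: binning not declared")
  decl <- setNames(vapply(bins, function(m) as.integer(m[3]), 1L),
                   vapply(bins, `[`, "", 2))
  declSize <- unique(vapply(bins, function(m) as.numeric(m[4]), 1))
  dims <- as.integer(dims)
  if (!identical(unname(decl[c("X", "Y", "Z")]), dims) ||
      length(declSize) != 1L || declSize != voxelSize)
    stop("dose grid geometry does not match the lattice")
  dat <- read.csv(path, comment.char = "#", header = FALSE)
  if (ncol(dat) != 4L || nrow(dat) != prod(dims))
    stop("malformed dose rows")
  if (any(!is.finite(dat[[4]])) || any(dat[[4]] < 0))
    stop("non-finite or negative doses in file")
  g <- array(NA_real_, dims)
  lin <- dat[[1]] + dims[1] * (dat[[2]] + dims[2] * dat[[3]]) + 1L
  if (anyDuplicated(lin) || any(lin < 1L) || any(lin > prod(dims)))
    stop("voxel indices out of range or duplicated")
  g[lin] <- dat[[4]]
  new("DoseGrid", grid = g, voxelSize = voxelSize)
}

#' Mean absorbed dose per cell
#'
#' @param dose a [DoseGrid-class] on the lattice geometry.
#' @param lattice the VoxelLattice.
#' @return named numeric vector, cell id -> mean dose (Gy) over the cell's
#'   voxels.  Boundary devices (donor/acceptor) are excluded; a registered
#'   cell without voxels is an error.
#' @export
meanDosePerCell <- function(dose, lattice) {
  if (!identical(dim(dose@grid), dim(lattice@grid)) ||
      dose@voxelSize != lattice@voxelSize)
    stop("dose grid geometry does not match the lattice")
  cells <- lattice@cells
  body <- cells[!cells$type %in% c("DONOR", "ACCEPTOR") & cells$alive, ,
                drop = FALSE]
  if (!nrow(body)) return(setNames(numeric(0), character(0)))
  mx <- max(body$id)
  res <- cell_field_means(as.vector(lattice@grid), as.vector(dose@grid), mx)
  m <- res$mean[body$id]
  if (anyNA(m))
    stop("cells without voxels: ",
         paste(head(body$id[is.na(m)]), collapse = ", "))
  setNames(m, body$id)
}
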
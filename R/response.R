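#' Construct an endothelial apoptosis dose-response table
#'
#' @param dose,probability support points (doses strictly increasing from
#'   0, probabilities non-decreasing in [0, 1]).
#' @param maxMeasuredDose upper end of the measured range, Gy; beyond it
#'   the response is linearly extrapolated through the two highest points
#'   and clamped to 1.
#' @return a [DoseResponseTable-class].
#' @export
doseResponseTable <- function(dose, probability,
                              maxMeasuredDose = max(dose)) {
  new("DoseResponseTable", dose = dose, probability = probability,
      maxMeasuredDose = maxMeasuredDose)
}

#' Default microvascular endothelial apoptosis response
#'
#' A smooth, monotone placeholder digitization of the measured
#' low-dose (0-25 Gy) endothelial apoptosis response; it is synthetic, not
#' an authoritative transcription of any published curve, and should be
#' replaced via [doseResponseTable()] (or a 2-column CSV through
#' [readDoseResponse()]) when a measured table is available.
#'
#' @return a [DoseResponseTable-class].
#' @export
defaultDoseResponse <- function() {
  doseResponseTable(dose = c(0, 5, 10, 15, 20, 25),
                    probability = c(0, 0.12, 0.25, 0.35, 0.42, 0.47),
                    maxMeasuredDose = 25)
}

#' @rdname defaultDoseResponse
#' @param path CSV with columns dose, probability.
#' @export
readDoseResponse <- function(path) {
  d <- read.csv(path)
  doseResponseTable(d[[1]], d[[2]])
}

#' Vascular cell death probability at a dose
#'
#' Linear interpolation within the measured range; linear extrapolation
#' through the two highest support points above it, clamped to [0, 1].
#'
#' @param dose absorbed dose(s), Gy (>= 0).
#' @param table a [DoseResponseTable-class].
#' @return death probabilities in [0, 1].
#' @export
deathProbability <- function(dose, table = defaultDoseResponse()) {
  if (any(dose < 0)) stop("dose must be >= 0")
  n <- length(table@dose)
  slope <- (table@probability[n] - table@probability[n - 1]) /
    (table@dose[n] - table@dose[n - 1])
  p <- approx(table@dose, table@probability, xout = pmin(dose,
                                                         table@dose[n]),
              rule = 2)$y
  hi <- dose > table@dose[n]
  p[hi] <- table@probability[n] + slope * (dose[hi] - table@dose[n])
  pmin(pmax(p, 0), 1)
}

#' Apply stochastic radiation death to vascular cells
#'
#' Each live vascular cell dies independently with the death probability of
#' its mean dose; dead cells' voxels revert to medium and the registry row
#' is flagged dead.  Uses R's RNG stream.
#'
#' @param lattice the VoxelLattice.
#' @param meanDoses named vector from [meanDosePerCell()].
#' @param table a [DoseResponseTable-class].
#' @return list with the updated `lattice` and a `report` data.frame
#'   (id, type, meanDose, probability, died).
#' @export
applyVascularDeaths <- function(lattice, meanDoses,
                                table = defaultDoseResponse()) {
  cells <- lattice@cells
  sel <- which(cells$type == "VASCULAR" & cells$alive)
  ids <- cells$id[sel]
  doses <- meanDoses[as.character(ids)]
  if (anyNA(doses)) stop("mean doses missing for some vascular cells")
  p <- deathProbability(unname(doses), table)
  died <- runif(length(ids)) < p
  if (any(died)) {
    deadIds <- ids[died]
    lattice@grid[lattice@grid %in% deadIds] <- 0L
    rows <- match(deadIds, lattice@cells$id)
    lattice@cells$alive[rows] <- FALSE
    lattice@cells$volume[rows] <- 0
  }
  report <- data.frame(id = ids, type = "VASCULAR",
                       meanDose = unname(doses), probability = p,
                       died = died, stringsAsFactors = FALSE)
  list(lattice = lattice, report = report)
}

#' Ablate non-vascular cells in the microbeam paths
#'
#' Deterministic removal of every live normal or tumor cell whose centroid
#' lies within the FWHM band of any beam along the lateral axis (half-open
#' bands `[center - fwhm/2, center + fwhm/2)`).  Vascular cells are
#' untouched by this rule: they follow the dose-response instead.
#'
#' @param lattice the VoxelLattice.
#' @param spec a [beamSpec()].
#' @return list with the updated `lattice` and a `report` data.frame
#'   (id, type, centroidUm, removed).
#' @export
ablateBeamPathCells <- function(lattice, spec) {
  lattice <- syncRegistry(lattice)
  cells <- lattice@cells
  sel <- which(cells$type %in% c("NORMAL", "TUMOR") & cells$alive &
                 cells$volume > 0)
  if (!length(sel))
    return(list(lattice = lattice,
                report = data.frame(id = integer(), type = character(),
                                    centroidUm = numeric(),
                                    removed = logical())))
  ax <- spec@lateralAxis
  cc <- switch(ax, cells$cx, cells$cy, cells$cz)[sel]
  pos <- (cc + 0.5) * lattice@voxelSize
  widthUm <- dim(lattice@grid)[ax] * lattice@voxelSize
  centers <- .beamCenters(spec, widthUm)
  inBand <- rep(FALSE, length(sel))
  for (c0 in centers)
    inBand <- inBand | (pos >= c0 - spec@fwhm / 2 &
                          pos < c0 + spec@fwhm / 2)
  if (any(inBand)) {
    deadIds <- cells$id[sel][inBand]
    lattice@grid[lattice@grid %in% deadIds] <- 0L
    rows <- match(deadIds, lattice@cells$id)
    lattice@cells$alive[rows] <- FALSE
    lattice@cells$volume[rows] <- 0
  }
  report <- data.frame(id = cells$id[sel], type = cells$type[sel],
                       centroidUm = pos, removed = inBand,
                       stringsAsFactors = FALSE)
  list(lattice = lattice, report = report)
}
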
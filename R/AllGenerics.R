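#' @rdname VoxelLattice-class
#' @param x a VoxelLattice.
#' @export
setGeneric("latticeDims", function(x) standardGeneric("latticeDims"))

#' @rdname VoxelLattice-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname VoxelLattice-class
#' @export
setGeneric("cellRegistry", function(x) standardGeneric("cellRegistry"))

#' @rdname VoxelLattice-class
#' @param value replacement registry data.frame.
#' @export
setGeneric("cellRegistry<-",
           function(x, value) standardGeneric("cellRegistry<-"))

#' @rdname VoxelLattice-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname VoxelLattice-class
#' @export
setGeneric("vascularFraction",
           function(x) standardGeneric("vascularFraction"))
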
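#' Accessors for boneCSG classes
#'
#' Slot accessors for the core data containers; prefer these over direct
#' \code{@} access.
#'
#' @param x an object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("intensities", "VoxelVolume", function(x) x@intensities)
#' @rdname accessors
setMethod("intensities", "CrossSectionImage", function(x) x@intensities)
#' @rdname accessors
setMethod("voxelSize", "VoxelVolume", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "AlignedBone", function(x) x@voxelSize)
#' @rdname accessors
setMethod("pixelSize", "CrossSectionImage", function(x) x@pixelSize)
#' @rdname accessors
setMethod("provenance", "VoxelVolume", function(x) x@provenance)
#' @rdname accessors
setMethod("provenance", "AlignedBone", function(x) x@provenance)
#' @rdname accessors
setMethod("provenance", "CrossSectionImage", function(x) x@provenance)
#' @rdname accessors
setMethod("lengthMm", "AlignedBone", function(x) x@lengthMm)
#' @rdname accessors
setMethod("binaryVolume", "AlignedBone", function(x) x@binaryVolume)
#' @rdname accessors
setMethod("growthCoefficients", "GrowthCurve", function(x) x@coefficients)

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@intensities)
  cat("VoxelVolume", if (!is.na(object@provenance)) object@provenance else "",
      "\n  dims:", paste(d, collapse = " x "),
      " voxel:", object@voxelSize, "mm\n")
})

setMethod("show", "AlignedBone", function(object) {
  d <- dim(object@binaryVolume)
  cat("AlignedBone", if (!is.na(object@provenance)) object@provenance else "",
      "\n  dims:", paste(d, collapse = " x "),
      " voxel:", object@voxelSize, "mm",
      " length:", round(object@lengthMm, 2), "mm\n")
})

setMethod("show", "CrossSectionImage", function(object) {
  d <- dim(object@intensities)
  cat("CrossSectionImage",
      if (!is.na(object@provenance)) object@provenance else "",
      "\n  dims:", paste(d, collapse = " x "),
      " pixel:", object@pixelSize, "mm\n")
})

setMethod("show", "SectionGeometry", function(object) {
  cat("SectionGeometry",
      if (!is.na(object@provenance)) object@provenance else "", "\n")
  cat(sprintf("  TA %.3f  CA %.3f  MA %.3f  CPA %.4f (mm^2)\n",
              object@TA, object@CA, object@MA, object@CPA))
  cat(sprintf("  Ix %.3f  Iy %.3f  Imax %.3f  Imin %.3f (mm^4)  theta %.1f deg\n",
              object@Ix, object@Iy, object@Imax, object@Imin, object@thetaDeg))
  cat(sprintf("  Imax/Imin %.3f  Ix/Iy %.3f  medullary %.3f  porosity %.4f\n",
              object@imaxIminRatio, object@ixIyRatio, object@medullaryIndex,
              object@porosityIndex))
})

setMethod("show", "GrowthCurve", function(object) {
  co <- object@coefficients
  cat(sprintf("GrowthCurve: FL(a) = %.3f + %.3f a + %.4f a^2 + %.5f a^3\n",
              co[1], co[2], co[3], co[4]))
  cat(sprintf("  ages [%.2f, %.2f] y  lengths [%.1f, %.1f] mm  monotone: %s\n",
              object@ageRange[1], object@ageRange[2], object@lengthRange[1],
              object@lengthRange[2], object@monotone))
})

setMethod("show", "TrendFit", function(object) {
  cat(sprintf("TrendFit: LOESS span %.2f degree %d, n = %d, grid [%.2f, %.2f]\n",
              object@span, as.integer(object@degree), as.integer(object@n),
              min(object@grid), max(object@grid)))
})

#' Flatten a SectionGeometry to a one-row data frame
#'
#' @param x a [SectionGeometry-class] object.
#' @param row.names,optional,... passed through for generic consistency.
#' @return one-row \code{data.frame} with all 14 measurement fields plus
#'   provenance.
#' @export
as.data.frame.SectionGeometry <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(provenance = x@provenance, TA_mm2 = x@TA, CA_mm2 = x@CA,
             MA_mm2 = x@MA, CPA_mm2 = x@CPA, Ix_mm4 = x@Ix, Iy_mm4 = x@Iy,
             Ixy_mm4 = x@Ixy, Imax_mm4 = x@Imax, Imin_mm4 = x@Imin,
             theta_deg = x@thetaDeg, imax_imin_ratio = x@imaxIminRatio,
             ix_iy_ratio = x@ixIyRatio, medullary_index = x@medullaryIndex,
             porosity_index = x@porosityIndex,
             stringsAsFactors = FALSE, row.names = row.names)
}
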
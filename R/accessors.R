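#' @describeIn accessors velocity array of a FlowField
#' @export
setMethod("velocityData", "FlowField", function(x) x@velocity)

#' @describeIn accessors magnitude array of a FlowField
#' @export
setMethod("magnitudeData", "FlowField", function(x) x@magnitude)

#' @describeIn accessors voxel spacing (mm)
#' @export
setMethod("voxelSpacing", "FlowField", function(x) x@spacing)

#' @describeIn accessors world position of voxel (1,1,1) (mm)
#' @export
setMethod("gridOrigin", "FlowField", function(x) x@origin)

#' @describeIn accessors number of cardiac frames
#' @export
setMethod("nFrames", "FlowField", function(x) dim(x@velocity)[4L])

#' @describeIn accessors frame duration (ms)
#' @export
setMethod("frameDuration", "FlowField", function(x) x@frameDuration)

#' @describeIn accessors cardiac cycle duration (ms)
#' @export
setMethod("cycleDuration", "FlowField", function(x) x@frameDuration * dim(x@velocity)[4L])

#' @describeIn accessors velocity-encoding limit (m/s)
#' @export
setMethod("venc", "FlowField", function(x) x@venc)

#' @describeIn accessors centreline points (mm)
#' @export
setMethod("clPoints", "Centerline", function(x) x@points)

#' @describeIn accessors unit tangents
#' @export
setMethod("clTangents", "Centerline", function(x) x@tangents)

#' @describeIn accessors cumulative arc length (mm)
#' @export
setMethod("arcLength", "Centerline", function(x) x@arcLength)

#' @describeIn accessors per-voxel region factor
#' @export
setMethod("regionLabels", "RegionLabels", function(x) x@labels)

#' @describeIn accessors the four boundary arc lengths (mm)
#' @export
setMethod("regionBoundaries", "RegionLabels", function(x) x@boundaries)

#' @describeIn accessors one named 3-D map ("ff", "rf", "stasis", "ke",
#'   "peakVelocity") from a VoxelMaps object
#' @export
setMethod("parameterMap", "VoxelMaps", function(x, parameter) {
    parameter <- match.arg(parameter, c("ff", "rf", "stasis", "ke", "peakVelocity"))
    slot(x, parameter)
})

setMethod("show", "FlowField", function(object) {
    d <- dim(object@velocity)
    cat(sprintf("FlowField: %d x %d x %d grid, %d frames\n", d[1], d[2], d[3], d[4]))
    cat(sprintf("  spacing %s mm, frame %.1f ms (cycle %.0f ms), venc %.2f m/s\n",
                paste(format(object@spacing, digits = 3), collapse = " x "),
                object@frameDuration, cycleDuration(object), object@venc))
    spd <- sqrt(rowSums(matrix(object@velocity, ncol = 3L)^2))
    cat(sprintf("  speed range [%.3f, %.3f] m/s\n", min(spd), max(spd)))
})

setMethod("show", "Centerline", function(object) {
    cat(sprintf("Centerline: %d points, arc length %.1f mm (step %.2f mm)\n",
                nrow(object@points), max(object@arcLength),
                mean(diff(object@arcLength))))
})

setMethod("show", "PlaneAssignment", function(object) {
    cat(sprintf("PlaneAssignment: %d voxels matched to %d planes\n",
                length(object@voxelIndex), length(unique(object@planeIndex))))
})

setMethod("show", "RegionLabels", function(object) {
    cat("RegionLabels:\n")
    print(table(object@labels))
    cat(sprintf("  boundaries (mm): %s\n",
                paste(format(object@boundaries, digits = 4), collapse = ", ")))
})

setMethod("show", "VoxelMaps", function(object) {
    n <- sum(object@mask)
    cat(sprintf("VoxelMaps over %d lumen voxels (%s mm grid)\n", n,
                paste(format(object@spacing, digits = 3), collapse = " x ")))
    for (p in c("ff", "rf", "stasis", "ke", "peakVelocity")) {
        v <- slot(object, p)[object@mask]
        cat(sprintf("  %-12s mean %8.4f  max %8.4f\n", p,
                    mean(v, na.rm = TRUE), max(v, na.rm = TRUE)))
    }
    cat(sprintf("  systole: frames %s\n",
                paste(range(object@systoleFrames), collapse = "-")))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec (%s): radius %.1f mm, %d frames over %.0f ms\n",
                object@geometry, object@radius, object@nFrames,
                object@cycleDuration))
    cat(sprintf("  spacing %s mm, swirl %.2f m/s, noise %.3f m/s, venc %.2f m/s\n",
                paste(format(object@spacing, digits = 3), collapse = " x "),
                object@swirl, object@noiseSigma, object@venc))
})
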
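#' @import methods
NULL

#' FlowField: a time-resolved three-directional velocity field
#'
#' Container for 4D-flow MRI data (measured or synthetic): three velocity
#' components per voxel per cardiac frame, the signal magnitude, the grid
#' geometry and the velocity-encoding limit (venc).
#'
#' World coordinates are voxel-centre positions in millimetres,
#' \code{origin + (index - 1) * spacing}, axis order (x, y, z).
#'
#' @slot velocity 5-D numeric array \code{(x, y, z, t, component)} in m/s;
#'   components are the x, y, z velocity directions.
#' @slot magnitude 4-D numeric array \code{(x, y, z, t)}, arbitrary units.
#' @slot spacing numeric(3), voxel spacing in mm (may be anisotropic).
#' @slot origin numeric(3), world position of voxel (1,1,1) in mm.
#' @slot frameDuration length of one cardiac frame in ms; the cycle duration
#'   is \code{frameDuration * nFrames} (retrospectively gated full cycle).
#' @slot venc velocity-encoding limit in m/s; speeds beyond ±venc alias.
#'
#' @seealso [flowField()], [generateStraightTube()], [generateCandyCane()]
#' @export
setClass("FlowField",
    representation(
        velocity = "array",
        magnitude = "array",
        spacing = "numeric",
        origin = "numeric",
        frameDuration = "numeric",
        venc = "numeric"
    )
)

setValidity("FlowField", function(object) {
    dv <- dim(object@velocity)
    dm <- dim(object@magnitude)
    msg <- character()
    if (length(dv) != 5L || dv[5L] != 3L)
        msg <- c(msg, "velocity must be a 5-D array (x, y, z, t, 3)")
    if (length(dm) != 4L)
        msg <- c(msg, "magnitude must be a 4-D array (x, y, z, t)")
    if (length(dv) == 5L && length(dm) == 4L && !all(dv[1:4] == dm))
        msg <- c(msg, "velocity and magnitude grids must share (x, y, z, t) shape")
    if (length(dv) >= 4L && dv[4L] < 2L)
        msg <- c(msg, "at least 2 cardiac frames required")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be 3 finite values (mm)")
    if (length(object@frameDuration) != 1L || object@frameDuration <= 0)
        msg <- c(msg, "frameDuration must be a single positive value (ms)")
    if (length(object@venc) != 1L || object@venc <= 0)
        msg <- c(msg, "venc must be a single positive value (m/s)")
    if (anyNA(object@velocity) || any(!is.finite(object@velocity)))
        msg <- c(msg, "velocities must be finite")
    if (length(msg)) msg else TRUE
})

#' Construct a FlowField
#'
#' @param velocity 5-D array \code{(x, y, z, t, 3)} of velocities in m/s.
#' @param magnitude 4-D array \code{(x, y, z, t)}; defaults to all-ones.
#' @param spacing voxel spacing in mm, recycled to length 3.
#' @param origin world position of the first voxel centre (mm).
#' @param frameDuration cardiac frame duration in ms.
#' @param venc velocity-encoding limit in m/s.
#' @return A validated [FlowField-class] object.
#' @examples
#' v <- array(0, c(4, 4, 4, 3, 3))
#' f <- flowField(v, spacing = 2, frameDuration = 50, venc = 1.5)
#' nFrames(f)
#' @export
flowField <- function(velocity, magnitude = NULL, spacing = 1,
                      origin = c(0, 0, 0), frameDuration = 40, venc = 1.5) {
    if (is.null(magnitude))
        magnitude <- array(1, dim(velocity)[1:4])
    new("FlowField",
        velocity = velocity, magnitude = magnitude,
        spacing = rep_len(as.numeric(spacing), 3L),
        origin = rep_len(as.numeric(origin), 3L),
        frameDuration = as.numeric(frameDuration), venc = as.numeric(venc))
}

#' Centerline: an ordered vessel centreline
#'
#' Ordered lumen centreline in world millimetres with unit tangents and
#' cumulative arc length, resampled at approximately 1 mm steps. The tangent
#' direction defines "downstream" for forward/reverse flow decomposition.
#'
#' @slot points n-by-3 matrix of point positions (mm, world coordinates).
#' @slot tangents n-by-3 matrix of unit tangent vectors.
#' @slot arcLength numeric(n), cumulative arc length (mm), strictly increasing
#'   from 0.
#' @seealso [extractCenterline()], [assignVoxels()]
#' @export
setClass("Centerline",
    representation(points = "matrix", tangents = "matrix", arcLength = "numeric")
)

setValidity("Centerline", function(object) {
    msg <- character()
    n <- nrow(object@points)
    if (n < 2L) msg <- c(msg, "centerline needs at least 2 points")
    if (ncol(object@points) != 3L) msg <- c(msg, "points must be n-by-3")
    if (!all(dim(object@tangents) == dim(object@points)))
        msg <- c(msg, "tangents must match points in shape")
    nrm <- sqrt(rowSums(object@tangents^2))
    if (any(abs(nrm - 1) > 1e-6)) msg <- c(msg, "tangents must be unit-norm")
    if (length(object@arcLength) != n || any(diff(object@arcLength) <= 0))
        msg <- c(msg, "arcLength must be strictly increasing, one per point")
    if (length(msg)) msg else TRUE
})

centerline <- function(points, tangents, arcLength) {
    new("Centerline", points = points, tangents = tangents,
        arcLength = as.numeric(arcLength))
}

#' PlaneAssignment: nearest-plane matching of lumen voxels
#'
#' For every segmented voxel, the index of the nearest centreline point (the
#' plane it belongs to, shortest 3-D distance, ties broken toward the lower
#' / upstream index) and the signed distance along that point's tangent.
#'
#' @slot voxelIndex integer(n), linear indices of the lumen voxels into the
#'   3-D grid of dimension \code{dim}.
#' @slot planeIndex integer(n), matched centreline point per voxel.
#' @slot signedDistance numeric(n), mm along the matched tangent (positive
#'   downstream of the plane).
#' @slot dim integer(3), the grid dimension the indices refer to.
#' @seealso [assignVoxels()]
#' @export
setClass("PlaneAssignment",
    representation(voxelIndex = "integer", planeIndex = "integer",
                   signedDistance = "numeric", dim = "integer")
)

setValidity("PlaneAssignment", function(object) {
    msg <- character()
    n <- length(object@voxelIndex)
    if (length(object@planeIndex) != n || length(object@signedDistance) != n)
        msg <- c(msg, "voxelIndex, planeIndex, signedDistance must align")
    if (n && (min(object@planeIndex) < 1L))
        msg <- c(msg, "planeIndex out of range")
    if (anyDuplicated(object@voxelIndex))
        msg <- c(msg, "each voxel must be assigned exactly once")
    if (length(msg)) msg else TRUE
})

#' RegionLabels: the five aortic analysis regions
#'
#' Partition of the segmented aorta into left ventricular outflow tract
#' (LVOT), ascending aorta (AAo), aortic arch (Arch), proximal descending
#' aorta (PDAo) and distal descending aorta (DDAo), induced by four arc-length
#' boundaries on the centreline.
#'
#' @slot labels factor(n) over levels LVOT, AAo, Arch, PDAo, DDAo, aligned
#'   with the voxels of the generating [PlaneAssignment-class].
#' @slot boundaries numeric(4), strictly increasing arc lengths (mm).
#' @slot pointRegion factor over the same levels, one entry per centreline
#'   point.
#' @seealso [splitRegions()]
#' @export
setClass("RegionLabels",
    representation(labels = "factor", boundaries = "numeric",
                   pointRegion = "factor")
)

#' @export
aorticRegions <- c("LVOT", "AAo", "Arch", "PDAo", "DDAo")

setValidity("RegionLabels", function(object) {
    msg <- character()
    if (!identical(levels(object@labels), aorticRegions))
        msg <- c(msg, "labels must use levels LVOT, AAo, Arch, PDAo, DDAo")
    if (length(object@boundaries) != 4L || any(diff(object@boundaries) <= 0))
        msg <- c(msg, "boundaries must be 4 strictly increasing arc lengths")
    if (anyNA(object@labels)) msg <- c(msg, "every voxel must carry a region")
    if (length(msg)) msg else TRUE
})

#' VoxelMaps: voxel-by-voxel hemodynamic parameter maps
#'
#' Per-voxel forward flow (FF, mL/cycle), reverse flow (RF, mL/cycle), flow
#' stasis (% of cardiac frames with speed below the slow-flow threshold),
#' cycle-summed kinetic energy (µJ) and systolic peak velocity (m/s) over the
#' segmented lumen. Arrays are NA outside the lumen.
#'
#' @slot ff,rf,stasis,ke,peakVelocity 3-D numeric arrays.
#' @slot mask 3-D logical array (lumen).
#' @slot spacing numeric(3), mm.
#' @slot systoleFrames integer, the frames treated as systole for peak
#'   velocity.
#' @export
setClass("VoxelMaps",
    representation(ff = "array", rf = "array", stasis = "array",
                   ke = "array", peakVelocity = "array", mask = "array",
                   spacing = "numeric", systoleFrames = "integer")
)

setValidity("VoxelMaps", function(object) {
    msg <- character()
    d <- dim(object@mask)
    for (s in c("ff", "rf", "stasis", "ke", "peakVelocity"))
        if (!identical(dim(slot(object, s)), d))
            msg <- c(msg, sprintf("%s must share the mask's shape", s))
    m <- object@mask
    chk <- function(x, lo, hi, nm) {
        v <- x[m]
        if (any(!is.na(v) & (v < lo | v > hi)))
            msg <<- c(msg, sprintf("%s out of [%g, %g]", nm, lo, hi))
    }
    chk(object@ff, 0, Inf, "FF"); chk(object@rf, 0, Inf, "RF")
    chk(object@stasis, 0, 100, "stasis"); chk(object@ke, 0, Inf, "KE")
    chk(object@peakVelocity, 0, Inf, "peak velocity")
    if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of the synthetic pulsatile-flow phantom
#'
#' Describes a ground-truthed pulsatile laminar tube-flow dataset: geometry
#' (straight tube or aorta-like candy cane), lumen radius, grid spacing,
#' cardiac timing, waveform, retrograde mixing fraction, helical swirl,
#' noise level and venc.
#'
#' @slot geometry \code{"straight-tube"} or \code{"candy-cane"}.
#' @slot radius lumen radius (mm).
#' @slot length tube length (straight) or limb length (candy cane), mm.
#' @slot archRadius arch radius of curvature (candy cane only), mm.
#' @slot spacing numeric(3), grid spacing (mm), may be anisotropic.
#' @slot nFrames number of cardiac frames.
#' @slot cycleDuration cardiac cycle duration (ms).
#' @slot waveform mean cross-sectional velocity per frame (m/s, signed).
#' @slot retrogradeFraction sign-mixing fraction in [0, 1]: the effective
#'   waveform is \code{(1 - 2 * retrogradeFraction)} times the nominal one, so
#'   0 leaves it unchanged and 1 reverses the flow at every station.
#' @slot swirl helical (azimuthal) velocity amplitude at the wall (m/s).
#' @slot noiseSigma Gaussian velocity noise s.d. (m/s).
#' @slot venc velocity-encoding limit (m/s).
#' @slot seed integer random seed.
#' @seealso [phantomSpec()], [generateStraightTube()], [generateCandyCane()]
#' @export
setClass("PhantomSpec",
    representation(geometry = "character", radius = "numeric",
                   length = "numeric", archRadius = "numeric",
                   spacing = "numeric", nFrames = "integer",
                   cycleDuration = "numeric", waveform = "numeric",
                   retrogradeFraction = "numeric", swirl = "numeric",
                   noiseSigma = "numeric", venc = "numeric", seed = "integer")
)

setValidity("PhantomSpec", function(object) {
    msg <- character()
    if (!object@geometry %in% c("straight-tube", "candy-cane"))
        msg <- c(msg, "geometry must be 'straight-tube' or 'candy-cane'")
    if (object@radius <= 0) msg <- c(msg, "lumen radius must be positive")
    if (object@length <= 0) msg <- c(msg, "length must be positive")
    if (object@nFrames < 2L) msg <- c(msg, "at least 2 frames required")
    if (any(object@spacing <= 0)) msg <- c(msg, "grid spacing must be positive")
    if (object@retrogradeFraction < 0 || object@retrogradeFraction > 1)
        msg <- c(msg, "retrograde fraction must lie in [0, 1]")
    if (object@venc <= 0) msg <- c(msg, "venc must be positive")
    if (length(object@waveform) != object@nFrames)
        msg <- c(msg, "waveform must have one value per frame")
    if (object@noiseSigma < 0) msg <- c(msg, "noise sigma must be non-negative")
    if (object@cycleDuration <= 0) msg <- c(msg, "cycle duration must be positive")
    if (length(msg)) msg else TRUE
})
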
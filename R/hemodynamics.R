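## voxel face area (mm^2) for flow integration; the analysis grid is meant
## to be 1 mm isotropic
.faceArea <- function(spacing) {
    if (diff(range(spacing)) > 1e-6)
        warning("anisotropic grid in flow integration; using mean spacing")
    mean(spacing)^2
}

.newMap <- function(dim) array(NA_real_, dim)

#' Voxel-wise forward and reverse flow maps
#'
#' Projects each lumen voxel's velocity onto the tangent of its matched
#' centreline plane; flow moving downstream (positive projection)
#' accumulates as forward flow (FF), flow moving upstream as reverse flow
#' (RF). Per frame the projected velocity times the voxel face area times
#' the frame duration gives a volume; summing over the cardiac cycle yields
#' mL/cycle per voxel.
#'
#' @param field a [FlowField-class] on the 1 mm isotropic analysis grid.
#' @param assignment a [PlaneAssignment-class] on the same grid.
#' @param cl the [Centerline-class] the assignment was built against.
#' @return list with 3-D arrays \code{ff} and \code{rf} (mL/cycle, NA
#'   outside the lumen).
#' @export
forwardReverseFlow <- function(field, assignment, cl) {
    d <- dim(field@velocity)
    if (!identical(as.integer(d[1:3]), assignment@dim))
        stop("assignment does not match the field grid")
    tg <- cl@tangents[assignment@planeIndex, , drop = FALSE]
    nrm <- sqrt(rowSums(tg^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("internal error: non-unit tangents")
    idx <- assignment@voxelIndex
    dt <- field@frameDuration / 1000            # s
    A <- .faceArea(field@spacing)               # mm^2; v[m/s]*A[mm^2]*dt[s] = mL
    ffv <- rfv <- numeric(length(idx))
    plane <- prod(d[1:3])
    nT <- d[4]
    for (t in seq_len(nT)) {
        vpar <- 0
        for (c in 1:3) {
            off <- ((c - 1) * nT + (t - 1)) * plane
            vpar <- vpar + field@velocity[off + idx] * tg[, c]
        }
        ffv <- ffv + pmax(vpar, 0)
        rfv <- rfv + pmax(-vpar, 0)
    }
    ff <- .newMap(d[1:3]); rf <- .newMap(d[1:3])
    ff[idx] <- ffv * dt * A
    rf[idx] <- rfv * dt * A
    list(ff = ff, rf = rf)
}

#' Voxel-wise flow stasis map
#'
#' Stasis is the percentage of cardiac frames in which a voxel's speed
#' (velocity magnitude) stays below the slow-flow threshold (0.1 m/s by
#' default).
#'
#' @param field a [FlowField-class].
#' @param mask 3-D logical lumen mask.
#' @param constants a [flowConstants()] list.
#' @return 3-D array of stasis in percent (NA outside the lumen).
#' @export
stasisMap <- function(field, mask, constants = flowConstants()) {
    d <- dim(field@velocity)
    idx <- which(mask)
    cnt <- numeric(length(idx))
    for (t in seq_len(d[4]))
        cnt <- cnt + (.frameSpeed(field@velocity, t)[idx] <
                      constants$stasisThreshold)
    out <- .newMap(d[1:3])
    out[idx] <- 100 * cnt / d[4]
    out
}

#' Voxel-wise cycle-summed kinetic energy map
#'
#' Per voxel and frame the kinetic energy is half the blood density times
#' the unit voxel volume times the squared speed; frames are summed over
#' the cardiac cycle and reported in microjoules.
#'
#' @inheritParams stasisMap
#' @return 3-D array of KE in µJ (NA outside the lumen).
#' @examples
#' v <- array(0, c(2, 2, 2, 2, 3)); v[, , , 1, 1] <- 1
#' m <- array(TRUE, c(2, 2, 2))
#' kineticEnergyMap(flowField(v), m)[1, 1, 1]  # 0.53 uJ
#' @export
kineticEnergyMap <- function(field, mask, constants = flowConstants()) {
    d <- dim(field@velocity)
    idx <- which(mask)
    acc <- numeric(length(idx))
    for (t in seq_len(d[4]))
        acc <- acc + .frameSpeed(field@velocity, t)[idx]^2
    out <- .newMap(d[1:3])
    ## 0.5 * rho[kg/m^3] * dV[m^3] * v^2[m^2/s^2] = J; report uJ
    out[idx] <- 0.5 * constants$rho * (constants$voxelVolume * 1e-9) * acc * 1e6
    out
}

#' Detect the systolic frame window
#'
#' Systole is taken as the contiguous frame window containing the frame of
#' maximal spatial-mean lumen speed, extended in both directions while the
#' spatial-mean speed stays at or above a fraction of that maximum.
#'
#' @param field a [FlowField-class].
#' @param mask 3-D logical lumen mask.
#' @param threshold extension threshold as a fraction of the peak
#'   spatial-mean speed (default 0.25).
#' @return integer vector of systolic frame indices.
#' @export
detectSystole <- function(field, mask, threshold = 0.25) {
    d <- dim(field@velocity)
    if (d[4] < 2L) stop("at least 2 frames required")
    idx <- which(mask)
    ms <- vapply(seq_len(d[4]),
                 function(t) mean(.frameSpeed(field@velocity, t)[idx]),
                 numeric(1))
    if (max(ms) <= 0) {
        warning("all-zero field; treating every frame as systolic")
        return(seq_len(d[4]))
    }
    pk <- which.max(ms)
    lo <- pk; hi <- pk
    while (lo > 1L && ms[lo - 1L] >= threshold * ms[pk]) lo <- lo - 1L
    while (hi < d[4] && ms[hi + 1L] >= threshold * ms[pk]) hi <- hi + 1L
    lo:hi
}

#' Systolic peak-velocity map
#'
#' Per voxel, the maximum speed over the systolic frames (a temporal
#' maximum intensity projection).
#'
#' @param field a [FlowField-class].
#' @param mask 3-D logical lumen mask.
#' @param systoleFrames non-empty integer vector of systolic frames.
#' @return 3-D array of peak speed in m/s (NA outside the lumen).
#' @export
peakVelocityMap <- function(field, mask, systoleFrames) {
    if (!length(systoleFrames)) stop("systoleFrames must be non-empty")
    d <- dim(field@velocity)
    idx <- which(mask)
    pk <- rep(-Inf, length(idx))
    for (t in systoleFrames)
        pk <- pmax(pk, .frameSpeed(field@velocity, t)[idx])
    out <- .newMap(d[1:3])
    out[idx] <- pk
    out
}

#' Compute all voxel-wise hemodynamic maps
#'
#' Convenience wrapper producing a [VoxelMaps-class] from a 1 mm field,
#' lumen mask, plane assignment and centreline: FF/RF, stasis, cycle-summed
#' KE and systolic peak velocity.
#'
#' @inheritParams forwardReverseFlow
#' @param mask 3-D logical lumen mask.
#' @param constants a [flowConstants()] list.
#' @param systoleFrames systolic frames; auto-detected when NULL.
#' @return A [VoxelMaps-class].
#' @export
computeVoxelMaps <- function(field, mask, assignment, cl,
                             constants = flowConstants(),
                             systoleFrames = NULL) {
    if (is.null(systoleFrames)) systoleFrames <- detectSystole(field, mask)
    fr <- forwardReverseFlow(field, assignment, cl)
    new("VoxelMaps", ff = fr$ff, rf = fr$rf,
        stasis = stasisMap(field, mask, constants),
        ke = kineticEnergyMap(field, mask, constants),
        peakVelocity = peakVelocityMap(field, mask, systoleFrames),
        mask = array(as.logical(mask), dim(mask)),
        spacing = field@spacing, systoleFrames = as.integer(systoleFrames))
}

.resolveAxis <- function(axis) {
    if (is.character(axis)) match(tolower(axis), c("x", "y", "z")) else
        as.integer(axis)
}

#' Mean intensity projection of a parametric map
#'
#' Averages the masked voxel values along one grid axis; pixels whose ray
#' meets no lumen voxel are NA (absent background), not zero.
#'
#' @param map 3-D array, NA outside the lumen.
#' @param axis 1, 2, 3 or "x", "y", "z".
#' @return 2-D matrix over the remaining axes.
#' @export
meanProjection <- function(map, axis = "y") {
    a <- .resolveAxis(axis)
    out <- apply(map, setdiff(1:3, a), function(v)
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    out
}

#' Maximum intensity projection of a parametric map
#'
#' @inheritParams meanProjection
#' @return 2-D matrix over the remaining axes.
#' @export
mipProjection <- function(map, axis = "y") {
    a <- .resolveAxis(axis)
    apply(map, setdiff(1:3, a), function(v)
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
}

#' Per-region aortic geometry report
#'
#' Joins per-region maximum diameters with their BSA-indexed values and the
#' AAo dilation class.
#'
#' @param diameters named numeric of per-region maximum diameters (mm), as
#'   from [measureDiameters()]\code{$regions}.
#' @param subjectBSA body surface area (m^2).
#' @return data.frame region, diameter, indexedDiameter; attribute
#'   \code{"dilation"} carries the AAo dilation class.
#' @export
aorticGeometryReport <- function(diameters, subjectBSA) {
    df <- data.frame(region = factor(names(diameters), levels = aorticRegions),
                     diameter = as.numeric(diameters),
                     indexedDiameter = indexDiameter(as.numeric(diameters),
                                                     subjectBSA))
    attr(df, "dilation") <- if (is.na(df$diameter[df$region == "AAo"]))
        NA_character_ else classifyDilation(df$diameter[df$region == "AAo"])
    df
}

#' Regional summary of the voxel maps
#'
#' Aggregates the voxel-wise maps over the five regions: arithmetic mean of
#' FF, RF, stasis and KE; regional maximum for peak velocity. Empty regions
#' are reported as NA, not zero. Diameters are joined when a geometry
#' report is supplied.
#'
#' @param maps a [VoxelMaps-class].
#' @param labels a [RegionLabels-class] aligned with \code{assignment}.
#' @param assignment the [PlaneAssignment-class] the labels were built on.
#' @param geometry optional [aorticGeometryReport()] data.frame.
#' @return data.frame with one row per region.
#' @export
regionalSummary <- function(maps, labels, assignment, geometry = NULL) {
    idx <- assignment@voxelIndex
    lab <- labels@labels
    agg <- function(map, fun) vapply(aorticRegions, function(r) {
        v <- map[idx[lab == r]]
        v <- v[!is.na(v)]
        if (!length(v)) NA_real_ else fun(v)
    }, numeric(1))
    out <- data.frame(
        region = factor(aorticRegions, levels = aorticRegions),
        nVoxels = as.integer(table(lab)[aorticRegions]),
        ff = agg(maps@ff, mean), rf = agg(maps@rf, mean),
        stasis = agg(maps@stasis, mean), ke = agg(maps@ke, mean),
        peakVelocity = agg(maps@peakVelocity, max))
    if (!is.null(geometry))
        out <- merge(out, geometry, by = "region", all.x = TRUE, sort = FALSE)
    out[order(out$region), , drop = FALSE]
}

#' Reynolds number at the vena contracta
#'
#' The vena contracta is taken as the centreline station whose cross-section
#' contains the global systolic peak-velocity voxel; the Reynolds number is
#' \code{rho * v_peak * D / mu} with D the effective diameter at that
#' station (converted to metres).
#'
#' @param maps a [VoxelMaps-class] (peak velocity filled).
#' @param assignment a [PlaneAssignment-class].
#' @param diameters result of [measureDiameters()].
#' @param constants a [flowConstants()] list.
#' @return list: \code{reynolds}, \code{vPeak} (m/s), \code{station},
#'   \code{diameter} (mm).
#' @export
reynoldsNumber <- function(maps, assignment, diameters,
                           constants = flowConstants()) {
    idx <- assignment@voxelIndex
    pv <- maps@peakVelocity[idx]
    if (all(is.na(pv)) || max(pv, na.rm = TRUE) == 0)
        return(list(reynolds = 0, vPeak = 0, station = NA_integer_,
                    diameter = NA_real_))
    i <- which.max(pv)
    station <- assignment@planeIndex[i]
    D <- diameters$stations$diameter[station]
    if (is.na(D)) {
        warning("no diameter at the vena contracta station; using nearest valid station")
        ok <- which(!is.na(diameters$stations$diameter))
        station <- ok[which.min(abs(ok - station))]
        D <- diameters$stations$diameter[station]
    }
    vPeak <- pv[i]
    list(reynolds = constants$rho * vPeak * (D / 1000) / constants$mu,
         vPeak = vPeak, station = station, diameter = D)
}
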
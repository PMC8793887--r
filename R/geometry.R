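#' Match every lumen voxel to its nearest centreline plane
#'
#' Each segmented voxel is matched to the centreline point minimising the
#' Euclidean 3-D distance between the voxel centre and the point; ties are
#' broken toward the lower (upstream) index. The matched point's tangent
#' defines the downstream direction for that voxel; the signed distance of
#' the voxel centre along the tangent is returned for plane bookkeeping.
#'
#' @param mask 3-D logical array of lumen voxels.
#' @param cl a [Centerline-class].
#' @param spacing voxel spacing (mm), recycled to 3.
#' @param origin world position of voxel (1,1,1) (mm).
#' @return A [PlaneAssignment-class].
#' @export
assignVoxels <- function(mask, cl, spacing = 1, origin = c(0, 0, 0)) {
    spacing <- rep_len(as.numeric(spacing), 3L)
    idx <- which(mask)
    if (!length(idx)) stop("mask is empty")
    W <- .voxelWorld(idx, dim(mask), spacing, origin)
    k <- .nearestPoint(W, cl@points)
    sd <- rowSums((W - cl@points[k, , drop = FALSE]) *
                  cl@tangents[k, , drop = FALSE])
    new("PlaneAssignment", voxelIndex = as.integer(idx),
        planeIndex = as.integer(k), signedDistance = sd,
        dim = as.integer(dim(mask)))
}

#' Partition the aorta into the five analysis regions
#'
#' Cuts the centreline arc length at four boundaries into LVOT, AAo, Arch,
#' PDAo and DDAo; every voxel inherits the region of its matched centreline
#' point, so the five regions partition the mask.
#'
#' @param cl a [Centerline-class].
#' @param assignment a [PlaneAssignment-class] against \code{cl}.
#' @param boundaries four strictly increasing arc lengths (mm) inside the
#'   centreline span.
#' @return A [RegionLabels-class].
#' @export
splitRegions <- function(cl, assignment, boundaries) {
    boundaries <- as.numeric(boundaries)
    if (length(boundaries) != 4L || any(diff(boundaries) <= 0))
        stop("boundaries must be 4 strictly increasing arc lengths")
    span <- range(cl@arcLength)
    if (boundaries[1] <= span[1] || boundaries[4] >= span[2])
        stop("boundaries must lie strictly inside the centreline arc span")
    pointRegion <- cut(cl@arcLength, c(-Inf, boundaries, Inf),
                       labels = aorticRegions, right = FALSE)
    labels <- pointRegion[assignment@planeIndex]
    new("RegionLabels", labels = labels, boundaries = boundaries,
        pointRegion = pointRegion)
}

#' Per-station and per-region maximum aortic diameters
#'
#' At each centreline point the lumen cross-section is taken as the slab of
#' voxels matched to that point (the plane normal to the local tangent);
#' its area gives the effective circular diameter \code{2 sqrt(A / pi)},
#' which is robust to segmentation roughness. The per-region value is the
#' maximum over that region's stations. Stations with an empty cross-section
#' are skipped and counted in the QC field.
#'
#' @param mask 3-D logical array of lumen voxels.
#' @param cl a [Centerline-class].
#' @param labels a [RegionLabels-class] (optional; when NULL only station
#'   diameters are returned).
#' @param assignment a [PlaneAssignment-class]; computed when NULL.
#' @param spacing,origin grid geometry (mm).
#' @return list: \code{stations} data.frame (index, arcLength, region,
#'   nVoxels, diameter in mm), \code{regions} named numeric of per-region
#'   maxima (mm), \code{qcEmptyStations} count.
#' @export
measureDiameters <- function(mask, cl, labels = NULL, assignment = NULL,
                             spacing = 1, origin = c(0, 0, 0)) {
    spacing <- rep_len(as.numeric(spacing), 3L)
    if (is.null(assignment))
        assignment <- assignVoxels(mask, cl, spacing, origin)
    nPts <- nrow(cl@points)
    ## arc position of every voxel: arc of its matched point plus the signed
    ## offset along that point's tangent; the cross-section at a station is
    ## the slab of voxels within half a slab thickness of its arc length
    s <- cl@arcLength[assignment@planeIndex] + assignment@signedDistance
    ds <- diff(cl@arcLength)
    thick <- pmax(c(ds[1], (ds[-length(ds)] + ds[-1]) / 2, ds[length(ds)]),
                  max(spacing))
    sSort <- sort(s)
    counts <- findInterval(cl@arcLength + thick / 2, sSort) -
              findInterval(cl@arcLength - thick / 2, sSort)
    area <- counts * prod(spacing) / thick            # mm^2
    ## 3-station moving average suppresses slab-count jitter from the
    ## discrete voxel-to-plane matching without masking real calibre change
    if (length(area) >= 3L)
        area <- .movAvg(area, 3L)
    diam <- 2 * sqrt(area / pi)
    empty <- counts == 0L
    diam[empty] <- NA_real_
    counts <- as.integer(counts)
    region <- if (!is.null(labels)) labels@pointRegion else
        factor(rep("AAo", nPts), levels = aorticRegions)
    stations <- data.frame(index = seq_len(nPts), arcLength = cl@arcLength,
                           region = region, nVoxels = counts, diameter = diam)
    regions <- vapply(aorticRegions, function(r) {
        v <- diam[region == r]
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }, numeric(1))
    list(stations = stations, regions = regions,
         qcEmptyStations = sum(empty))
}

#' Body surface area
#'
#' Mosteller's formula \code{sqrt(height * weight / 3600)} by default;
#' Du Bois available as an alternative.
#'
#' @param height height in cm.
#' @param weight weight in kg.
#' @param method \code{"mosteller"} (default) or \code{"dubois"}.
#' @return BSA in m^2.
#' @examples
#' bsa(180, 72)  # 1.897
#' @export
bsa <- function(height, weight, method = c("mosteller", "dubois")) {
    method <- match.arg(method)
    if (any(height <= 0) || any(weight <= 0))
        stop("height and weight must be positive")
    switch(method,
        mosteller = sqrt(height * weight / 3600),
        dubois = 0.007184 * height^0.725 * weight^0.425)
}

#' BSA-indexed diameter
#'
#' @param d diameter in mm.
#' @param bsa body surface area in m^2.
#' @return indexed diameter in mm/m^2.
#' @export
indexDiameter <- function(d, bsa) {
    if (any(bsa <= 0)) stop("BSA must be positive")
    d / bsa
}

#' Classify ascending-aorta dilation severity
#'
#' Grades the maximum AAo diameter: non-dilated below 35 mm, moderately
#' dilated from 35 to below 45 mm, severely dilated from 45 mm. Exact
#' boundary values are assigned to the higher class.
#'
#' @param maxAAoDiameter maximum ascending-aorta diameter (mm).
#' @return one of \code{"non-dilated"}, \code{"moderate"}, \code{"severe"}.
#' @examples
#' classifyDilation(c(30, 40, 50))
#' @export
classifyDilation <- function(maxAAoDiameter) {
    if (any(maxAAoDiameter <= 0)) stop("diameter must be positive")
    out <- ifelse(maxAAoDiameter >= 45, "severe",
           ifelse(maxAAoDiameter >= 35, "moderate", "non-dilated"))
    unname(out)
}

#' Reverse a centreline's orientation
#'
#' Flips the downstream direction: point order is reversed, tangents are
#' negated, arc length is re-measured from the new start.
#'
#' @param cl a [Centerline-class].
#' @return The reversed [Centerline-class].
#' @export
reverseCenterline <- function(cl) {
    n <- nrow(cl@points)
    centerline(cl@points[n:1, , drop = FALSE],
               -cl@tangents[n:1, , drop = FALSE],
               max(cl@arcLength) - cl@arcLength[n:1])
}

#' Orient a centreline along the net flow direction
#'
#' A centreline extracted from a mask alone has an arbitrary orientation.
#' This orients it so the cycle-summed tangent-projected flow over the
#' lumen is positive (net flow runs downstream), reversing centreline and
#' assignment together when needed.
#'
#' @param cl a [Centerline-class].
#' @param assignment the matching [PlaneAssignment-class].
#' @param field the [FlowField-class] the assignment indexes.
#' @return list: \code{centerline}, \code{assignment}, \code{flipped}.
#' @export
orientByFlow <- function(cl, assignment, field) {
    d <- dim(field@velocity)
    tg <- cl@tangents[assignment@planeIndex, , drop = FALSE]
    idx <- assignment@voxelIndex
    net <- 0
    plane <- prod(d[1:3]); nT <- d[4]
    for (t in seq_len(nT)) for (c in 1:3) {
        off <- ((c - 1) * nT + (t - 1)) * plane
        net <- net + sum(field@velocity[off + idx] * tg[, c])
    }
    if (net >= 0)
        return(list(centerline = cl, assignment = assignment, flipped = FALSE))
    n <- nrow(cl@points)
    asg <- new("PlaneAssignment", voxelIndex = assignment@voxelIndex,
               planeIndex = n + 1L - assignment@planeIndex,
               signedDistance = -assignment@signedDistance,
               dim = assignment@dim)
    list(centerline = reverseCenterline(cl), assignment = asg, flipped = TRUE)
}
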
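#' Derive a time-averaged PC-MRA volume
#'
#' Computes the phase-contrast MR angiogram used to depict the lumen: per
#' voxel the magnitude-weighted root-mean-square speed over the cycle,
#' \code{sqrt(mean_t (M(t) * |v(t)|)^2)}. Voxels with flowing blood (high
#' magnitude and speed) score high; static tissue and air score low. The
#' result is invariant to the ordering of the cardiac frames.
#'
#' @param field a [FlowField-class].
#' @return list with \code{data} (3-D non-negative array) and \code{spacing}.
#' @examples
#' v <- array(0.5, c(3, 3, 3, 2, 3))
#' range(computePCMRA(flowField(v))$data)
#' @export
computePCMRA <- function(field) {
    d <- dim(field@velocity)
    acc <- array(0, d[1:3])
    for (t in seq_len(d[4]))
        acc <- acc + (field@magnitude[, , , t] * .frameSpeed(field@velocity, t))^2
    list(data = sqrt(acc / d[4]), spacing = field@spacing)
}

#' Noise masking by magnitude threshold
#'
#' Marks voxels whose time-averaged signal magnitude falls below a given
#' quantile of the image as noise; returns the keep-mask (TRUE = retained
#' for analysis).
#'
#' @param field a [FlowField-class].
#' @param quantile magnitude quantile in (0, 1) below which voxels are
#'   discarded (default 0.3).
#' @return 3-D logical array, same spatial shape as the field.
#' @export
noiseMask <- function(field, quantile = 0.3) {
    if (quantile <= 0 || quantile >= 1)
        stop("quantile must lie strictly between 0 and 1")
    d <- dim(field@magnitude)
    mbar <- apply(field@magnitude, 1:3, mean)
    if (max(mbar) - min(mbar) < .Machine$double.eps * 100) {
        warning("magnitude is constant; keeping all voxels")
        return(array(TRUE, d[1:3]))
    }
    thr <- stats::quantile(mbar, quantile, names = FALSE)
    array(mbar >= thr, d[1:3])
}

## static-tissue auto-detection: low temporal speed variation, above the
## noise floor
.autoStaticMask <- function(field, sdQuantile = 0.2, noiseQuantile = 0.3) {
    d <- dim(field@velocity)
    nT <- d[4]
    spd <- vapply(seq_len(nT), function(t) .frameSpeed(field@velocity, t),
                  array(0, d[1:3]))
    spd <- array(spd, c(d[1:3], nT))
    m <- apply(spd, 1:3, stats::sd)
    keep <- noiseMask(field, noiseQuantile)
    thr <- stats::quantile(m[keep], sdQuantile, names = FALSE)
    keep & (m <= thr)
}

#' Eddy-current background-phase correction
#'
#' Removes the slowly varying background-phase offset eddy currents leave in
#' phase-contrast velocities: for each component, a first-order (planar)
#' polynomial in the world coordinates is fitted to the temporal-mean
#' velocity over static-tissue voxels and subtracted everywhere, so the
#' static-region temporal mean is driven to approximately zero. The
#' operation is idempotent up to fit noise.
#'
#' @param field a [FlowField-class].
#' @param staticMask 3-D logical array of static-tissue voxels; when NULL,
#'   static tissue is auto-detected as voxels above the noise floor whose
#'   temporal speed standard deviation lies in the lowest 20%.
#' @return The corrected [FlowField-class].
#' @seealso [injectEddyOffset()] for the matching artifact generator.
#' @export
correctEddy <- function(field, staticMask = NULL) {
    if (is.null(staticMask)) staticMask <- .autoStaticMask(field)
    d <- dim(field@velocity)
    idx <- which(staticMask)
    if (length(idx) < 10L) {
        warning("fewer than 10 static voxels; eddy-current correction skipped")
        return(field)
    }
    W <- .voxelWorld(idx, d[1:3], field@spacing, field@origin)
    ax <- .axisCoords(d[1:3], field@spacing, field@origin)
    X <- array(rep(ax[[1]], times = d[2] * d[3]), d[1:3])
    Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d[1:3])
    Z <- array(rep(ax[[3]], each = d[1] * d[2]), d[1:3])
    for (c in 1:3) {
        vbar <- apply(field@velocity[, , , , c, drop = FALSE], 1:3, mean)
        fit <- stats::lm.fit(cbind(1, W), vbar[idx])
        cf <- fit$coefficients
        cf[is.na(cf)] <- 0
        off <- cf[1] + cf[2] * X + cf[3] * Y + cf[4] * Z
        for (t in seq_len(d[4]))
            field@velocity[, , , t, c] <- field@velocity[, , , t, c] - off
    }
    field
}

#' Maxwell-term correction (not applicable)
#'
#' Concomitant-gradient (Maxwell-term) phase correction requires the
#' sequence gradient waveforms, which are not available to this pipeline;
#' scanners apply it at reconstruction. This pass-through keeps the
#' preprocessing slot explicit.
#'
#' @param field a [FlowField-class].
#' @return The field, unchanged.
#' @export
correctMaxwell <- function(field) {
    message("Maxwell-term correction not applicable - requires sequence gradient data")
    field
}

#' Temporal velocity anti-aliasing (phase unwrapping)
#'
#' Restores velocities aliased by a too-low venc. Per voxel and component,
#' frame-to-frame jumps larger than venc are removed by adding the
#' appropriate multiple of 2*venc (the first frame is taken as reference).
#' Single-wrap data whose true values stay within 3*venc are recovered
#' exactly. Voxels whose unwrapped magnitude still exceeds 3*venc are
#' counted as irresolvable in the QC attribute.
#'
#' @param field a [FlowField-class] with venc set.
#' @return The unwrapped [FlowField-class]; attribute \code{"qcIrresolvable"}
#'   carries the count of flagged voxels.
#' @seealso [injectAliasing()]
#' @export
unwrapVelocity <- function(field) {
    d <- dim(field@velocity)
    nT <- d[4]
    vn <- field@venc
    nbad <- 0L
    for (c in 1:3) {
        V <- matrix(field@velocity[, , , , c], ncol = nT)
        for (t in 2:nT)  # remove whole-period jumps against the running value
            V[, t] <- V[, t] - 2 * vn * round((V[, t] - V[, t - 1]) / (2 * vn))
        nbad <- nbad + sum(rowSums(abs(V) > 3 * vn) > 0)
        field@velocity[, , , , c] <- array(V, d[1:4])
    }
    attr(field, "qcIrresolvable") <- nbad
    field
}
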
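## separable cubic-spline resampling implemented as per-axis linear
## operators: with fixed input and output grids, 1-D spline interpolation is
## a linear map, so each axis is a dense (m_out x n_in) matrix built by
## interpolating the unit vectors; fmm end conditions reproduce cubic
## polynomials exactly, hence constants and linear ramps survive unchanged.

.interpMatrix <- function(xin, xout, method = c("spline", "nearest")) {
    method <- match.arg(method)
    n <- length(xin)
    W <- matrix(0, length(xout), n)
    if (method == "nearest") {
        j <- vapply(xout, function(x) which.min(abs(xin - x)), integer(1))
        W[cbind(seq_along(xout), j)] <- 1
        return(W)
    }
    for (j in seq_len(n)) {
        e <- numeric(n); e[j] <- 1
        W[, j] <- if (n >= 4)
            stats::spline(xin, e, xout = xout, method = "fmm")$y
        else stats::approx(xin, e, xout = xout, rule = 2)$y
    }
    W
}

## apply per-axis matrices to a 3-D array: successive mode products
.applySeparable <- function(A, Wx, Wy, Wz) {
    d <- dim(A)
    M <- Wx %*% matrix(A, d[1], d[2] * d[3])            # (mx, ny*nz)
    A <- array(M, c(nrow(Wx), d[2], d[3]))
    A <- aperm(A, c(2, 1, 3))
    M <- Wy %*% matrix(A, d[2], nrow(Wx) * d[3])
    A <- array(M, c(nrow(Wy), nrow(Wx), d[3]))
    A <- aperm(A, c(3, 2, 1))
    M <- Wz %*% matrix(A, d[3], nrow(Wx) * nrow(Wy))
    A <- array(M, c(nrow(Wz), nrow(Wx), nrow(Wy)))
    aperm(A, c(2, 3, 1))
}

#' Resample a flow field and mask to an isotropic 1 mm grid
#'
#' Interpolates every velocity component (and the magnitude) to isotropic
#' voxels with cubic splines, on a grid covering the segmentation bounding
#' box plus a small margin; the mask is resampled nearest-neighbour, which
#' preserves the lumen volume. Constant and linear fields are reproduced
#' exactly.
#'
#' @param field a [FlowField-class].
#' @param mask 3-D logical array on the field's grid.
#' @param newSpacing target isotropic spacing (mm, default 1).
#' @param margin margin around the mask bounding box (mm, default 2).
#' @return list with \code{field} (resampled [FlowField-class]) and
#'   \code{mask} (logical array on the new grid).
#' @export
interpolateIsotropic <- function(field, mask, newSpacing = 1, margin = 2) {
    if (!any(mask)) stop("mask is empty")
    d <- dim(field@velocity)
    ax <- .axisCoords(d[1:3], field@spacing, field@origin)
    sub <- arrayInd(which(mask), d[1:3])
    outAx <- vector("list", 3L)
    for (a in 1:3) {
        lo <- max(min(ax[[a]]), ax[[a]][min(sub[, a])] - margin)
        hi <- min(max(ax[[a]]), ax[[a]][max(sub[, a])] + margin)
        lo <- newSpacing * ceiling(lo / newSpacing)  # whole-spacing world grid
        outAx[[a]] <- seq(lo, hi, by = newSpacing)
    }
    Ws <- lapply(1:3, function(a) .interpMatrix(ax[[a]], outAx[[a]], "spline"))
    Wl <- lapply(1:3, function(a) .interpMatrix(ax[[a]], outAx[[a]], "nearest"))
    dimOut <- vapply(outAx, length, integer(1))
    nT <- d[4]
    vel <- array(0, c(dimOut, nT, 3L))
    mag <- array(0, c(dimOut, nT))
    for (t in seq_len(nT)) {
        for (c in 1:3)
            vel[, , , t, c] <- .applySeparable(field@velocity[, , , t, c],
                                               Ws[[1]], Ws[[2]], Ws[[3]])
        mag[, , , t] <- .applySeparable(field@magnitude[, , , t],
                                        Ws[[1]], Ws[[2]], Ws[[3]])
    }
    maskOut <- .applySeparable(array(as.numeric(mask), d[1:3]),
                               Wl[[1]], Wl[[2]], Wl[[3]]) >= 0.5
    out <- flowField(vel, mag, spacing = newSpacing,
                     origin = vapply(outAx, min, numeric(1)),
                     frameDuration = field@frameDuration, venc = field@venc)
    list(field = out, mask = maskOut)
}
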
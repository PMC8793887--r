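## ---- centreline extraction -------------------------------------------------
## The mask is treated as a (possibly curved) tube. The centreline is the
## centredness-weighted geodesic between the two ends of the lumen:
##   1. erosion depth (distance-to-wall proxy) per voxel;
##   2. 26-neighbour voxel graph with edge weight = step length / centredness,
##      so paths hug the lumen core;
##   3. double-sweep to find the two mutually farthest end voxels, then the
##      shortest weighted path between them;
##   4. moving-average smoothing, extension to the mask caps, and 1 mm
##      arc-length resampling with central-difference tangents.

## erosion depth in voxel layers (6-connected peeling), vectorised
.erosionDepth <- function(mask) {
    d <- dim(mask)
    depth <- array(0L, d)
    cur <- mask
    k <- 0L
    shift1 <- function(a, axis, by) {
        out <- array(FALSE, d)
        src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
        n <- d[axis]
        if (by > 0) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
        else { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
        out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
        out
    }
    while (any(cur)) {
        k <- k + 1L
        depth[cur] <- k
        er <- cur
        for (axis in 1:3) for (by in c(-1L, 1L))
            er <- er & shift1(cur, axis, by)
        cur <- er
    }
    depth
}

## 26-neighbour edge list among masked voxels
.maskGraph <- function(mask, spacing) {
    d <- dim(mask)
    idx <- which(mask)
    node <- array(0L, d)
    node[idx] <- seq_along(idx)
    sub <- arrayInd(idx, d)
    offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
    ## half of the offsets suffice (undirected edges)
    keep <- offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
            (offs[, 2] == 0 & offs[, 1] > 0)))
    offs <- offs[keep, , drop = FALSE]
    from <- integer(0); to <- integer(0); len <- numeric(0)
    for (r in seq_len(nrow(offs))) {
        nb <- sweep(sub, 2, offs[r, ], "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
        if (!any(ok)) next
        nbl <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
               (nb[ok, 3] - 1L) * d[1] * d[2]
        tn <- node[nbl]
        hit <- tn > 0L
        from <- c(from, node[idx[ok]][hit])
        to <- c(to, tn[hit])
        len <- c(len, rep(sqrt(sum((offs[r, ] * spacing)^2)), sum(hit)))
    }
    list(from = from, to = to, len = len, idx = idx, sub = sub)
}

## symmetric moving average with shrinking windows at the ends
.movAvg <- function(x, w) {
    h <- max(0L, (w - 1L) %/% 2L)
    n <- length(x)
    vapply(seq_len(n), function(i) {
        hh <- min(h, i - 1L, n - i)
        mean(x[(i - hh):(i + hh)])
    }, numeric(1))
}

#' Extract the vessel centreline from a segmentation mask
#'
#' Reduces a tubular binary mask to an ordered centreline: the two lumen
#' ends are located as the mutually farthest voxels under a
#' centredness-weighted geodesic metric, the connecting path is traced
#' through the lumen core, smoothed, extended to the mask caps and
#' resampled at approximately 1 mm arc steps. Tangents are unit central
#' differences of the smoothed curve.
#'
#' A mask with several connected components, or with a side branch or loop
#' not covered by the main path, is rejected with an informative error, as
#' is a mask too thin or short to carry a meaningful centreline.
#'
#' @param mask 3-D logical (or 0/1) array.
#' @param spacing voxel spacing (mm), recycled to 3.
#' @param origin world position of voxel (1,1,1) (mm).
#' @param resample target arc step of the output (mm).
#' @return A [Centerline-class].
#' @examples
#' p <- generateStraightTube(phantomSpec("straight-tube", radius = 6,
#'     length = 40, spacing = 2, nFrames = 4))
#' cl <- extractCenterline(p$truth$mask, spacing = 2,
#'     origin = gridOrigin(p$field))
#' max(arcLength(cl))
#' @export
extractCenterline <- function(mask, spacing = 1, origin = c(0, 0, 0),
                              resample = 1) {
    spacing <- rep_len(as.numeric(spacing), 3L)
    mask <- array(as.logical(mask), dim(mask))
    if (!any(mask)) stop("mask is empty")
    d <- dim(mask)
    g <- .maskGraph(mask, spacing)
    gr <- igraph::graph_from_edgelist(cbind(g$from, g$to), directed = FALSE)
    if (igraph::vcount(gr) < length(g$idx))
        gr <- igraph::add_vertices(gr, length(g$idx) - igraph::vcount(gr))
    comp <- igraph::components(gr)
    if (comp$no > 1L)
        stop(sprintf("mask has %d connected components; expected a single tube",
                     comp$no))
    depth <- .erosionDepth(mask)
    maxDepth <- max(depth)
    if (maxDepth < 2L || length(g$idx) < 30L)
        stop("mask is too thin or too small to carry a centreline (degenerate tube)")
    ## centredness-weighted edge length: deep (core) voxels are cheap
    dmid <- (depth[g$idx[g$from]] + depth[g$idx[g$to]]) / 2
    w <- g$len / (0.25 + dmid)^2
    gr <- igraph::set_edge_attr(gr, "weight", value = w)
    far <- function(v) {
        ds <- igraph::distances(gr, v = v)[1, ]
        which.max(ds)
    }
    e1 <- far(1L)
    e2 <- far(e1)
    path <- igraph::shortest_paths(gr, from = e1, to = e2,
                                   output = "vpath")$vpath[[1]]
    path <- as.integer(path)
    if (length(path) < 5L)
        stop("extracted path is too short; mask is not a usable tube")
    P <- sweep(sweep(g$sub[path, , drop = FALSE] - 1, 2, spacing, "*"),
               2, origin, "+")
    ## branch / loop guard: the single end-to-end path must explain the
    ## whole mask within a radius-scaled envelope
    maxR <- maxDepth * max(spacing)
    all3 <- sweep(sweep(g$sub - 1, 2, spacing, "*"), 2, origin, "+")
    nearest <- .nearestPoint(all3, P)
    resid <- sqrt(rowSums((all3 - P[nearest, , drop = FALSE])^2))
    if (any(resid > 1.5 * maxR + 2 * max(spacing)))
        stop("mask contains a loop or branch not covered by a single centreline path")
    ## the geodesic enters the lumen at a cap-rim voxel; trim the shallow
    ## ramp at each end (it is off-axis by construction) and recover the
    ## axial length later by extending the smoothed curve to the caps
    pd <- depth[g$idx[path]]
    thr <- max(2, ceiling(0.75 * stats::median(pd)))
    cap <- 3L * maxDepth                 # never trim deep into the lumen
    lo <- 1L; hi <- length(path)
    while (lo < min(hi - 4L, cap) && pd[lo] < thr) lo <- lo + 1L
    while (hi > max(lo + 4L, length(path) - cap) && pd[hi] < thr) hi <- hi - 1L
    path <- path[lo:hi]
    P <- P[lo:hi, , drop = FALSE]

    ## smooth with a window comparable to the lumen radius
    wlen <- 2L * as.integer(ceiling(maxDepth)) + 1L
    S <- apply(P, 2, .movAvg, w = wlen)
    ## extend the smoothed curve along its end tangents to the mask caps
    insideMask <- function(p) {
        v <- round((p - origin) / spacing) + 1
        all(v >= 1) && all(v <= d) && mask[v[1], v[2], v[3]]
    }
    extend <- function(S, headEnd) {
        n <- nrow(S)
        k <- min(12L, n - 1L)  # multi-point end tangent: robust to jitter
        tg <- if (headEnd) S[1, ] - S[k + 1, ] else S[n, ] - S[n - k, ]
        tg <- tg / sqrt(sum(tg^2))
        p0 <- if (headEnd) S[1, ] else S[n, ]
        added <- NULL
        smax <- 0
        for (s in seq(0.25, 3 * maxR + 6 * max(spacing), by = 0.25)) {
            if (!insideMask(p0 + s * tg)) break
            smax <- s
        }
        ## stop at the cap voxel centres, not their far edge
        smax <- smax - sum(abs(tg) * spacing) / 2
        if (smax >= 0.25)
            added <- t(vapply(seq(0.25, smax, by = 0.25),
                              function(s) p0 + s * tg, numeric(3)))
        ## re-centre each extended station in-plane: the slab is taken
        ## perpendicular to the (straight) end direction, so cap truncation
        ## cannot bias the in-plane centroid
        if (!is.null(added)) {
            h <- max(spacing)
            for (i in seq_len(nrow(added))) {
                dW <- all3 - matrix(added[i, ], nrow(all3), 3, byrow = TRUE)
                a <- as.numeric(dW %*% tg)
                perp2 <- rowSums(dW^2) - a^2
                ## local slab only: stay clear of unrelated vessel segments
                sel <- abs(a) <= h / 2 & perp2 <= (maxR + 2 * h)^2
                if (sum(sel) >= 5) {
                    corr <- colMeans(all3[sel, , drop = FALSE]) - added[i, ]
                    corr <- corr - sum(corr * tg) * tg
                    added[i, ] <- added[i, ] + corr
                }
            }
        }
        if (is.null(added)) S
        else if (headEnd) rbind(added[rev(seq_len(nrow(added))), , drop = FALSE], S)
        else rbind(S, added)
    }
    ## slab-centroid refinement: each station moves to the centre of mass of
    ## its cross-sectional slab, which removes the residual bias the rough
    ## geodesic carries near the lumen entry and inside bends; extension to
    ## the end caps only happens once the end tangents are trustworthy
    thick <- pmax(resample, max(spacing))
    Q <- .resampleCurve(S, resample)
    Q <- .centroidRefine(Q, all3, thick)
    Q <- .resampleCurve(apply(Q, 2, .movAvg, w = 5L), resample)
    ## the refined stations nearest the curve ends are biased (every
    ## beyond-end voxel is matched to the terminal station through its
    ## tangent): drop them, then rebuild the ends by extending the clean
    ## interior to the caps along its end tangents; extended stations are
    ## not re-refined because cap-truncated slabs would bias the centroids
    nTrim <- max(3L, as.integer(ceiling(1.5 * maxDepth)))
    if (nrow(Q) > 2L * nTrim + 10L)
        Q <- Q[(nTrim + 1L):(nrow(Q) - nTrim), , drop = FALSE]
    Q <- extend(Q, TRUE)
    Q <- extend(Q, FALSE)
    Q <- .resampleCurve(Q, resample)
    arc <- c(0, cumsum(sqrt(rowSums(diff(Q)^2))))
    ## central-difference unit tangents over a +-3-station baseline
    ## (suppresses direction jitter from residual 1 mm-scale wiggle)
    n <- nrow(Q)
    h <- min(3L, n - 1L)
    iLo <- pmax(seq_len(n) - h, 1L)
    iHi <- pmin(seq_len(n) + h, n)
    Tg <- Q[iHi, , drop = FALSE] - Q[iLo, , drop = FALSE]
    Tg <- Tg / sqrt(rowSums(Tg^2))
    centerline(Q, Tg, arc)
}

## spline resampling of a polyline at uniform arc steps
.resampleCurve <- function(S, step) {
    seg <- sqrt(rowSums(diff(S)^2))
    S <- S[c(TRUE, seg > 1e-9), , drop = FALSE]
    s <- c(0, cumsum(sqrt(rowSums(diff(S)^2))))
    sout <- seq(0, max(s), by = step)
    if (length(sout) < 2L) sout <- c(0, max(s))
    matrix(vapply(1:3, function(a) stats::spline(s, S[, a], xout = sout)$y,
                  numeric(length(sout))), ncol = 3)
}

## one pass of cross-sectional slab centroids along an approximate
## centreline; W is the n-by-3 matrix of lumen voxel centres (mm).
## Inside a bend an arc-length slab under-samples the inner side (physical
## arc shrinks by (1 - u kappa) at offset u toward the curvature centre),
## so voxels are weighted by the inverse metric factor.
.centroidRefine <- function(Q, W, thick) {
    n <- nrow(Q)
    k <- .nearestPoint(W, Q)
    seg <- sqrt(rowSums(diff(Q)^2))
    arc <- c(0, cumsum(seg))
    tg <- rbind(Q[2, ] - Q[1, ], diff(Q))
    tg <- tg / sqrt(rowSums(tg^2))
    ## curvature vector by second differences on a 5-point baseline
    curv <- matrix(0, n, 3)
    if (n >= 5) {
        i <- 3:(n - 2)
        ds <- (arc[i + 2] - arc[i - 2]) / 2
        curv[i, ] <- (Q[i + 2, ] - 2 * Q[i, ] + Q[i - 2, ]) / ds^2
    }
    s <- arc[k] + rowSums((W - Q[k, , drop = FALSE]) * tg[k, , drop = FALSE])
    out <- Q
    cnt <- integer(n)
    for (i in seq_len(n)) {
        inSlab <- which(abs(s - arc[i]) <= thick / 2)
        cnt[i] <- length(inSlab)
        if (!cnt[i]) next
        Wi <- W[inSlab, , drop = FALSE]
        u <- (Wi - matrix(Q[i, ], cnt[i], 3, byrow = TRUE)) %*% curv[i, ]
        w <- pmin(pmax(1 / pmax(1 - u, 0.25), 0.5), 4)  # u = offset * kappa
        out[i, ] <- colSums(Wi * as.numeric(w)) / sum(w)
    }
    ## drop stations with grossly deficient slabs (beyond the caps)
    out[cnt >= 0.25 * stats::median(cnt), , drop = FALSE]
}
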
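#' Aorta-like mean-velocity waveform
#'
#' Builds the default cardiac waveform of the phantoms: a half-sine systolic
#' ejection over the first part of the cycle, a small retrograde lobe
#' immediately after (early-diastolic flow reversal at valve closure), and
#' zero diastolic flow. Values are the mean cross-sectional velocity per
#' frame (m/s, signed along the local downstream direction).
#'
#' @param nFrames number of cardiac frames.
#' @param peak systolic peak of the mean cross-sectional velocity (m/s).
#' @param systoleFraction fraction of the cycle occupied by systole.
#' @param lobeFraction fraction of the cycle occupied by the retrograde lobe.
#' @param lobeAmplitude retrograde lobe peak as a fraction of \code{peak}.
#' @return numeric(nFrames).
#' @examples
#' aorticWaveform(20)
#' @export
aorticWaveform <- function(nFrames, peak = 0.8, systoleFraction = 0.35,
                           lobeFraction = 0.15, lobeAmplitude = 0.1) {
    tc <- (seq_len(nFrames) - 0.5) / nFrames   # frame-centre phase in [0,1)
    w <- numeric(nFrames)
    sys <- tc < systoleFraction
    w[sys] <- peak * sin(pi * tc[sys] / systoleFraction)
    lobe <- !sys & tc < systoleFraction + lobeFraction
    w[lobe] <- -lobeAmplitude * peak *
        sin(pi * (tc[lobe] - systoleFraction) / lobeFraction)
    w
}

#' Construct a PhantomSpec
#'
#' Parameters default to an acquisition-like configuration: 2.4 mm isotropic
#' spacing, 20 frames over a 1000 ms cycle, venc 1.5 m/s, and the
#' [aorticWaveform()] shape, so that the 1 mm re-interpolation step of the
#' analysis is exercised nontrivially.
#'
#' @param geometry \code{"straight-tube"} or \code{"candy-cane"}.
#' @param radius lumen radius (mm).
#' @param length tube length (straight tube) or length of each vertical limb
#'   (candy cane), mm.
#' @param archRadius radius of the semicircular arch (candy cane), mm; must
#'   be at least twice the lumen radius or the geometry self-intersects.
#' @param spacing grid spacing (mm), recycled to 3 axes.
#' @param nFrames number of cardiac frames.
#' @param cycleDuration cardiac cycle duration (ms).
#' @param waveform mean cross-sectional velocity per frame (m/s, signed);
#'   default [aorticWaveform()].
#' @param retrogradeFraction sign-mixing fraction in [0, 1] applied to the
#'   waveform: the effective waveform is \code{(1 - 2 * retrogradeFraction)}
#'   times the nominal one (0 = unchanged, 1 = fully reversed flow).
#' @param swirl helical (azimuthal) velocity amplitude at the wall (m/s);
#'   the swirl follows the waveform envelope in time.
#' @param noiseSigma Gaussian velocity noise standard deviation (m/s).
#' @param venc velocity-encoding limit (m/s).
#' @param seed integer random seed (noise is fully reproducible).
#' @return A validated [PhantomSpec-class].
#' @examples
#' phantomSpec("straight-tube", radius = 8, length = 60)
#' @export
phantomSpec <- function(geometry = c("candy-cane", "straight-tube"),
                        radius = 8, length = 50, archRadius = 40,
                        spacing = 2.4, nFrames = 20L, cycleDuration = 1000,
                        waveform = NULL, retrogradeFraction = 0, swirl = 0,
                        noiseSigma = 0, venc = 1.5, seed = 1L) {
    geometry <- match.arg(geometry)
    nFrames <- as.integer(nFrames)
    if (is.null(waveform)) waveform <- aorticWaveform(nFrames)
    new("PhantomSpec", geometry = geometry, radius = radius, length = length,
        archRadius = archRadius, spacing = rep_len(as.numeric(spacing), 3L),
        nFrames = nFrames, cycleDuration = cycleDuration,
        waveform = as.numeric(waveform),
        retrogradeFraction = retrogradeFraction, swirl = swirl,
        noiseSigma = noiseSigma, venc = venc, seed = as.integer(seed))
}

## dense analytic centreline (step mm) for either geometry; returns points,
## unit tangents, arc length, and for the candy cane the default region
## boundaries (fractions of the span chosen so all five regions are populated)
.phantomCenterline <- function(spec, step = 0.5) {
    R <- spec@radius
    if (spec@geometry == "straight-tube") {
        s <- seq(0, spec@length, by = step)
        P <- cbind(0, 0, s)
        Tg <- matrix(rep(c(0, 0, 1), each = length(s)), ncol = 3)
        bounds <- NULL
    } else {
        Ra <- spec@archRadius
        if (Ra < 2 * R)
            stop("candy-cane arch radius must be at least twice the lumen radius (self-intersection)")
        L <- spec@length
        total <- 2 * L + pi * Ra
        s <- seq(0, total, by = step)
        P <- matrix(0, length(s), 3)
        Tg <- matrix(0, length(s), 3)
        asc <- s <= L
        P[asc, ] <- cbind(0, 0, s[asc])
        Tg[asc, ] <- matrix(rep(c(0, 0, 1), each = sum(asc)), ncol = 3)
        arch <- s > L & s <= L + pi * Ra
        th <- (s[arch] - L) / Ra
        P[arch, ] <- cbind(Ra - Ra * cos(th), 0, L + Ra * sin(th))
        Tg[arch, ] <- cbind(sin(th), 0, cos(th))
        desc <- s > L + pi * Ra
        P[desc, ] <- cbind(2 * Ra, 0, L - (s[desc] - L - pi * Ra))
        Tg[desc, ] <- matrix(rep(c(0, 0, -1), each = sum(desc)), ncol = 3)
        bounds <- c(0.10, 0.45, 0.60, 0.80) * total
    }
    list(points = P, tangents = Tg, arc = s, boundaries = bounds,
         analyticLength = if (spec@geometry == "straight-tube") spec@length
                          else 2 * spec@length + pi * spec@archRadius)
}

## grid axes covering the lumen with a margin of background voxels; the
## lower corner is snapped to a multiple of the spacing so the tube axis
## falls on voxel centres whenever the spacing divides the geometry
.phantomGrid <- function(spec, margin = 2) {
    R <- spec@radius; sp <- spec@spacing
    m <- (margin + 0.5) * sp + R
    if (spec@geometry == "straight-tube") {
        lo <- c(-m[1], -m[2], -margin * sp[3])
        hi <- c(m[1], m[2], spec@length + margin * sp[3])
    } else {
        Ra <- spec@archRadius
        lo <- c(-m[1], -m[2], -margin * sp[3])
        hi <- c(2 * Ra + m[1], m[2], spec@length + Ra + m[3])
    }
    lo <- sp * floor(lo / sp)
    dim <- pmax(2L, as.integer(ceiling((hi - lo) / sp)) + 1L)
    list(dim = dim, origin = lo)
}

## shared generator core: Poiseuille profile along the local tangent plus
## optional helical swirl, analytic truth, then noise on top
.generatePhantom <- function(spec) {
    validObject(spec)
    cl <- .phantomCenterline(spec)
    g <- .phantomGrid(spec)
    dim <- g$dim; origin <- g$origin; sp <- spec@spacing
    R <- spec@radius
    nT <- spec@nFrames
    veff <- (1 - 2 * spec@retrogradeFraction) * spec@waveform
    vmax <- max(abs(veff))

    nvox <- prod(dim)
    xyz <- .voxelWorld(seq_len(nvox), dim, sp, origin)
    k <- .nearestPoint(xyz, cl$points)
    rvec <- xyz - cl$points[k, , drop = FALSE]
    tg <- cl$tangents[k, , drop = FALSE]
    ax <- rowSums(rvec * tg)                    # axial offset from the point
    rperp <- rvec - ax * tg
    d <- sqrt(rowSums(rperp^2))                 # perpendicular (radial) dist
    ## inside the lumen: within the radius, and not beyond the end caps
    ## (the nearest sample of an out-of-cap voxel is the first/last station)
    M <- nrow(cl$points)
    inside <- d <= R & !(k == 1L & ax < -0.25) & !(k == M & ax > 0.25)
    mask <- array(inside, dim)

    idx <- which(inside)
    profile <- 2 * (1 - (d[idx] / R)^2)         # Poiseuille shape, peak 2*Vbar
    tgI <- tg[idx, , drop = FALSE]
    swirlU <- matrix(0, length(idx), 3)
    if (spec@swirl != 0) {
        u <- rperp[idx, , drop = FALSE] / pmax(d[idx], 1e-9)
        ## azimuthal unit vector: tangent x radial
        swirlU <- cbind(tgI[, 2] * u[, 3] - tgI[, 3] * u[, 2],
                        tgI[, 3] * u[, 1] - tgI[, 1] * u[, 3],
                        tgI[, 1] * u[, 2] - tgI[, 2] * u[, 1])
        swirlU <- swirlU * spec@swirl * (d[idx] / R)
    }

    vel <- array(0, c(dim, nT, 3L))
    speed2sum <- numeric(length(idx))
    slowCount <- integer(length(idx))
    plane <- prod(dim)
    for (t in seq_len(nT)) {
        env <- if (vmax > 0) veff[t] / vmax else 0
        vax <- veff[t] * profile
        vmat <- tgI * vax + swirlU * env
        spd2 <- rowSums(vmat^2)
        speed2sum <- speed2sum + spd2
        slowCount <- slowCount + (sqrt(spd2) < 0.1)
        for (c in 1:3) {
            off <- ((c - 1) * nT + (t - 1)) * plane
            vel[off + idx] <- vmat[, c]
        }
    }

    mag <- array(0.1, c(dim, nT))
    for (t in seq_len(nT)) mag[(t - 1) * plane + idx] <- 1

    if (spec@noiseSigma > 0) {
        .withSeed(spec@seed, {
            vel <- vel + array(stats::rnorm(length(vel), sd = spec@noiseSigma),
                               dim(vel))
            mag <- pmax(mag + array(stats::rnorm(length(mag),
                                                 sd = spec@noiseSigma),
                                    dim(mag)), 0)
        })
    }

    field <- flowField(vel, mag, spacing = sp, origin = origin,
                       frameDuration = spec@cycleDuration / nT,
                       venc = spec@venc)

    ## analytic truth (noiseless)
    keep <- seq(1, length(cl$arc), by = max(1L, round(1 / mean(diff(cl$arc)))))
    stasisT <- array(NA_real_, dim)
    stasisT[idx] <- 100 * slowCount / nT
    keT <- array(NA_real_, dim)
    dt_s <- spec@cycleDuration / nT / 1000
    ## cycle-summed KE per unit (1 mm^3) voxel, uJ: 0.5*1060*1e-9*v^2*1e6
    keT[idx] <- 0.5 * 1060 * 1e-9 * speed2sum * 1e6
    truth <- structure(list(
        centerline = cl$points[keep, , drop = FALSE],
        tangents = cl$tangents[keep, , drop = FALSE],
        arcLength = cl$arc[keep],
        analyticLength = cl$analyticLength,
        flowRate = outer(rep(1, length(keep)), veff * pi * R^2),  # mL/s
        strokeVolume = sum(pmax(veff, 0)) * dt_s * pi * R^2,      # mL/cycle
        waveform = veff,
        stasis = stasisT,
        ke = keT,
        mask = mask,
        regionBoundaries = cl$boundaries
    ), class = "PhantomTruth")
    stopifnot(sum(mask) > 0)
    list(field = field, truth = truth)
}

#' Generate a straight-tube pulsatile flow phantom
#'
#' Pulsatile laminar (Poiseuille) flow along a straight tube on a regular
#' grid: inside the lumen the axial velocity is
#' \code{2 * Vbar(t) * (1 - (r/R)^2)} with optional helical swirl, outside
#' it is zero; Gaussian noise is added everywhere when requested. Exact
#' ground truth (centreline, per-station flow rate, per-voxel stasis and
#' cycle-summed kinetic energy, lumen mask) is returned alongside.
#'
#' @param spec a [PhantomSpec-class] with \code{geometry = "straight-tube"}.
#' @return list with elements \code{field} ([FlowField-class]) and
#'   \code{truth} (a \code{PhantomTruth} list: \code{centerline},
#'   \code{tangents}, \code{arcLength}, \code{flowRate} in mL/s per station
#'   and frame, \code{strokeVolume} in mL, \code{stasis} and \code{ke}
#'   arrays, \code{mask}, and for the candy cane \code{regionBoundaries}).
#' @examples
#' p <- generateStraightTube(phantomSpec("straight-tube", radius = 6,
#'     length = 30, spacing = 2, nFrames = 5))
#' sum(p$truth$mask)
#' @export
generateStraightTube <- function(spec) {
    if (spec@geometry != "straight-tube")
        stop("spec geometry must be 'straight-tube'")
    .generatePhantom(spec)
}

#' Generate a candy-cane (aorta-like) pulsatile flow phantom
#'
#' Same flow model as [generateStraightTube()] on an aorta-like geometry:
#' a vertical ascending limb, a semicircular arch, and a vertical descending
#' limb. The truth carries the arc-length parameterised centreline and the
#' four default region boundary arc lengths (10/45/60/80% of the span), so
#' all five analysis regions are populated.
#'
#' @inheritParams generateStraightTube
#' @return As [generateStraightTube()].
#' @export
generateCandyCane <- function(spec) {
    if (spec@geometry != "candy-cane")
        stop("spec geometry must be 'candy-cane'")
    .generatePhantom(spec)
}

#' Wrap velocities beyond the venc (manufacture aliasing)
#'
#' Applies the phase-wrapping a too-low velocity-encoding limit produces:
#' each component is mapped by \code{v -> ((v + venc) mod 2 venc) - venc}.
#' Values already within \code{(-venc, venc]} are unchanged, so the
#' operation is idempotent.
#'
#' @param field a [FlowField-class].
#' @return The field with aliased velocities.
#' @examples
#' f <- flowField(array(1.2, c(2, 2, 2, 2, 3)), venc = 1)
#' range(velocityData(injectAliasing(f)))  # -0.8
#' @export
injectAliasing <- function(field) {
    v <- field@velocity
    vn <- field@venc
    out <- ((v + vn) %% (2 * vn)) - vn
    keep <- v > -vn & v <= vn
    out[keep] <- v[keep]
    field@velocity <- out
    field
}

#' Add a static, spatially linear background-phase offset
#'
#' Manufactures an eddy-current-like artifact: a time-constant offset
#' \code{a + b x + c y + d z} (world mm) added to each velocity component.
#'
#' @param field a [FlowField-class].
#' @param coefficients 3-by-4 numeric matrix, one row per velocity component:
#'   intercept (m/s) and x, y, z slopes (m/s per mm).
#' @return The offset field.
#' @seealso [correctEddy()] for the removal.
#' @export
injectEddyOffset <- function(field, coefficients) {
    coefficients <- matrix(as.numeric(coefficients), 3L, 4L)
    if (any(!is.finite(coefficients)))
        stop("eddy offset coefficients must be finite")
    d <- dim(field@velocity)
    ax <- .axisCoords(d[1:3], field@spacing, field@origin)
    X <- array(rep(ax[[1]], times = d[2] * d[3]), d[1:3])
    Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d[1:3])
    Z <- array(rep(ax[[3]], each = d[1] * d[2]), d[1:3])
    for (c in 1:3) {
        off <- coefficients[c, 1] + coefficients[c, 2] * X +
            coefficients[c, 3] * Y + coefficients[c, 4] * Z
        for (t in seq_len(d[4]))
            field@velocity[, , , t, c] <- field@velocity[, , , t, c] + off
    }
    field
}
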
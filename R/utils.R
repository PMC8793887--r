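#' Physical constants for hemodynamic mapping
#'
#' Bundles the constants of the voxel-wise energy and flow computations:
#' blood density, the unit voxel volume of the 1 mm isotropic analysis grid,
#' the slow-flow (stasis) speed threshold, and blood dynamic viscosity for
#' the Reynolds number.
#'
#' @param rho blood density, kg/m^3 (default 1060).
#' @param voxelVolume unit voxel volume, mm^3 (default 1, the isotropic
#'   analysis voxel).
#' @param stasisThreshold slow-flow speed threshold, m/s (default 0.1).
#' @param mu blood dynamic viscosity, Pa s (default 3.5e-3, typical whole
#'   blood).
#' @return A named list with class \code{"flowConstants"}.
#' @examples
#' flowConstants()
#' @export
flowConstants <- function(rho = 1060, voxelVolume = 1,
                          stasisThreshold = 0.1, mu = 3.5e-3) {
    vals <- c(rho = rho, voxelVolume = voxelVolume,
              stasisThreshold = stasisThreshold, mu = mu)
    if (any(!is.finite(vals)) || any(vals <= 0))
        stop("all physical constants must be positive and finite")
    structure(list(rho = rho, voxelVolume = voxelVolume,
                   stasisThreshold = stasisThreshold, mu = mu),
              class = "flowConstants")
}

## voxel-centre world coordinates along each axis (mm)
.axisCoords <- function(dim, spacing, origin) {
    lapply(1:3, function(a) origin[a] + (seq_len(dim[a]) - 1) * spacing[a])
}

## n-by-3 matrix of voxel-centre world coordinates for given linear indices
.voxelWorld <- function(idx, dim, spacing, origin) {
    sub <- arrayInd(idx, dim)
    sweep(sweep(sub - 1, 2, spacing, "*"), 2, origin, "+")
}

## evaluate expr with a local, restored RNG state
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

## per-voxel speed for one frame: 3-D array
.frameSpeed <- function(vel, t) {
    sqrt(vel[, , , t, 1]^2 + vel[, , , t, 2]^2 + vel[, , , t, 3]^2)
}

## nearest row of pts (m-by-3) for each row of x (n-by-3), chunked;
## first (lowest-index) minimum wins on ties
.nearestPoint <- function(x, pts, chunk = 4096L) {
    n <- nrow(x)
    idx <- integer(n)
    p2 <- rowSums(pts^2)
    tp <- t(pts)
    for (s in seq(1L, n, by = chunk)) {
        e <- min(s + chunk - 1L, n)
        xc <- x[s:e, , drop = FALSE]
        d2 <- sweep(-2 * (xc %*% tp), 2, p2, "+")  # row offsets |x|^2 irrelevant
        idx[s:e] <- max.col(-d2, ties.method = "first")
    }
    idx
}
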
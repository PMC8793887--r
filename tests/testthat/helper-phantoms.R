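# Shared small phantoms, built once per test run. Sizes are kept small so
# the suite stays fast; the geometry is exercised at acquisition-like
# spacing in the acceptance tests.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
    if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
    .cache[[name]]
}

# straight tube at 2 mm spacing, constant flow
tinyTube <- function() cached("tinyTube", {
    generateStraightTube(phantomSpec("straight-tube", radius = 5, length = 40,
                                     spacing = 2, nFrames = 10,
                                     waveform = rep(0.2, 10), seed = 7))
})

# straight tube generated natively at 1 mm (no resampling needed):
# the parametric-map oracles compare against its analytic truth directly
tube1mm <- function() cached("tube1mm", {
    generateStraightTube(phantomSpec("straight-tube", radius = 5, length = 24,
                                     spacing = 1, nFrames = 12,
                                     waveform = aorticWaveform(12, peak = 0.6),
                                     seed = 3))
})

# small candy cane at 2 mm
tinyCane <- function() cached("tinyCane", {
    generateCandyCane(phantomSpec("candy-cane", radius = 6, length = 30,
                                  archRadius = 24, spacing = 2, nFrames = 8,
                                  waveform = aorticWaveform(8), seed = 11))
})

# a random velocity field with magnitude, for brute-force oracles
randomField <- function(dim = c(5, 4, 3), nT = 6, seed = 42, venc = 1.5) {
    withr::with_seed(seed, {
        flowField(array(rnorm(prod(dim) * nT * 3, sd = 0.4), c(dim, nT, 3)),
                  array(runif(prod(dim) * nT), c(dim, nT)),
                  spacing = 1, frameDuration = 50, venc = venc)
    })
}
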
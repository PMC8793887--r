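test_that("isotropic resampling reproduces constants and linear ramps", {
    mask <- array(TRUE, c(6, 5, 7))
    v <- array(0.3, c(6, 5, 7, 3, 3))
    f <- flowField(v, spacing = c(2, 2.5, 3), frameDuration = 40)
    iso <- interpolateIsotropic(f, mask)
    expect_equal(voxelSpacing(iso$field), rep(1, 3))
    expect_equal(max(abs(velocityData(iso$field) - 0.3)), 0, tolerance = 1e-12)
    # linear in z is reproduced exactly by the cubic interpolant
    zc <- VoxelFlow:::.axisCoords(c(6, 5, 7), c(2, 2.5, 3), c(0, 0, 0))[[3]]
    for (k in 1:7) v[, , k, , 1] <- 0.01 * zc[k]
    f2 <- flowField(v, spacing = c(2, 2.5, 3), frameDuration = 40)
    iso2 <- interpolateIsotropic(f2, mask)
    zo <- VoxelFlow:::.axisCoords(dim(iso2$mask), rep(1, 3),
                                  gridOrigin(iso2$field))[[3]]
    got <- velocityData(iso2$field)[1, 1, , 1, 1]
    expect_equal(got, 0.01 * zo, tolerance = 1e-10)
    expect_error(interpolateIsotropic(f, array(FALSE, c(6, 5, 7))), "empty")
})

test_that("lumen volume survives resampling within 5%", {
    p <- tinyCane()
    iso <- interpolateIsotropic(p$field, p$truth$mask)
    v0 <- sum(p$truth$mask) * 8                      # 2 mm voxels
    v1 <- sum(iso$mask) * 1
    expect_lt(abs(v1 / v0 - 1), 0.05)
})

straightAnalysis <- function(p, spacing = 1) {
    cl <- extractCenterline(p$truth$mask, spacing = spacing,
                            origin = gridOrigin(p$field))
    asg <- assignVoxels(p$truth$mask, cl, spacing, gridOrigin(p$field))
    ori <- orientByFlow(cl, asg, p$field)
    list(cl = ori$centerline, asg = ori$assignment)
}

test_that("constant axial flow yields the closed-form FF and zero RF", {
    # 0.15 m/s along +z for a full 1 s cycle: 0.15 mL/cycle per voxel
    v <- array(0, c(4, 4, 9, 10, 3)); v[, , , , 3] <- 0.15
    f <- flowField(v, spacing = 1, frameDuration = 100)
    mask <- array(TRUE, c(4, 4, 9))
    pts <- cbind(1.5, 1.5, 0:8)
    cl <- new("Centerline",
              points = pts,
              tangents = matrix(rep(c(0, 0, 1), each = 9), ncol = 3),
              arcLength = as.numeric(0:8))
    asg <- assignVoxels(mask, cl, 1, c(0, 0, 0))
    fr <- forwardReverseFlow(f, asg, cl)
    expect_equal(unique(fr$ff[mask]), 0.15, tolerance = 1e-12)
    expect_equal(unique(fr$rf[mask]), 0)
    # sign flip swaps the maps exactly
    f2 <- f; f2@velocity <- -f@velocity
    fr2 <- forwardReverseFlow(f2, asg, cl)
    expect_identical(fr2$ff, fr$rf)
    expect_identical(fr2$rf, fr$ff)
    # zero-mean sinusoid: FF equals RF
    v3 <- v
    for (t in 1:10) v3[, , , t, 3] <- 0.2 * sin(2 * pi * (t - 0.5) / 10)
    fr3 <- forwardReverseFlow(flowField(v3, spacing = 1,
                                        frameDuration = 100), asg, cl)
    expect_equal(fr3$ff, fr3$rf, tolerance = 1e-12)
})

test_that("stasis counts slow frames exactly", {
    mask <- array(TRUE, c(2, 2, 2))
    mk <- function(speeds) {
        v <- array(0, c(2, 2, 2, length(speeds), 3))
        for (t in seq_along(speeds)) v[, , , t, 1] <- speeds[t]
        flowField(v, spacing = 1, frameDuration = 50)
    }
    expect_equal(unique(stasisMap(mk(rep(0.05, 8)), mask)[mask]), 100)
    expect_equal(unique(stasisMap(mk(rep(0.5, 8)), mask)[mask]), 0)
    sp <- c(rep(0.05, 5), rep(0.5, 15))
    expect_equal(unique(stasisMap(mk(sp), mask)[mask]), 25)
    # brute-force oracle on a random field
    f <- randomField(seed = 20)
    m <- array(TRUE, dim(f@magnitude)[1:3])
    got <- stasisMap(f, m)
    v <- velocityData(f)
    for (i in 1:2) for (j in 1:2) for (k in 1:2) {
        cnt <- 0
        for (t in seq_len(nFrames(f)))
            cnt <- cnt + (sqrt(sum(v[i, j, k, t, ]^2)) < 0.1)
        expect_identical(got[i, j, k], 100 * cnt / nFrames(f))
    }
})

test_that("kinetic energy follows the half-rho-dV-v-squared rule", {
    mask <- array(TRUE, c(2, 2, 2))
    v <- array(0, c(2, 2, 2, 1, 3)); v[, , , 1, 2] <- 1
    v <- v[, , , c(1, 1), , drop = FALSE] # two frames for a valid field
    v[, , , 2, ] <- 0
    f <- flowField(v, spacing = 1, frameDuration = 500)
    ke <- kineticEnergyMap(f, mask)
    expect_equal(unique(ke[mask]), 0.5 * 1060 * 1e-9 * 1 * 1e6)  # 0.53 uJ
    z <- flowField(array(0, c(2, 2, 2, 2, 3)))
    expect_equal(unique(kineticEnergyMap(z, mask)[mask]), 0)
    # doubling the velocity quadruples KE
    f4 <- f; f4@velocity <- 2 * f@velocity
    expect_equal(kineticEnergyMap(f4, mask), 4 * ke)
    # brute-force loop oracle in joules on a random field
    g <- randomField(seed = 21)
    m <- array(TRUE, dim(g@magnitude)[1:3])
    got <- kineticEnergyMap(g, m)
    v <- velocityData(g)
    for (i in 1:2) for (j in 1:2) {
        acc <- 0
        for (t in seq_len(nFrames(g)))
            acc <- acc + 0.5 * 1060 * 1e-9 * sum(v[i, j, 1, t, ]^2)
        expect_equal(got[i, j, 1], acc * 1e6, tolerance = 1e-12)
    }
})

test_that("systole detection brackets the ejection window", {
    p <- tube1mm()                      # half-sine systole, first 35% of cycle
    sys <- detectSystole(p$field, p$truth$mask)
    expect_true(all(sys <= ceiling(0.4 * nFrames(p$field))))
    ms <- vapply(seq_len(nFrames(p$field)), function(t)
        mean(VoxelFlow:::.frameSpeed(velocityData(p$field), t)[p$truth$mask]),
        numeric(1))
    expect_true(which.max(ms) %in% sys)
    expect_equal(diff(range(sys)) + 1L, length(sys))   # contiguous
    # constant-in-time field: every frame is systolic
    v <- array(0.4, c(3, 3, 3, 5, 3))
    m <- array(TRUE, c(3, 3, 3))
    expect_equal(detectSystole(flowField(v), m), 1:5)
    expect_warning(all0 <- detectSystole(flowField(array(0, c(3, 3, 3, 5, 3))), m),
                   "all-zero")
    expect_equal(all0, 1:5)
})

test_that("peak velocity is the systolic speed maximum per voxel", {
    f <- randomField(seed = 22)
    m <- array(TRUE, dim(f@magnitude)[1:3])
    one <- peakVelocityMap(f, m, 3L)
    expect_equal(one[1, 1, 1],
                 sqrt(sum(velocityData(f)[1, 1, 1, 3, ]^2)))
    some <- peakVelocityMap(f, m, c(2L, 3L))
    more <- peakVelocityMap(f, m, c(2L, 3L, 4L))
    expect_true(all(more[m] >= some[m]))           # max is monotone
    expect_error(peakVelocityMap(f, m, integer(0)), "non-empty")
})

test_that("maps on a native 1 mm phantom match the analytic truth", {
    p <- tube1mm()
    an <- straightAnalysis(p)
    maps <- computeVoxelMaps(p$field, p$truth$mask, an$asg, an$cl)
    m <- p$truth$mask
    expect_equal(maps@stasis[m], p$truth$stasis[m])             # exact
    expect_equal(maps@ke[m], p$truth$ke[m], tolerance = 0.02)
    # Poiseuille peak: 2 * max(Vbar) at the tube centre, within 3%
    expect_lt(abs(max(maps@peakVelocity[m], na.rm = TRUE) /
                  (2 * max(p$truth$waveform)) - 1), 0.03)
    validObject(maps)
})

test_that("reversing the field swaps FF and RF maps bitwise", {
    p <- tube1mm()
    an <- straightAnalysis(p)
    fr <- forwardReverseFlow(p$field, an$asg, an$cl)
    neg <- p$field; neg@velocity <- -neg@velocity
    fr2 <- forwardReverseFlow(neg, an$asg, an$cl)
    expect_identical(fr$ff, fr2$rf)
    expect_identical(fr$rf, fr2$ff)
})

test_that("band-summed FF approximates the analytic stroke volume", {
    p <- tube1mm()
    an <- straightAnalysis(p)
    maps <- computeVoxelMaps(p$field, p$truth$mask, an$asg, an$cl)
    mid <- round(nrow(clPoints(an$cl)) / 2)
    band <- an$asg@planeIndex == mid
    ffSum <- sum(maps@ff[an$asg@voxelIndex[band]])
    expect_lt(abs(ffSum / p$truth$strokeVolume - 1), 0.05)
})

test_that("projections collapse the masked maps as stated", {
    map <- array(NA_real_, c(3, 4, 5))
    map[2, , ] <- 7                                   # single-slice mask
    expect_equal(meanProjection(map, "x"), matrix(7, 4, 5))
    expect_equal(mipProjection(map, "x"), matrix(7, 4, 5))
    f <- randomField(seed = 23)
    m <- array(FALSE, dim(f@magnitude)[1:3]); m[2:4, 2:3, 1:2] <- TRUE
    ke <- kineticEnergyMap(f, m)
    mp <- meanProjection(ke, "z"); xp <- mipProjection(ke, "z")
    expect_true(all(is.na(mp) == is.na(xp)))
    expect_true(all(mp[!is.na(mp)] <= xp[!is.na(xp)] + 1e-12))
    expect_true(all(is.na(mp[1, ])))                  # background absent
})

test_that("regional summaries aggregate voxel values faithfully", {
    p <- tinyCane()
    iso <- interpolateIsotropic(p$field, p$truth$mask)
    cl <- extractCenterline(iso$mask, 1, gridOrigin(iso$field))
    asg <- assignVoxels(iso$mask, cl, 1, gridOrigin(iso$field))
    ori <- orientByFlow(cl, asg, iso$field)
    cl <- ori$centerline; asg <- ori$assignment
    lab <- splitRegions(cl, asg, c(.1, .45, .6, .8) * max(arcLength(cl)))
    maps <- computeVoxelMaps(iso$field, iso$mask, asg, cl)
    summ <- regionalSummary(maps, lab, asg)
    expect_equal(as.character(summ$region), aorticRegions)
    expect_equal(sum(summ$nVoxels), sum(iso$mask))
    for (r in aorticRegions) {
        vox <- asg@voxelIndex[regionLabels(lab) == r]
        expect_equal(summ$ff[summ$region == r], mean(maps@ff[vox]))
        expect_gte(summ$stasis[summ$region == r], min(maps@stasis[vox]))
        expect_lte(summ$stasis[summ$region == r], max(maps@stasis[vox]))
        expect_equal(summ$peakVelocity[summ$region == r],
                     max(maps@peakVelocity[vox]))
    }
    # hand-computed mean over a 10-voxel toy region
    vox10 <- asg@voxelIndex[which(regionLabels(lab) == "Arch")[1:10]]
    expect_equal(mean(maps@ke[vox10]), sum(maps@ke[vox10]) / 10)
})

test_that("Reynolds number follows rho v D over mu at the vena contracta", {
    # closed form: 1060 * 1.5 * 0.028 / 0.0035
    cst <- flowConstants()
    expect_equal(1060 * 1.5 * 0.028 / 0.0035, 12720)
    p <- tube1mm()
    an <- straightAnalysis(p)
    maps <- computeVoxelMaps(p$field, p$truth$mask, an$asg, an$cl)
    dia <- measureDiameters(p$truth$mask, an$cl, assignment = an$asg,
                            spacing = 1, origin = gridOrigin(p$field))
    re <- reynoldsNumber(maps, an$asg, dia)
    vmax <- max(maps@peakVelocity[p$truth$mask], na.rm = TRUE)
    D <- dia$stations$diameter[re$station]
    expect_equal(re$reynolds, 1060 * vmax * (D / 1000) / 0.0035)
    # doubling the viscosity halves it
    re2 <- reynoldsNumber(maps, an$asg, dia, flowConstants(mu = 7e-3))
    expect_equal(re2$reynolds, re$reynolds / 2)
    # zero flow gives zero
    z <- p$field; z@velocity[] <- 0
    mz <- computeVoxelMaps(z, p$truth$mask, an$asg, an$cl,
                           systoleFrames = 1:3)
    expect_equal(reynoldsNumber(mz, an$asg, dia)$reynolds, 0)
})
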
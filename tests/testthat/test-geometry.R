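test_that("straight-tube centreline is recovered on-axis with true length", {
    p <- tinyTube()
    cl <- extractCenterline(p$truth$mask, spacing = 2,
                            origin = gridOrigin(p$field))
    radial <- sqrt(rowSums(clPoints(cl)[, 1:2, drop = FALSE]^2))
    expect_lt(max(radial), 0.5 * 2)               # within half a voxel
    expect_lt(abs(max(arcLength(cl)) / 40 - 1), 0.02)
    expect_true(all(abs(sqrt(rowSums(clTangents(cl)^2)) - 1) < 1e-6))
    expect_true(all(diff(arcLength(cl)) > 0))
})

test_that("candy-cane centreline recovers the analytic arc length", {
    p <- tinyCane()
    cl <- extractCenterline(p$truth$mask, spacing = 2,
                            origin = gridOrigin(p$field))
    expect_lt(abs(max(arcLength(cl)) / p$truth$analyticLength - 1), 0.02)
    k <- VoxelFlow:::.nearestPoint(clPoints(cl), p$truth$centerline)
    dev <- sqrt(rowSums((clPoints(cl) - p$truth$centerline[k, ])^2))
    expect_lt(max(dev), 0.5 * 2)
})

test_that("degenerate and malformed masks raise errors, not crashes", {
    slab <- array(FALSE, c(24, 24, 6))
    slab[3:22, 3:22, 3:4] <- TRUE                 # two-voxel-thick plate
    expect_error(extractCenterline(slab, spacing = 1), "degenerate|loop")
    two <- array(FALSE, c(20, 8, 8))
    two[2:8, 3:6, 3:6] <- TRUE
    two[12:18, 3:6, 3:6] <- TRUE
    expect_error(extractCenterline(two, spacing = 1), "components")
    expect_error(extractCenterline(array(FALSE, c(4, 4, 4))), "empty")
    # a torus is a loop: rejected
    d <- c(28, 28, 8)
    ax <- VoxelFlow:::.axisCoords(d, rep(1, 3), c(0, 0, 0))
    tor <- array(FALSE, d)
    for (i in 1:28) for (j in 1:28) {
        r <- sqrt((ax[[1]][i] - 13)^2 + (ax[[2]][j] - 13)^2)
        if (abs(r - 9) <= 2.5) tor[i, j, 3:5] <- TRUE
    }
    expect_error(extractCenterline(tor, spacing = 1), "loop|degenerate")
})

test_that("voxel-plane matching equals exhaustive nearest-point search", {
    p <- tinyCane()
    cl <- extractCenterline(p$truth$mask, spacing = 2,
                            origin = gridOrigin(p$field))
    asg <- assignVoxels(p$truth$mask, cl, spacing = 2,
                        origin = gridOrigin(p$field))
    # brute force, plain double loop, on a random voxel subset
    W <- VoxelFlow:::.voxelWorld(asg@voxelIndex, dim(p$truth$mask),
                                 rep(2, 3), gridOrigin(p$field))
    pts <- clPoints(cl)
    set.seed(1)
    take <- sample(nrow(W), 400)
    for (i in take) {
        d2 <- rowSums((pts - matrix(W[i, ], nrow(pts), 3, byrow = TRUE))^2)
        expect_identical(asg@planeIndex[i], which.min(d2))
    }
    expect_false(anyDuplicated(asg@voxelIndex) > 0)
    expect_true(all(asg@planeIndex >= 1 & asg@planeIndex <= nrow(pts)))
})

test_that("a voxel on a centreline point matches it at distance zero", {
    pts <- cbind(0, 0, seq(0, 10, by = 1))
    tg <- matrix(rep(c(0, 0, 1), each = nrow(pts)), ncol = 3)
    cl <- new("Centerline", points = pts, tangents = tg,
              arcLength = seq(0, 10, by = 1))
    mask <- array(FALSE, c(3, 3, 12))
    mask[1, 1, 4] <- TRUE                          # world (0, 0, 3)
    asg <- assignVoxels(mask, cl, spacing = 1, origin = c(0, 0, 0))
    expect_equal(asg@planeIndex, 4L)
    expect_equal(asg@signedDistance, 0)
    # straight axis along z: every voxel matches the plane with nearest z
    mask2 <- array(TRUE, c(3, 3, 11))
    asg2 <- assignVoxels(mask2, cl, spacing = 1, origin = c(-1, -1, 0))
    W <- VoxelFlow:::.voxelWorld(asg2@voxelIndex, dim(mask2), rep(1, 3),
                                 c(-1, -1, 0))
    expect_equal(asg2@planeIndex, as.integer(round(W[, 3]) + 1))
    expect_error(assignVoxels(array(FALSE, c(2, 2, 2)), cl), "empty")
})

test_that("region splitting partitions the mask along arc-length bands", {
    pts <- cbind(0, 0, seq(0, 100, by = 1))
    tg <- matrix(rep(c(0, 0, 1), each = nrow(pts)), ncol = 3)
    cl <- new("Centerline", points = pts, tangents = tg,
              arcLength = seq(0, 100, by = 1))
    mask <- array(TRUE, c(2, 2, 101))
    asg <- assignVoxels(mask, cl, spacing = 1, origin = c(0, 0, 0))
    lab <- splitRegions(cl, asg, c(20, 40, 60, 80))
    tt <- table(regionLabels(lab))
    expect_equal(sum(tt), sum(mask))               # partition
    expect_equal(as.integer(tt),
                 c(20, 20, 20, 20, 21) * 4)        # five 20 mm bands
    # moving one boundary by +5 mm relabels exactly the 5 mm band
    lab2 <- splitRegions(cl, asg, c(25, 40, 60, 80))
    moved <- which(regionLabels(lab) != regionLabels(lab2))
    s <- arcLength(cl)[asg@planeIndex[moved]]
    expect_true(all(s >= 20 & s < 25))
    expect_equal(length(moved), 5 * 4)
    expect_error(splitRegions(cl, asg, c(20, 40, 60, 120)), "span")
    expect_error(splitRegions(cl, asg, c(40, 20, 60, 80)), "increasing")
})

test_that("effective diameters recover tube calibre, bulges and rotations", {
    p <- tinyTube()
    cl <- extractCenterline(p$truth$mask, spacing = 2,
                            origin = gridOrigin(p$field))
    dia <- measureDiameters(p$truth$mask, cl, spacing = 2,
                            origin = gridOrigin(p$field))
    mid <- dia$stations$diameter[5:(nrow(dia$stations) - 5)]
    expect_true(all(abs(mid - 10) <= 2))           # within one voxel
    # fusiform bulge: radius 8 over a 12 mm band on a radius-5 tube
    d <- c(21, 21, 40)
    ax <- VoxelFlow:::.axisCoords(d, rep(1, 3), c(-10, -10, 0))
    R <- function(z) ifelse(z >= 14 & z <= 26, 8, 5)
    bul <- array(FALSE, d)
    for (k in seq_len(d[3])) {
        rr <- sqrt(outer(ax[[1]]^2, ax[[2]]^2, "+"))
        bul[, , k] <- rr <= R(ax[[3]][k])
    }
    clb <- extractCenterline(bul, spacing = 1, origin = c(-10, -10, 0))
    lab <- splitRegions(clb, assignVoxels(bul, clb, 1, c(-10, -10, 0)),
                        c(8, 13, 27, 32))
    diab <- measureDiameters(bul, clb, lab,
                             spacing = 1, origin = c(-10, -10, 0))
    expect_equal(unname(diab$regions["Arch"]), 16, tolerance = 0.08)
    expect_lt(unname(diab$regions["LVOT"]), 12)
    # in-plane rotation: tube axis diagonal in the x-y plane
    dd <- c(30, 30, 9)
    axd <- VoxelFlow:::.axisCoords(dd, rep(1, 3), c(0, 0, 0))
    rot <- array(FALSE, dd)
    for (i in 1:30) for (j in 1:30) {
        u <- (axd[[1]][i] + axd[[2]][j]) / sqrt(2)    # along (1,1,0)
        w2 <- ((axd[[1]][i] - axd[[2]][j])^2) / 2
        if (u >= 2 && u <= 38) rot[i, j, ] <- sqrt(w2 + (axd[[3]] - 4)^2) <= 3.5
    }
    clr <- extractCenterline(rot, spacing = 1)
    diar <- measureDiameters(rot, clr, spacing = 1)
    midr <- diar$stations$diameter[6:(nrow(diar$stations) - 6)]
    expect_lt(abs(median(midr, na.rm = TRUE) / 7 - 1), 0.05)
})

test_that("BSA, indexing and dilation grading follow the stated rules", {
    expect_equal(bsa(180, 72), sqrt(12960 / 3600))
    expect_equal(bsa(180, 72), 1.897, tolerance = 1e-3)
    expect_gt(abs(bsa(180, 72) - bsa(180, 72, "dubois")), 0)  # distinct formulas
    expect_error(bsa(-1, 70), "positive")
    expect_equal(indexDiameter(40, 2), 20)
    # printed-scale check: 40 mm at BSA 2 lands on the reported 20 +- 4 band
    ref <- referenceRegionalStats("bav")
    aao <- ref[ref$region == "AAo" & ref$parameter == "indexedDiameter", ]
    expect_lt(abs(indexDiameter(40, 2) - aao$mean), aao$sd)
    expect_error(indexDiameter(40, 0), "positive")
    expect_equal(classifyDilation(30), "non-dilated")
    expect_equal(classifyDilation(40), "moderate")
    expect_equal(classifyDilation(50), "severe")
    expect_equal(classifyDilation(c(35, 45)), c("moderate", "severe"))
    # monotone non-decreasing in diameter
    cls <- classifyDilation(seq(20, 60, by = 0.5))
    ord <- c("non-dilated" = 1, moderate = 2, severe = 3)
    expect_true(all(diff(ord[cls]) >= 0))
})

test_that("centreline reversal flips tangents and preserves geometry", {
    p <- tinyTube()
    cl <- extractCenterline(p$truth$mask, spacing = 2,
                            origin = gridOrigin(p$field))
    rv <- reverseCenterline(cl)
    n <- nrow(clPoints(cl))
    expect_equal(clPoints(rv), clPoints(cl)[n:1, ])
    expect_equal(clTangents(rv), -clTangents(cl)[n:1, ])
    expect_equal(max(arcLength(rv)), max(arcLength(cl)))
    # orientation by net flow: whichever orientation goes in, the oriented
    # tangents point with the (+z) flow and agree with each other
    oriented <- lapply(list(cl, rv), function(c0) {
        a <- assignVoxels(p$truth$mask, c0, 2, gridOrigin(p$field))
        orientByFlow(c0, a, p$field)$centerline
    })
    expect_gt(mean(clTangents(oriented[[1]])[, 3]), 0.9)
    expect_equal(clTangents(oriented[[1]]), clTangents(oriented[[2]]))
    expect_equal(clPoints(oriented[[1]]), clPoints(oriented[[2]]))
})
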
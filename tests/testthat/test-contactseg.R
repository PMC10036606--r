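test_that("linear membrane background is removed exactly", {
    nt <- 8; ny <- 20; nx <- 20
    arr <- array(0, c(nt, ny, nx))
    for (t in seq_len(nt)) arr[t, , ] <- 50 + 3 * t
    v <- TirfVideo(arr)
    out <- videoData(correctMembraneBackground(v))
    # a + b*t everywhere -> constant at the first frame's fitted level
    expect_lt(max(out) - min(out), 1e-6)
    expect_equal(mean(out), 53, tolerance = 1e-6)

    # static bright blob on a ramp keeps its contrast
    blob <- discMask(ny, 10, 10, 4)
    arr2 <- arr
    for (t in seq_len(nt)) {
        fr <- arr2[t, , ]; fr[blob] <- fr[blob] + 200; arr2[t, , ] <- fr
    }
    out2 <- videoData(correctMembraneBackground(TirfVideo(arr2)))
    contrast <- vapply(seq_len(nt), function(t)
        mean(out2[t, , ][blob]) - mean(out2[t, , ][!blob]), numeric(1))
    expect_lt(max(abs(contrast - 200)) / 200, 0.02)

    # b = 0: output equals input (offset zero)
    arr3 <- array(70, c(nt, ny, nx))
    out3 <- videoData(correctMembraneBackground(TirfVideo(arr3)))
    expect_equal(out3, arr3, tolerance = 1e-9)

    expect_error(correctMembraneBackground(TirfVideo(array(0, c(2, 5, 5)))),
                 "3 frames")
})

test_that("membrane masks find cells and reject noise", {
    cfg <- segmentationConfig(min_cell_area = 5)
    set.seed(2)
    # pure noise with a conservative global threshold: empty after
    # min-area filtering
    noise <- TirfVideo(array(100 + rnorm(5 * 40 * 40, sd = 5),
                             c(5, 40, 40)))
    mN <- segmentMembrane(noise, segmentationConfig(min_cell_area = 5,
                                                    global_threshold = 1e6))
    expect_equal(sum(mN), 0)

    # simulated cell disc, radius 2 um: one component, area within 15%
    sc <- groundTruthScene(fieldSize = c(5.35, 5.35), nFrames = 5,
        cells = list(cellTruth(2.675, 2.675, 2, nFrames = 5)))
    v <- simulateVideo(sc, seed = 8)
    m <- segmentMembrane(v$membrane, cfg)
    fr <- m[3, , ]
    expect_equal(max(EBImage::bwlabel(fr)), 1)
    expect_equal(sum(fr) * 0.107^2, pi * 4, tolerance = 0.15)

    # two disjoint cells: two components
    sc2 <- groundTruthScene(fieldSize = c(8.56, 8.56), nFrames = 5,
        cells = list(cellTruth(2.5, 2.5, 1.5, nFrames = 5),
                     cellTruth(6, 6, 1.5, nFrames = 5)))
    v2 <- simulateVideo(sc2, seed = 9)
    m2 <- segmentMembrane(v2$membrane, cfg)
    expect_equal(max(EBImage::bwlabel(m2[3, , ])), 2)
})

test_that("spatiotemporal watershed labels cells consistently", {
    cfg <- segmentationConfig(min_cell_area = 3, cell_radius = 3.5)
    sc <- groundTruthScene(fieldSize = c(8.56, 8.56), nFrames = 6,
        cells = list(cellTruth(2.5, 2.5, 1.2, nFrames = 6),
                     cellTruth(6, 6, 1.2, nFrames = 6)))
    v <- simulateVideo(sc, seed = 12)
    m <- segmentMembrane(v$membrane, cfg)
    lv <- labelCells(m, v$membrane, cfg)

    # two labels, one per cell, stable across all frames
    lab <- labelData(lv)
    expect_equal(sort(setdiff(unique(as.vector(lab)), 0L)), c(1L, 2L))
    for (t in 1:6) {
        fr <- lab[t, , ]
        expect_equal(sort(setdiff(unique(as.vector(fr)), 0L)), c(1L, 2L))
        # labels never share a voxel by construction; check spatial split
        w1 <- which(fr == 1L, arr.ind = TRUE)
        w2 <- which(fr == 2L, arr.ind = TRUE)
        expect_lt(max(colMeans(w1)), min(colMeans(w2)))
    }

    # a one-frame gap within 2 cell radii keeps the same label
    m2 <- m
    m2[3, , ] <- FALSE
    lv2 <- labelCells(m2, v$membrane, cfg)
    lab2 <- labelData(lv2)
    expect_equal(sort(setdiff(unique(as.vector(lab2[2, , ])), 0L)),
                 sort(setdiff(unique(as.vector(lab2[4, , ])), 0L)))
    expect_equal(sort(setdiff(unique(as.vector(lab2[1, , ])), 0L)),
                 c(1L, 2L))

    # no seeds anywhere -> informative error
    expect_error(labelCells(array(FALSE, dim(m)), v$membrane, cfg),
                 "seed")
})

test_that("flat-field correction normalises vignetted fields", {
    ny <- 30; nx <- 30
    vig <- outer(exp(-((seq_len(ny) - 15)^2) / 600),
                 exp(-((seq_len(nx) - 15)^2) / 600))
    ffStack <- TirfVideo(aperm(array(rep(vig * 50, 4), c(ny, nx, 4)),
                               c(3, 1, 2)))
    # input equal to the flat-field pattern: uniform output
    v <- TirfVideo(aperm(array(rep(vig * 200, 3), c(ny, nx, 3)),
                         c(3, 1, 2)))
    out <- videoData(flatfieldCorrect(v, ffStack))
    expect_lt(sd(out) / mean(out), 1e-9)

    # uniform flat-field: identity
    u <- TirfVideo(array(123, c(2, ny, nx)))
    expect_equal(videoData(flatfieldCorrect(u, matrix(1, ny, nx))),
                 videoData(u))

    # vignetted noisy field: corrected CV far below uncorrected
    set.seed(5)
    noisy <- TirfVideo(aperm(array(rep(vig * 200, 3), c(ny, nx, 3)),
                             c(3, 1, 2)) + rnorm(3 * ny * nx, sd = 0.1))
    corr <- videoData(flatfieldCorrect(noisy, ffStack))
    cvU <- sd(videoData(noisy)) / mean(videoData(noisy))
    cvC <- sd(corr) / mean(corr)
    expect_lt(cvC / cvU, 0.01)

    expect_error(flatfieldCorrect(u, matrix(0, ny, nx)), "positive")
})

test_that("the resolution floor is one camera pixel", {
    expect_equal(round(minContactArea(107), 3), 0.011)
})

test_that("close-contact segmentation detects rendered discs and stays
          silent on noise", {
    # 400 nm disc, 60% exclusion: detected in >= 95% of frames with
    # centroid within 1 pixel of truth
    nDet <- 0L; nTot <- 0L
    for (s in 1:3) {
        v <- simulateVideo(discScene(0.4, 0.6), seed = 500 + s)
        lab <- labelData(segmentCloseContacts(v$glycocalyx,
                                              restrict = FALSE))
        for (t in 1:10) {
            nTot <- nTot + 1L
            w <- which(lab[t, , ] > 0L, arr.ind = TRUE)
            if (nrow(w) &&
                sqrt(sum((colMeans(w) - discCenterPx)^2)) <= 1)
                nDet <- nDet + 1L
        }
    }
    expect_gte(nDet / nTot, 0.95)

    # zero false positives on seeded contact-free videos
    for (s in 1:6) {
        v <- simulateVideo(groundTruthScene(fieldSize = c(3.21, 3.21),
                                            nFrames = 10),
                           seed = 700 + s)
        expect_equal(max(labelData(segmentCloseContacts(v$glycocalyx,
                                                        restrict = FALSE))),
                     0L)
    }

    # determinism: identical labels on repeated segmentation
    v <- simulateVideo(discScene(0.4, 0.6), seed = 77)
    l1 <- segmentCloseContacts(v$glycocalyx, restrict = FALSE)
    l2 <- segmentCloseContacts(v$glycocalyx, restrict = FALSE)
    expect_identical(labelData(l1), labelData(l2))
})

test_that("detection probability rises with exclusion depth and measured
          area is monotone in true area", {
    # sharpened sweep: per-depth detection frequency non-decreasing
    depths <- c(0.2, 0.5, 0.9)
    freq <- vapply(depths, function(d) {
        hits <- 0L
        for (s in 1:4) {
            v <- simulateVideo(discScene(0.25, d), seed = 900 + s * 7 +
                               round(d * 10))
            lab <- labelData(segmentCloseContacts(v$glycocalyx,
                                                  restrict = FALSE))
            nf <- sum(vapply(1:10, function(t) {
                w <- which(lab[t, , ] > 0L, arr.ind = TRUE)
                nrow(w) > 0 &&
                    min(sqrt((w[, 1] - discCenterPx)^2 +
                             (w[, 2] - discCenterPx)^2)) <= 3
            }, logical(1)))
            hits <- hits + (nf > 5L)
        }
        hits
    }, numeric(1))
    expect_true(all(diff(freq) >= 0))
    expect_equal(freq[3], 4)

    # noise-free rendered discs: measured area monotone in true area
    areas <- vapply(c(0.3, 0.5, 0.8), function(d) {
        v <- simulateVideo(discScene(d, 1.0, nFrames = 6), seed = 1,
                           noise = FALSE)
        lab <- labelData(segmentCloseContacts(v$glycocalyx,
                                              restrict = FALSE))
        sum(lab[3, , ] > 0L)
    }, numeric(1))
    expect_true(all(diff(areas) > 0))
})

test_that("contacts are clipped to their owning cell when restricted", {
    sc <- groundTruthScene(fieldSize = c(5.35, 5.35), nFrames = 8,
        contacts = contactTruth(2.675, 2.675, 0.4, 0.8),
        cells = list(cellTruth(2.675, 2.675, 1.5, nFrames = 8)))
    v <- simulateVideo(sc, seed = 31)
    cfg <- segmentationConfig(min_cell_area = 5)
    m <- segmentMembrane(correctMembraneBackground(v$membrane), cfg)
    cl <- labelCells(m, v$membrane, cfg)
    cc <- segmentCloseContacts(v$glycocalyx, cl, cfg, restrict = TRUE)
    lab <- labelData(cc)
    expect_gt(max(lab), 0L)
    owners <- contactOwners(cc)
    # every contact voxel lies inside its owning cell's mask
    clab <- labelData(cl)
    for (id in as.integer(names(owners))) {
        sel <- lab == id
        expect_true(all(clab[sel] == owners[as.character(id)]))
    }

    # restriction without cell labels warns and returns empty
    expect_warning(
        empty <- segmentCloseContacts(v$glycocalyx, NULL, cfg,
                                      restrict = TRUE),
        "no cell labels")
    expect_equal(max(labelData(empty)), 0L)
})
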
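# hand-built cell label volume: disc of radius r at (cy, cx), present in
# the given frames
mkCellLabels <- function(nt, n, cy, cx, r, frames = seq_len(nt),
                         id = 1L, base = NULL) {
    lab <- if (is.null(base)) array(0L, c(nt, n, n)) else base
    for (t in frames) {
        fr <- lab[t, , ]
        fr[discMask(n, cy, cx, r)] <- id
        lab[t, , ] <- fr
    }
    LabelVolume(lab, "cell", 107, 1)
}

test_that("per-cell calcium traces are measured and interpolated", {
    nt <- 12; n <- 40
    # uniform calcium channel at 7: every trace constantly 7
    v7 <- TirfVideo(array(7, c(nt, n, n)))
    cl <- mkCellLabels(nt, n, 20, 20, 6)
    tr <- measureCellCalcium(v7, cl, circleRadius_um = 1,
                             minDuration = 5)
    expect_equal(unique(tr[["1"]]$intensity), 7)

    # centroid missing at frame 5: midpoint of frames 4 and 6
    clMove <- mkCellLabels(nt, n, 10, 10, 4, frames = 1:4)
    for (t in 6:12) {
        fr <- labelData(clMove)[t, , ]
        fr[discMask(n, 10 + 2 * (t - 4), 10, 4)] <- 1L
        clMove@labels[t, , ] <- fr
    }
    tr2 <- measureCellCalcium(v7, clMove, circleRadius_um = 1,
                              minDuration = 5)
    cen <- tr2[["1"]]$centroid
    expect_true(tr2[["1"]]$interpolated[5])
    expect_equal(cen[5, 1], (cen[4, 1] + cen[6, 1]) / 2)

    # a painted calcium step is recovered by trigger analysis
    sc <- groundTruthScene(fieldSize = c(4.28, 4.28), nFrames = 30,
        frameInterval = 5,
        cells = list(cellTruth(2.14, 2.14, 1.2,
            calcium = c(rep(20, 15), rep(100, 15)), nFrames = 30)))
    v <- simulateVideo(sc, seed = 14)
    cfg <- segmentationConfig(min_cell_area = 3)
    m <- segmentMembrane(v$membrane, cfg)
    cl2 <- labelCells(m, v$membrane, cfg)
    tr3 <- measureCellCalcium(v$calcium, cl2, circleRadius_um = 1,
                              earlyExclusion = 0, minDuration = 10)
    expect_true(tr3[["1"]]$trigger$triggered)
    # true step at frame 16 -> t = 75 s; allow +- 1 frame
    expect_lte(abs(tr3[["1"]]$trigger$triggerTime +
                   tr3[["1"]]$time_s[1] - 75), 5)
})

test_that("edge-touching cells are excluded by the QC rule", {
    nt <- 10; n <- 30
    interior <- mkCellLabels(nt, n, 15, 15, 5)
    edge <- mkCellLabels(nt, n, 15, 3, 4)

    # interior cell is kept
    qc <- qcEdgeExclusion(interior, triggerTimes = c("1" = 5),
                          firstContactTimes = c("1" = 1))
    expect_true(qc$kept)

    # edge touch (frame 1, t = 0) before the trigger at 5 s: excluded
    qc2 <- qcEdgeExclusion(edge, triggerTimes = c("1" = 5),
                           firstContactTimes = c("1" = 1))
    expect_false(qc2$kept)

    # non-triggering cell touching only after window_s past first
    # contact: kept
    lateEdge <- mkCellLabels(nt, n, 15, 15, 5, frames = 1:9)
    fr <- labelData(lateEdge)[10, , ]
    fr[discMask(n, 15, 3, 4)] <- 1L
    lateEdge@labels[10, , ] <- fr
    qc3 <- qcEdgeExclusion(lateEdge, triggerTimes = c("1" = NA),
                           firstContactTimes = c("1" = 0), window_s = 5)
    expect_true(qc3$kept)
    # ... but excluded when the window covers the touch
    qc4 <- qcEdgeExclusion(lateEdge, triggerTimes = c("1" = NA),
                           firstContactTimes = c("1" = 0), window_s = 20)
    expect_false(qc4$kept)
})

test_that("event detection reports the five stage anchors", {
    nt <- 20; n <- 40
    # growing footprint: area strictly increasing to the final frame
    cl <- mkCellLabels(nt, n, 20, 20, 3, frames = 1)
    for (t in 2:nt) {
        fr <- labelData(cl)[t, , ]
        fr[discMask(n, 20, 20, 3 + 0.5 * t)] <- 1L
        cl@labels[t, , ] <- fr
    }
    # contact appears at frame 6 (t = 5 s)
    clab <- array(0L, c(nt, n, n))
    for (t in 6:nt) clab[t, 20:21, 20:21] <- 1L
    cc <- LabelVolume(clab, "close_contact", 107, 1,
                      owners = c("1" = 1L))
    ev <- detectEvents(cl, cc)
    expect_equal(ev$time_CZ_first_s, 0)
    expect_equal(ev$time_CCZ_first_s, 5)
    expect_equal(ev$time_to_CZ_max_s, (nt - 1) * 1)
    expect_true(is.na(ev$time_Ca_s))
    # static centroid: adhered from the start
    expect_equal(ev$time_adhesion_s, 0)
})

test_that("stage assignment is half-open, ordered and trigger-gated", {
    ev <- data.frame(cellId = 1, time_CZ_first_s = 0,
                     time_adhesion_s = 5, time_CCZ_first_s = 20,
                     time_Ca_s = 60, time_to_CZ_max_s = 120)
    st <- assignStages(ev, nFrames = 16, frameInterval = 10)
    # frames at 10/40/90/150 s -> I/II/III/IV
    expect_equal(st[1, c(2, 5, 10, 16)], c("I", "II", "III", "IV"))
    # trigger exactly at a frame boundary: that frame is stage III
    expect_equal(unname(st[1, 7]), "III")
    # monotone, gapless
    codes <- match(st[1, ], c("I", "II", "III", "IV"))
    expect_true(all(diff(codes) >= 0))

    # no trigger: only I and II
    ev2 <- ev; ev2$time_Ca_s <- NA
    st2 <- assignStages(ev2, 16, 10)
    expect_setequal(unique(st2[1, ]), c("I", "II"))

    # inconsistent ordering clipped with warning
    ev3 <- ev; ev3$time_Ca_s <- 10
    expect_warning(st3 <- assignStages(ev3, 16, 10), "clipped")
    codes3 <- match(st3[1, ], c("I", "II", "III", "IV"))
    expect_true(all(diff(codes3) >= 0))
})

test_that("exclusion_10 follows its definition on constructed images", {
    n <- 40
    lab <- array(0L, c(1, n, n))
    inside <- discMask(n, 20, 20, 3)
    lab[1, , ][inside] <- 1L
    cc <- LabelVolume(lab, "close_contact", 107, 1, owners = c("1" = 1L))
    cellLab <- mkCellLabels(1, n, 20, 20, 15)

    # inside all 60, cell outline 100 -> exclusion 0.40
    img <- matrix(100, n, n); img[inside] <- 60
    v <- TirfVideo(img)
    rec <- contactFeatures(cc, v, cellLab)
    expect_equal(rec$exclusion_10, 0.40)
    expect_equal(rec$area_um2, sum(inside) * 0.107^2)

    # inside distribution equal to outside: exclusion ~ 0
    set.seed(4)
    img2 <- matrix(100, n, n)
    v2 <- TirfVideo(img2)
    expect_equal(contactFeatures(cc, v2, cellLab)$exclusion_10, 0)

    # graded inside values: 10th percentile by the sort-based oracle
    vals <- seq(50, 140, by = 10)
    idx <- which(inside)
    img3 <- matrix(100, n, n)
    img3[idx[seq_along(vals)]] <- vals
    if (length(idx) > length(vals)) img3[idx[-seq_along(vals)]] <- 150
    v3 <- TirfVideo(img3)
    got <- contactFeatures(cc, v3, cellLab)$exclusion_10
    expected <- 1 - percentileOracle(img3[inside], 0.1) / 100
    expect_equal(got, expected)

    # missing outline -> flagged invalid
    recNo <- contactFeatures(cc, v, cellLabels = NULL)
    expect_false(recNo$valid)
})

test_that("measured exclusion_10 on noise-free renders matches the
          dense-convolution oracle within 0.05", {
    depth <- 0.6
    v <- simulateVideo(discScene(0.4, depth, nFrames = 6), seed = 1,
                       noise = FALSE)
    cc <- segmentCloseContacts(v$glycocalyx, restrict = FALSE)
    lab <- labelData(cc)
    expect_gt(max(lab), 0L)
    # a synthetic owning cell large enough that its outline sits on
    # undisturbed background
    cellLab <- mkCellLabels(6, 30, round(discCenterPx),
                            round(discCenterPx), 12)
    cc@owners <- c("1" = 1L)
    rec <- contactFeatures(cc, v$glycocalyx, cellLab)

    orc <- oracleDiscImage(100, depth, 0.4, 131)
    for (k in seq_len(nrow(rec))) {
        inside <- lab[rec$frame[k], , ] == rec$contactId[k]
        outline <- closecontacts:::.maskOutline(
            labelData(cellLab)[rec$frame[k], , ] == 1L)
        oExcl <- 1 - percentileOracle(orc[inside], 0.1) /
            mean(orc[outline])
        expect_lt(abs(rec$exclusion_10[k] - oExcl), 0.05)
    }
})

test_that("contact records conserve label counts and accumulate contact
          time by one frame interval", {
    sc <- groundTruthScene(fieldSize = c(4.28, 4.28), nFrames = 8,
        contacts = contactTruth(c(1.4, 2.9), c(1.4, 2.9), 0.4, 0.9,
                                birth_s = c(0, 3)))
    v <- simulateVideo(sc, seed = 6)
    cc <- segmentCloseContacts(v$glycocalyx, restrict = FALSE)
    lab <- labelData(cc)
    cellLab <- mkCellLabels(8, 40, 20, 20, 19)
    rec <- contactFeatures(cc, v$glycocalyx, cellLab)

    # per frame, one record per distinct label in the volume
    for (t in seq_len(8)) {
        expect_equal(sum(rec$frame == t),
                     length(setdiff(unique(as.vector(lab[t, , ])), 0L)))
    }
    # contact_time increments by exactly one frame interval
    for (id in unique(rec$contactId)) {
        ct <- rec$contact_time_s[rec$contactId == id]
        expect_equal(diff(ct), rep(1, length(ct) - 1L))
    }
})

test_that("contact area fraction divides by the membrane surface area", {
    rec <- data.frame(contactId = c(1, 2), cellId = 1, frame = 1,
                      time_s = 0, area_um2 = c(0.6, 0.4))
    expect_equal(contactAreaFraction(rec, 0, 500), 0.002)
    expect_equal(contactAreaFraction(rec[0, ], 0, 500), 0)
    expect_true(is.na(contactAreaFraction(rec, NA, 500)))
    expect_error(contactAreaFraction(rec, 0, -1))
})

test_that("feature tables are written with conventional column names", {
    dir <- withr::local_tempdir()
    ev <- data.frame(cellId = 1, time_CZ_first_s = 0,
                     time_adhesion_s = 5, time_CCZ_first_s = 20,
                     time_Ca_s = 60, time_to_CZ_max_s = 120)
    rec <- data.frame(contactId = 1, cellId = 1, frame = 1, time_s = 0,
                      area_um2 = 0.1, exclusion_10 = 0.4,
                      contact_time_s = 1, stage = "II", valid = TRUE)
    writeFeatureTables(ev, rec, dir)
    evBack <- read.csv(file.path(dir, "events.csv"), check.names = FALSE)
    expect_true("time_CZ_first (s)" %in% names(evBack))
    recBack <- read.csv(file.path(dir, "contacts.csv"),
                        check.names = FALSE)
    expect_true(all(c("Area (um^2)", "exclusion_10", "contact_time (s)",
                      "stage") %in% names(recBack)))
})
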
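# Shared fixtures and independent oracles.

# standard single-contact scene: disc centred in a 3.21 um field
# (30 camera pixels at 107 nm)
discScene <- function(diameter_um, depth, nFrames = 10, birth_s = 0,
                      death_s = Inf, frameInterval = 1) {
    groundTruthScene(
        fieldSize = c(3.21, 3.21),
        contacts = contactTruth(1.605, 1.605, diameter_um, depth,
                                birth_s, death_s),
        nFrames = nFrames, frameInterval = frameInterval)
}

# truth centre of discScene in pixel coordinates (1-based, pixel centres
# at half-integers)
discCenterPx <- 1.605 / 0.107 + 0.5

# Independent dense-convolution oracle for a blurred exclusion disc.
# The convolution of an isotropic Gaussian with a disc of radius R has the
# radial form  B(r) = integral_0^R (rho/sigma^2) exp(-(r^2+rho^2)/(2 s^2))
# * I0(r rho / s^2) drho  (Rice CDF integrand), evaluated by quadrature --
# a completely different route from the package's separable matrix blur.
# Returns the blurred *fractional coverage* of the disc at radius r (um).
ovl_discBlur <- function(r_um, R_um, sigma_um, nq = 4000) {
    vapply(r_um, function(r) {
        rho <- seq(0, R_um, length.out = nq)
        s2 <- sigma_um^2
        # exp-scaled Bessel for numerical stability
        f <- (rho / s2) * exp(-(r - rho)^2 / (2 * s2)) *
            besselI(r * rho / s2, 0, expon.scaled = TRUE)
        sum((f[-1] + f[-nq]) / 2 * diff(rho))
    }, numeric(1))
}

# oracle camera-pixel image of a blurred exclusion disc: average the
# radial profile over a sub-grid of each camera pixel
oracleDiscImage <- function(background, depth, diameter_um, sigma_nm,
                            n_px = 30, px_nm = 107, sub = 5) {
    R <- diameter_um / 2
    sigma_um <- sigma_nm / 1000
    px_um <- px_nm / 1000
    cen <- 1.605
    img <- matrix(0, n_px, n_px)
    offs <- ((seq_len(sub) - 0.5) / sub) * px_um
    for (i in seq_len(n_px)) for (j in seq_len(n_px)) {
        ys <- (i - 1) * px_um + offs
        xs <- (j - 1) * px_um + offs
        rr <- sqrt(outer((ys - cen)^2, (xs - cen)^2, `+`))
        cov <- ovl_discBlur(as.vector(rr), R, sigma_um, nq = 600)
        img[i, j] <- background * (1 - depth * mean(cov))
    }
    img
}

# sort-based percentile oracle (type-7: linear interpolation between
# order statistics)
percentileOracle <- function(x, p) {
    x <- sort(x)
    n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
}

# hand-rolled product-limit estimator
kmOracle <- function(durations, observed) {
    tt <- sort(unique(durations[observed]))
    s <- 1
    surv <- numeric(length(tt))
    for (k in seq_along(tt)) {
        atRisk <- sum(durations >= tt[k])
        d <- sum(durations == tt[k] & observed)
        s <- s * (1 - d / atRisk)
        surv[k] <- s
    }
    list(time = tt, surv = surv)
}

# independent log-rank statistic (observed - expected under the
# hypergeometric null at each event time), and its permutation p-value
logrankOracle <- function(tA, tB, nPerm = 2000, seed = 1) {
    stat <- function(tA, tB) {
        times <- sort(unique(c(tA, tB)))
        O <- 0; E <- 0; V <- 0
        for (tt in times) {
            n1 <- sum(tA >= tt); n2 <- sum(tB >= tt)
            d1 <- sum(tA == tt); d2 <- sum(tB == tt)
            n <- n1 + n2; d <- d1 + d2
            if (n < 1 || d == 0) next
            O <- O + d1
            E <- E + d * n1 / n
            if (n > 1)
                V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
        }
        if (V == 0) return(0)
        (O - E)^2 / V
    }
    obs <- stat(tA, tB)
    all <- c(tA, tB)
    nA <- length(tA)
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(nPerm)) {
        idx <- sample(length(all), nA)
        if (stat(all[idx], all[-idx]) >= obs - 1e-12) hits <- hits + 1L
    }
    list(chisq = obs, p = (hits + 1) / (nPerm + 1))
}

# circular disc mask on an n x n grid (pixel units)
discMask <- function(n, cy, cx, r_px) {
    outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`) <= r_px^2
}
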
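# Internal separable Gaussian blur with reflective (whole-sample symmetric)
# boundary handling. The blur operator along one axis is materialised as a
# dense doubly-stochastic matrix so that constants are preserved exactly and
# total intensity is conserved; fields here are at most a few thousand
# pixels per side so the matrix product is cheap and exactly reproducible.

.gaussKernel <- function(sigma_px, radius = ceiling(4 * sigma_px)) {
    k <- exp(-(seq(-radius, radius))^2 / (2 * sigma_px^2))
    k / sum(k)
}

# n x n blur matrix: out[i] = sum_j S[i, j] in[j], kernel taps falling
# outside [1, n] folded back by reflection (j < 1 -> 1 - j; j > n -> 2n + 1 - j).
.gaussBlurMat <- function(n, sigma_px) {
    k <- .gaussKernel(sigma_px)
    r <- (length(k) - 1L) / 2L
    S <- matrix(0, n, n)
    for (off in -r:r) {
        j <- seq_len(n) + off
        j <- ifelse(j < 1L, 1L - j, j)
        j <- ifelse(j > n, 2L * n + 1L - j, j)
        # second fold for kernels wider than the field
        j <- ifelse(j < 1L, 1L - j, j)
        j <- pmin(pmax(j, 1L), n)
        S[cbind(seq_len(n), j)] <- S[cbind(seq_len(n), j)] + k[off + r + 1L]
    }
    S
}

# Gaussian blur of a (y, x) matrix, sigma in pixels of that matrix.
.blurField <- function(field, sigma_px) {
    if (sigma_px <= 0) stop("blur sigma must be > 0")
    Sy <- .gaussBlurMat(nrow(field), sigma_px)
    Sx <- if (ncol(field) == nrow(field)) Sy else
        .gaussBlurMat(ncol(field), sigma_px)
    Sy %*% field %*% t(Sx)
}

# Mean-bin a matrix by an integer factor along both axes. Partial edge
# pixels (when the field is not an exact multiple of the factor) are
# discarded.
.binField <- function(field, factor) {
    ny <- nrow(field) %/% factor
    nx <- ncol(field) %/% factor
    if (ny < 1L || nx < 1L)
        stop("field is smaller than one camera pixel")
    field <- field[seq_len(ny * factor), seq_len(nx * factor), drop = FALSE]
    dim(field) <- c(factor, ny, factor, nx)
    out <- apply(field, c(2L, 4L), mean)
    matrix(out, ny, nx)
}

# Temporal running mean over a (time, y, x) array, window w frames,
# shrinking symmetrically at the ends.
.runningMeanT <- function(arr, w) {
    nt <- dim(arr)[1L]
    if (w <= 1L || nt == 1L) return(arr)
    half <- (w - 1L) %/% 2L
    out <- arr
    for (t in seq_len(nt)) {
        idx <- max(1L, t - half):min(nt, t + half)
        out[t, , ] <- if (length(idx) == 1L) arr[idx, , ] else
            colMeans(arr[idx, , , drop = FALSE], dims = 1L)
    }
    out
}

# 2-d Gaussian smoothing of each frame of a (time, y, x) array (reflective).
.gaussXY <- function(arr, sigma_px) {
    nt <- dim(arr)[1L]
    Sy <- .gaussBlurMat(dim(arr)[2L], sigma_px)
    Sx <- if (dim(arr)[3L] == dim(arr)[2L]) Sy else
        .gaussBlurMat(dim(arr)[3L], sigma_px)
    tSx <- t(Sx)
    for (t in seq_len(nt))
        arr[t, , ] <- Sy %*% arr[t, , ] %*% tSx
    arr
}

# Discrete 5-point Laplacian with replicated edges.
.laplacian <- function(m) {
    ny <- nrow(m); nx <- ncol(m)
    up    <- m[c(1L, seq_len(ny - 1L)), ]
    down  <- m[c(seq_len(ny - 1L) + 1L, ny), ]
    left  <- m[, c(1L, seq_len(nx - 1L))]
    right <- m[, c(seq_len(nx - 1L) + 1L, nx)]
    up + down + left + right - 4 * m
}

# Run-preserving local RNG: evaluate expr under a temporary seed without
# clobbering the caller's RNG stream.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}
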
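# Independent oracles and drawing helpers shared across the test files.
# These deliberately use direct-definition algorithms (explicit loops,
# shift-and-accumulate morphology, exhaustive scans) so they exercise none
# of the package's own code paths.

drawDisk <- function(nr, nc, cr, cc, radius, value = 1L, base = NULL) {
    m <- if (is.null(base)) matrix(0L, nr, nc) else base
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    m[(rows - cr)^2 + (cols - cc)^2 <= radius^2] <- value
    m
}

drawEllipse <- function(nr, nc, cr, cc, a, b, value = 1L, base = NULL) {
    m <- if (is.null(base)) matrix(0L, nr, nc) else base
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    m[((rows - cr) / a)^2 + ((cols - cc) / b)^2 <= 1] <- value
    m
}

addGauss <- function(m, cr, cc, fwhm, amp) {
    sg <- fwhm / (2 * sqrt(2 * log(2)))
    rows <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
    cols <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
    m + amp * exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * sg^2))
}

# Direct shift-and-accumulate flat morphology over the explicit disk offsets.
shiftMat <- function(m, dr, dc, pad) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(pad, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs - dr, cs - dc] <- m[rs, cs]
    out
}

bruteDiskMorph <- function(m, r, dilate = FALSE) {
    acc <- matrix(if (dilate) -Inf else Inf, nrow(m), ncol(m))
    f <- if (dilate) pmax else pmin
    for (dr in -floor(r):floor(r))
        for (dc in -floor(r):floor(r))
            if (dr^2 + dc^2 <= r^2)
                acc <- f(acc, shiftMat(m, dr, dc, if (dilate) -Inf else Inf))
    acc
}

bruteTopHat <- function(m, diameter) {
    r <- floor(diameter / 2)
    pmax(m - bruteDiskMorph(bruteDiskMorph(m, r, FALSE), r, TRUE), 0)
}

# Exhaustive 256-candidate Otsu scan written as plain loops.
bruteOtsu <- function(values) {
    lo <- min(values); hi <- max(values)
    nb <- 256L
    bins <- pmin(pmax(floor((values - lo) / (hi - lo) * nb) + 1L, 1L), nb)
    h <- numeric(nb)
    for (b in bins) h[b] <- h[b] + 1
    p <- h / sum(h)
    centers <- lo + ((seq_len(nb) - 0.5) / nb) * (hi - lo)
    best <- -Inf; bestT <- NA_real_
    for (t in 1:(nb - 1L)) {
        w1 <- sum(p[1:t]); w2 <- 1 - w1
        if (w1 == 0 || w2 == 0) next
        m1 <- sum(p[1:t] * centers[1:t]) / w1
        m2 <- sum(p[(t + 1):nb] * centers[(t + 1):nb]) / w2
        v <- w1 * w2 * (m1 - m2)^2
        if (v > best) { best <- v; bestT <- lo + (t / nb) * (hi - lo) }
    }
    bestT
}

# Exhaustive window scan of the normalized rank-slope curve.
bruteCrossing <- function(sizes, window = 10, threshold = 1) {
    s <- sort(sizes)
    n <- length(s)
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (s - s[1]) / (s[n] - s[1])
    tt <- diff(y) / diff(x)
    for (i in seq_len(length(tt) - window + 1L))
        if (mean(tt[i:(i + window - 1L)]) >= threshold - 1e-9)
            return(list(index = i, cutoff = s[i]))
    list(index = NA_integer_, cutoff = NA_real_)
}

# Exact upper-tail overlap probability by enumerating every subset of the
# universe as set A against a fixed set B (the overlap law depends on the
# draws only through their sizes).
bruteHyperTail <- function(observed, nA, nB, N) {
    A <- utils::combn(N, nA)
    hits <- 0
    for (j in seq_len(ncol(A)))
        if (sum(A[, j] <= nB) >= observed) hits <- hits + 1
    hits / ncol(A)
}

# Greedy one-to-one centroid matching between truth and detections.
matchCentroids <- function(truth, detected, maxDist = 5) {
    if (nrow(truth) == 0L || nrow(detected) == 0L) return(0L)
    d <- outer(seq_len(nrow(truth)), seq_len(nrow(detected)),
               function(i, j) sqrt((truth$centroid_row[i] -
                                        detected$centroid_row[j])^2 +
                                   (truth$centroid_col[i] -
                                        detected$centroid_col[j])^2))
    matches <- 0L
    while (TRUE) {
        k <- which.min(d)
        if (!length(k) || d[k] > maxDist) break
        i <- (k - 1) %% nrow(d) + 1
        j <- (k - 1) %/% nrow(d) + 1
        matches <- matches + 1L
        d[i, ] <- Inf; d[, j] <- Inf
        if (all(!is.finite(d))) break
    }
    matches
}
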
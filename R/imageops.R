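# Low-level raster operations used by the illumination and detection stages.
# Flat grayscale morphology is computed separably per disk row with a
# sparse-table running min/max, so an opening with a 40-px disk costs a few
# hundred vectorized passes rather than one pass per structuring-element
# pixel.

colShiftPad <- function(m, s, pad) {
    nc <- ncol(m); nr <- nrow(m)
    if (s == 0) return(m)
    if (abs(s) >= nc) return(matrix(pad, nr, nc))
    if (s > 0) cbind(m[, (1 + s):nc, drop = FALSE], matrix(pad, nr, s))
    else cbind(matrix(pad, nr, -s), m[, 1:(nc + s), drop = FALSE])
}

rowShiftPad <- function(m, s, pad) {
    nr <- nrow(m); nc <- ncol(m)
    if (s == 0) return(m)
    if (abs(s) >= nr) return(matrix(pad, nr, nc))
    if (s > 0) rbind(m[(1 + s):nr, , drop = FALSE], matrix(pad, s, nc))
    else rbind(matrix(pad, -s, nc), m[1:(nr + s), , drop = FALSE])
}

# Left-anchored running extreme over column windows of width w, computed from
# a doubling table: tab[[k]] holds the extreme over [j, j + 2^(k-1) - 1].
runExtremeTable <- function(m, maxW, fun, pad) {
    K <- max(1L, ceiling(log2(max(maxW, 1))) + 1L)
    tab <- vector("list", K)
    tab[[1]] <- m
    if (K > 1) for (k in 2:K) {
        half <- 2^(k - 2)
        tab[[k]] <- fun(tab[[k - 1]], colShiftPad(tab[[k - 1]], half, pad))
    }
    tab
}

runExtremeWidth <- function(tab, w, fun, pad) {
    if (w <= 1) return(tab[[1]])
    k <- floor(log2(w))
    base <- tab[[k + 1]]                       # width 2^k
    if (w == 2^k) return(base)
    fun(base, colShiftPad(base, w - 2^k, pad))
}

diskRowHalfWidths <- function(r) {
    ri <- as.integer(floor(r))
    vapply(-ri:ri, function(dy) as.integer(floor(sqrt(r^2 - dy^2))), 1L)
}

flatDiskExtreme <- function(m, r, dilate = FALSE) {
    if (r <= 0) return(m)
    fun <- if (dilate) pmax else pmin
    pad <- if (dilate) -Inf else Inf
    ri <- as.integer(floor(r))
    # pad by the disk radius so centered windows never leave the domain;
    # the pad value is neutral for the corresponding extreme
    nr <- nrow(m); nc <- ncol(m)
    mp <- matrix(pad, nr + 2L * ri, nc + 2L * ri)
    mp[ri + seq_len(nr), ri + seq_len(nc)] <- m
    Ls <- diskRowHalfWidths(r)
    tab <- runExtremeTable(mp, 2L * max(Ls) + 1L, fun, pad)
    centered <- lapply(sort(unique(Ls)), function(L) {
        colShiftPad(runExtremeWidth(tab, 2L * L + 1L, fun, pad), -L, pad)
    })
    names(centered) <- as.character(sort(unique(Ls)))
    out <- NULL
    for (i in seq_along(Ls)) {
        dy <- i - ri - 1L
        shifted <- rowShiftPad(centered[[as.character(Ls[i])]], dy, pad)
        out <- if (is.null(out)) shifted else fun(out, shifted)
    }
    out[ri + seq_len(nr), ri + seq_len(nc), drop = FALSE]
}

#' Flat grayscale morphology with a disk structuring element
#'
#' \code{diskErode} and \code{diskDilate} compute the running minimum and
#' maximum of a numeric matrix over a digital disk of the given radius
#' (pixels whose offsets satisfy dx^2 + dy^2 <= r^2); \code{diskOpen} is the
#' erosion followed by dilation. Outside the image the erosion pads with
#' +Inf and the dilation with -Inf, so the opening never exceeds the input.
#'
#' @param m a numeric matrix.
#' @param r disk radius in pixels; \code{r <= 0} returns \code{m} unchanged.
#' @return a numeric matrix of the same dimensions.
#' @examples
#' m <- matrix(0, 9, 9); m[5, 5] <- 1
#' max(diskOpen(m, 2))   # isolated peak removed by the opening
#' @export
diskErode <- function(m, r) flatDiskExtreme(m, r, dilate = FALSE)

#' @rdname diskErode
#' @export
diskDilate <- function(m, r) flatDiskExtreme(m, r, dilate = TRUE)

#' @rdname diskErode
#' @export
diskOpen <- function(m, r) diskDilate(diskErode(m, r), r)

#' Gaussian smoothing of a matrix
#'
#' Separable Gaussian convolution with kernel radius \code{ceiling(3 sigma)}
#' and border renormalization (the kernel is renormalized over the part that
#' falls inside the image, so flat inputs stay flat up to the border).
#'
#' @param m numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; 0 returns \code{m}.
#' @return smoothed matrix of the same dimensions.
#' @export
gaussianSmooth <- function(m, sigma) {
    if (sigma < 0) stop("'sigma' must be >= 0")
    if (sigma == 0) return(m)
    R <- max(1L, ceiling(3 * sigma))
    kern <- exp(-((0:R)^2) / (2 * sigma^2))   # indexed by |i - j|
    bandMatrix <- function(n) {
        d <- abs(outer(seq_len(n), seq_len(n), "-"))
        A <- matrix(0, n, n)
        inb <- d <= R
        A[inb] <- kern[d[inb] + 1L]
        A / rowSums(A)
    }
    bandMatrix(nrow(m)) %*% m %*% t(bandMatrix(ncol(m)))
}

#' Connected-component labelling of a binary mask
#'
#' Labels the TRUE pixels of a logical matrix using 8-connectivity (or
#' 4-connectivity). Components are numbered 1, 2, ... in column-major scan
#' order of their first pixel, so labelling is deterministic.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same dimensions; 0 is background.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[1:2, 1:2] <- TRUE; m[4:5, 4:5] <- TRUE
#' max(labelConnected(m))   # 2 components
#' @export
labelConnected <- function(mask, connectivity = 8) {
    stopifnot(is.logical(mask), connectivity %in% c(4, 8))
    nr <- nrow(mask); nc <- ncol(mask)
    out <- matrix(0L, nr, nc)
    idx <- which(mask)
    if (length(idx) == 0L) return(out)
    pos <- integer(nr * nc)
    pos[idx] <- seq_along(idx)
    rw <- ((idx - 1L) %% nr) + 1L
    cl <- ((idx - 1L) %/% nr) + 1L
    offs <- list(c(1L, 0L), c(0L, 1L))                 # down, right
    if (connectivity == 8)
        offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))   # down-right, up-right
    edges <- integer(0)
    for (off in offs) {
        ok <- rw + off[1] >= 1L & rw + off[1] <= nr & cl + off[2] <= nc
        nidx <- idx[ok] + off[1] + off[2] * nr
        ok2 <- mask[nidx]
        if (any(ok2))
            edges <- c(edges, rbind(pos[idx[ok][ok2]], pos[nidx[ok2]]))
    }
    g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
    memb <- igraph::components(g)$membership
    out[idx] <- match(memb, unique(memb))
    out
}

#' Measure labelled objects
#'
#' Computes, per labelled object, the pixel area, centroid, equivalent
#' diameter 2 * sqrt(area / pi) (in pixels and, when \code{pixelSizeUm} is
#' given, micrometres), the eccentricity of the ellipse with the same second
#' central moments (0 for a circle, approaching 1 for a line), and the mean
#' and integrated intensity in each supplied channel.
#'
#' @param labels integer label matrix (0 = background); labels need not be
#'   contiguous.
#' @param intensity an optional numeric matrix, or named list of matrices,
#'   of the same dimensions.
#' @param pixelSizeUm optional micrometres per pixel.
#' @return a data.frame with one row per label, ordered by label.
#' @examples
#' m <- matrix(0L, 20, 20); m[5:10, 5:10] <- 1L
#' regionProperties(m)$area
#' @export
regionProperties <- function(labels, intensity = NULL, pixelSizeUm = NA_real_) {
    idx <- which(labels > 0L)
    labs <- sort(unique(labels[idx]))
    if (length(idx) == 0L) {
        out <- data.frame(label = integer(0), area = integer(0),
                          centroid_row = numeric(0), centroid_col = numeric(0),
                          equiv_diameter_px = numeric(0),
                          equiv_diameter_um = numeric(0),
                          eccentricity = numeric(0))
        if (!is.null(intensity)) {
            if (is.matrix(intensity)) intensity <- list(ch1 = intensity)
            if (is.null(names(intensity)))
                names(intensity) <- paste0("ch", seq_along(intensity))
            for (nm in names(intensity)) {
                out[[paste0("integrated_intensity_", nm)]] <- numeric(0)
                out[[paste0("mean_intensity_", nm)]] <- numeric(0)
            }
        }
        return(out)
    }
    nr <- nrow(labels)
    lab <- labels[idx]
    rw <- ((idx - 1L) %% nr) + 1
    cl <- ((idx - 1L) %/% nr) + 1
    g <- factor(lab, levels = labs)
    area <- as.integer(tabulate(g, nbins = length(labs)))
    # reorder = TRUE aligns rowsum's group order with the factor levels
    # (sorted labels), matching tabulate() regardless of scan order
    sums <- function(x) rowsum(x, g, reorder = TRUE)[, 1]
    cr <- sums(rw) / area
    cc <- sums(cl) / area
    mu20 <- sums(rw^2) / area - cr^2
    mu02 <- sums(cl^2) / area - cc^2
    mu11 <- sums(rw * cl) / area - cr * cc
    tr2 <- (mu20 + mu02) / 2
    det <- sqrt(pmax(((mu20 - mu02) / 2)^2 + mu11^2, 0))
    l1 <- tr2 + det
    l2 <- pmax(tr2 - det, 0)
    ecc <- ifelse(l1 > 0, sqrt(pmax(1 - l2 / l1, 0)), 0)
    eqd <- 2 * sqrt(area / pi)
    out <- data.frame(label = labs, area = area,
                      centroid_row = cr, centroid_col = cc,
                      equiv_diameter_px = eqd,
                      equiv_diameter_um = eqd * pixelSizeUm,
                      eccentricity = ecc)
    if (!is.null(intensity)) {
        if (is.matrix(intensity)) intensity <- list(ch1 = intensity)
        if (is.null(names(intensity)))
            names(intensity) <- paste0("ch", seq_along(intensity))
        for (nm in names(intensity)) {
            tot <- sums(intensity[[nm]][idx])
            out[[paste0("integrated_intensity_", nm)]] <- tot
            out[[paste0("mean_intensity_", nm)]] <- tot / area
        }
    }
    rownames(out) <- NULL
    out
}

# Bilinear interpolation of per-tile values (at tile centers) to full image
# resolution, clamped to the outermost tile centers.
interpolateTileGrid <- function(G, rowCenters, colCenters, nr, nc) {
    if (nrow(G) == 1L) { G <- rbind(G, G); rowCenters <- c(rowCenters - 0.5, rowCenters + 0.5) }
    if (ncol(G) == 1L) { G <- cbind(G, G); colCenters <- c(colCenters - 0.5, colCenters + 0.5) }
    interpAxis <- function(p, centers) {
        i1 <- pmin(pmax(findInterval(p, centers), 1L), length(centers) - 1L)
        tt <- (p - centers[i1]) / (centers[i1 + 1L] - centers[i1])
        list(i1 = i1, t = pmin(pmax(tt, 0), 1))
    }
    rA <- interpAxis(seq_len(nr), rowCenters)
    cA <- interpAxis(seq_len(nc), colCenters)
    (1 - rA$t) %o% (1 - cA$t) * G[rA$i1, cA$i1] +
        (1 - rA$t) %o% cA$t * G[rA$i1, cA$i1 + 1L] +
        rA$t %o% (1 - cA$t) * G[rA$i1 + 1L, cA$i1] +
        rA$t %o% cA$t * G[rA$i1 + 1L, cA$i1 + 1L]
}
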
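## Mosaic regularity, territory and synaptic-apposition statistics with their
## Monte Carlo nulls, plus synthetic anatomy generators.

#' Simulate a hard-core soma mosaic
#'
#' Sequential-inhibition (random sequential adsorption) point process: points
#' are proposed uniformly in the region and accepted only if at least
#' `exclusionRadius` away from every accepted point, until the target density
#' is reached.  `exclusionRadius = 0` gives complete spatial randomness.
#'
#' @param density target density, points per mm^2.
#' @param exclusionRadius hard-core radius, micrometres.
#' @param region `(xmin, xmax, ymin, ymax)` in micrometres.
#' @param seed RNG seed.
#' @param maxAttempts proposal budget per point before giving up.
#' @return a [PointMosaic-class].
#' @export
simulateMosaic <- function(density = 898, exclusionRadius = 18,
                           region = c(0, 1000, 0, 1000), seed = 1L,
                           maxAttempts = 500) {
  .assert(density > 0, "density must be positive")
  ## pairwise distance >= r is equivalent to packing discs of radius r/2;
  ## random sequential adsorption jams near fraction 0.547
  packing <- density / 1e6 * pi * (exclusionRadius / 2)^2
  .assert(packing < 0.5,
          "unachievable packing: density x pi (r/2)^2 = %.2f exceeds the RSA limit",
          packing)
  area_mm2 <- (region[2] - region[1]) * (region[4] - region[3]) / 1e6
  n <- round(density * area_mm2)
  .withSeed(seed, function() {
    pts <- matrix(NA_real_, n, 2)
    k <- 0L
    budget <- maxAttempts * n
    while (k < n && budget > 0) {
      p <- c(stats::runif(1, region[1], region[2]),
             stats::runif(1, region[3], region[4]))
      ok <- k == 0L || exclusionRadius == 0 ||
        min((pts[seq_len(k), 1] - p[1])^2 + (pts[seq_len(k), 2] - p[2])^2) >=
          exclusionRadius^2
      if (ok) {
        k <- k + 1L
        pts[k, ] <- p
      }
      budget <- budget - 1L
    }
    .assert(k == n,
            "could not place %d points at exclusion radius %g um (placed %d)",
            n, exclusionRadius, k)
    new("PointMosaic", points = pts, region = as.numeric(region))
  })
}

#' Density recovery profile
#'
#' Neighbor density in concentric annuli around each reference point.  Edge
#' effects are handled with a border buffer: only points at least `maxRadius`
#' from the region border serve as reference points (all points count as
#' neighbors), so every annulus lies fully inside the region.  The effective
#' exclusion radius is derived from the density deficit of the contiguous
#' central dip (annuli, starting at distance 0, whose density is below the
#' mosaic mean): `D = sum (mean - density_b) * area_b` over the dip and
#' `effectiveRadius = sqrt(D / (pi * mean))` — for a perfect hard core of
#' radius `r` this recovers `r` exactly.
#'
#' @param mosaic a [PointMosaic-class] with at least 50 points.
#' @param binWidth annulus width, micrometres.
#' @param maxRadius largest distance analyzed, micrometres.
#' @return a [DRProfile-class].
#' @export
drp <- function(mosaic, binWidth = 5, maxRadius = 60) {
  pts <- mosaicPoints(mosaic)
  .assert(nrow(pts) >= 50, "at least 50 points required (%d given)", nrow(pts))
  r <- mosaic@region
  ref <- pts[, 1] >= r[1] + maxRadius & pts[, 1] <= r[2] - maxRadius &
         pts[, 2] >= r[3] + maxRadius & pts[, 2] <= r[4] - maxRadius
  .assert(any(ref), "no reference points at least maxRadius from the border")

  edges <- seq(0, maxRadius, by = binWidth)
  if (edges[length(edges)] < maxRadius) edges <- c(edges, maxRadius)
  d <- sqrt(outer(pts[ref, 1], pts[, 1], "-")^2 +
            outer(pts[ref, 2], pts[, 2], "-")^2)
  d <- d[d > 0 & d <= maxRadius]        # drops each reference's self-distance
  counts <- tabulate(findInterval(d, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  areas <- pi * diff(edges^2)           # um^2
  dens <- counts / (sum(ref) * areas)   # points per um^2
  meanDens <- nrow(pts) /
    ((r[2] - r[1]) * (r[4] - r[3]))     # points per um^2

  below <- dens < meanDens
  dipLen <- if (below[1]) which.min(c(below, FALSE)) - 1L else 0L
  deficit <- if (dipLen > 0)
    sum((meanDens - dens[seq_len(dipLen)]) * areas[seq_len(dipLen)]) else 0
  effR <- sqrt(max(deficit, 0) / (pi * meanDens))

  new("DRProfile", binEdges = edges, annulusDensity = dens * 1e6,
      meanDensity = meanDens * 1e6, effectiveRadius = effR)
}

#' Convex-hull territory area
#'
#' Area of the smallest convex polygon encompassing a z-projected arbor
#' sample.
#'
#' @param points n x 2 matrix of (x, y) positions, micrometres (n >= 3,
#'   not all collinear).
#' @return area in um^2.
#' @export
territoryArea <- function(points) {
  points <- as.matrix(points)
  .assert(nrow(points) >= 3, "at least 3 points required")
  h <- grDevices::chull(points)
  .assert(length(h) >= 3, "degenerate geometry: hull has fewer than 3 vertices")
  x <- points[h, 1]; y <- points[h, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  .assert(area > 1e-12, "degenerate geometry: collinear points")
  area
}

#' Generate a synthetic neurite scene
#'
#' Random-walk tube skeleton rasterized into an anisotropic voxel mask, with
#' synaptic puncta placed partly on the neurite surface (`connectedFraction`)
#' and partly uniformly at random within the synaptic layer.  A stand-in for
#' segmented confocal stacks so the apposition statistics can be exercised
#' with known ground truth.
#'
#' @param volume `(x, y, z)` extent of the imaged volume, micrometres.
#' @param voxelSize `(vx, vy, vz)` micrometres (defaults to the standard
#'   confocal sampling 0.103/0.103/0.3 um).
#' @param tubeRadius neurite radius, micrometres.
#' @param stepLength_um random-walk step, micrometres.
#' @param nSteps number of random-walk steps.
#' @param nPuncta number of puncta.
#' @param connectedFraction fraction of puncta seeded on the neurite.
#' @param layerBounds z-range of the synaptic layer (defaults to the central
#'   80% of the volume).
#' @param skeleton optional k x 3 matrix of skeleton waypoints (overrides the
#'   random walk; e.g. a straight tube for calibration).
#' @param seed RNG seed.
#' @return a [NeuriteScene-class].
#' @export
simulateNeuriteScene <- function(volume = c(12, 12, 6),
                                 voxelSize = c(0.103, 0.103, 0.3),
                                 tubeRadius = 0.4, stepLength_um = 0.5,
                                 nSteps = 60, nPuncta = 100,
                                 connectedFraction = 0, layerBounds = NULL,
                                 skeleton = NULL, seed = 1L) {
  if (is.null(layerBounds)) layerBounds <- c(0.1, 0.9) * volume[3]
  dims <- pmax(2L, round(volume / voxelSize))
  .withSeed(seed, function() {
    if (is.null(skeleton)) {
      margin <- tubeRadius + max(voxelSize)
      p <- volume / 2
      dirv <- c(stats::rnorm(2), stats::rnorm(1) * 0.3)
      dirv <- dirv / sqrt(sum(dirv^2))
      skeleton <- matrix(NA_real_, nSteps + 1, 3)
      skeleton[1, ] <- p
      for (i in seq_len(nSteps)) {
        dirv <- dirv + c(stats::rnorm(2, sd = 0.4), stats::rnorm(1, sd = 0.1))
        dirv <- dirv / sqrt(sum(dirv^2))
        p <- pmin(pmax(p + dirv * stepLength_um, margin), volume - margin)
        skeleton[i + 1, ] <- p
      }
    }
    ## densify the polyline, then stamp a ball of tubeRadius at each sample
    seg <- diff(skeleton)
    segLen <- sqrt(rowSums(seg^2))
    samples <- do.call(rbind, lapply(which(segLen > 0), function(i) {
      k <- max(2L, ceiling(segLen[i] / (min(voxelSize) / 2)))
      u <- seq(0, 1, length.out = k)
      cbind(skeleton[i, 1] + u * seg[i, 1],
            skeleton[i, 2] + u * seg[i, 2],
            skeleton[i, 3] + u * seg[i, 3])
    }))
    mask <- array(FALSE, dims)
    half <- ceiling(tubeRadius / voxelSize)
    offs <- expand.grid(i = -half[1]:half[1], j = -half[2]:half[2],
                        k = -half[3]:half[3])
    offd2 <- (offs$i * voxelSize[1])^2 + (offs$j * voxelSize[2])^2 +
             (offs$k * voxelSize[3])^2
    offs <- offs[offd2 <= (tubeRadius + min(voxelSize) / 2)^2, ]
    ctr <- ceiling(sweep(samples, 2, voxelSize, "/"))
    ctr <- unique(pmin(pmax(ctr, 1L), matrix(dims, nrow(ctr), 3, byrow = TRUE)))
    for (q in seq_len(nrow(ctr))) {
      ii <- ctr[q, 1] + offs$i; jj <- ctr[q, 2] + offs$j; kk <- ctr[q, 3] + offs$k
      ok <- ii >= 1 & ii <= dims[1] & jj >= 1 & jj <= dims[2] &
            kk >= 1 & kk <= dims[3]
      mask[cbind(ii[ok], jj[ok], kk[ok])] <- TRUE
    }

    nOn <- round(connectedFraction * nPuncta)
    punctaOn <- if (nOn > 0) {
      vox <- which(mask)
      pick <- vox[sample.int(length(vox), nOn, replace = TRUE)]
      kk <- (pick - 1) %/% (dims[1] * dims[2])
      jj <- (pick - 1 - kk * dims[1] * dims[2]) %/% dims[1]
      ii <- pick - 1 - kk * dims[1] * dims[2] - jj * dims[1]
      cbind((ii + 0.5) * voxelSize[1], (jj + 0.5) * voxelSize[2],
            (kk + 0.5) * voxelSize[3]) +
        matrix(stats::runif(3 * nOn, -0.05, 0.05), nOn, 3)
    } else matrix(numeric(0), 0, 3)
    nOffP <- nPuncta - nOn
    punctaOff <- cbind(stats::runif(nOffP, 0, volume[1]),
                       stats::runif(nOffP, 0, volume[2]),
                       stats::runif(nOffP, layerBounds[1], layerBounds[2]))
    pn <- rbind(punctaOn, punctaOff)
    pn <- pmin(pmax(pn, 1e-6), matrix(volume - 1e-6, nrow(pn), 3, byrow = TRUE))
    colnames(pn) <- c("x_um", "y_um", "z_um")
    new("NeuriteScene", mask = mask, voxelSize = as.numeric(voxelSize),
        puncta = pn, layerBounds = as.numeric(layerBounds))
  })
}

## Exact distance (um, anisotropic) from each punctum to the nearest mask
## voxel center, by expanding-box search.
.punctaDistances <- function(scene) {
  dims <- dim(scene@mask)
  vs <- scene@voxelSize
  p <- scene@puncta
  vapply(seq_len(nrow(p)), function(q) {
    pos <- p[q, ]
    r <- 2 * max(vs)
    repeat {
      lo <- pmax(ceiling((pos - r) / vs), 1)
      hi <- pmin(ceiling((pos + r) / vs), dims)
      sub <- scene@mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      w <- which(sub, arr.ind = TRUE)
      if (nrow(w) > 0) {
        cx <- (w[, 1] + lo[1] - 1 - 0.5) * vs[1]
        cy <- (w[, 2] + lo[2] - 1 - 0.5) * vs[2]
        cz <- (w[, 3] + lo[3] - 1 - 0.5) * vs[3]
        dmin <- sqrt(min((cx - pos[1])^2 + (cy - pos[2])^2 + (cz - pos[3])^2))
        ## the nearest voxel inside the box is authoritative only if closer
        ## than the box boundary
        if (dmin <= r || all(lo == 1) && all(hi == dims)) return(dmin)
      } else if (all(lo == 1) && all(hi == dims)) return(Inf)
      r <- r * 2
    }
  }, numeric(1))
}

#' Synaptic apposition fraction
#'
#' Fraction of puncta whose centroid lies within `threshold_um` (Euclidean
#' distance honoring the anisotropic voxel size) of the nearest neurite-mask
#' voxel, plus the per-punctum nearest distances.  The standard criterion is
#' 0.5 um; [appositionSweep()] covers the 0.25-1 um sensitivity range.
#'
#' @param scene a [NeuriteScene-class] (non-empty puncta).
#' @param threshold_um apposition criterion, micrometres.
#' @return list with `fraction`, `distances` (um) and `threshold_um`.
#' @export
appositionFraction <- function(scene, threshold_um = 0.5) {
  .assert(nrow(scene@puncta) > 0, "scene has no puncta")
  if (!any(scene@mask)) {
    warning("empty neurite mask: apposition fraction is 0")
    return(list(fraction = 0,
                distances = rep(Inf, nrow(scene@puncta)),
                threshold_um = threshold_um))
  }
  d <- .punctaDistances(scene)
  list(fraction = mean(d <= threshold_um), distances = d,
       threshold_um = threshold_um)
}

#' @rdname appositionFraction
#' @param thresholds_um thresholds for the sensitivity sweep, micrometres.
#' @return for `appositionSweep`: data.frame `threshold_um`, `fraction`.
#' @export
appositionSweep <- function(scene, thresholds_um = seq(0.25, 1, by = 0.25)) {
  d <- appositionFraction(scene, max(thresholds_um))$distances
  data.frame(threshold_um = thresholds_um,
             fraction = vapply(thresholds_um, function(t) mean(d <= t),
                               numeric(1)))
}

## Voxel-lattice apposition lookup: TRUE where a voxel center lies within
## `threshold` of a mask voxel center (binary dilation by the anisotropic
## ball).  Used by the Monte Carlo null so observed and null fractions share
## one classification rule.
.dilatedLookup <- function(mask, voxelSize, threshold) {
  dims <- dim(mask)
  half <- floor(threshold / voxelSize)
  offs <- expand.grid(i = -half[1]:half[1], j = -half[2]:half[2],
                      k = -half[3]:half[3])
  d2 <- (offs$i * voxelSize[1])^2 + (offs$j * voxelSize[2])^2 +
        (offs$k * voxelSize[3])^2
  offs <- offs[d2 <= threshold^2, ]
  out <- array(FALSE, dims)
  for (q in seq_len(nrow(offs))) {
    oi <- offs$i[q]; oj <- offs$j[q]; ok <- offs$k[q]
    xs <- max(1, 1 - oi):min(dims[1], dims[1] - oi)
    ys <- max(1, 1 - oj):min(dims[2], dims[2] - oj)
    zs <- max(1, 1 - ok):min(dims[3], dims[3] - ok)
    out[xs, ys, zs] <- out[xs, ys, zs] |
      mask[xs + oi, ys + oj, zs + ok, drop = FALSE]
  }
  out
}

.lookupFraction <- function(lookup, dims, voxelSize, pts) {
  idx <- ceiling(sweep(pts, 2, voxelSize, "/"))
  idx <- pmin(pmax(idx, 1L), matrix(dims, nrow(pts), 3, byrow = TRUE))
  mean(lookup[idx])
}

#' Monte Carlo apposition null
#'
#' Repositions the puncta uniformly at random within the synaptic layer
#' (`layerBounds` slab intersected with the imaged volume) `nIter` times and
#' recomputes the apposition fraction, yielding a null distribution and the
#' empirical p-value `p = fraction of iterations with null >= observed`.
#' Observed and null fractions are both evaluated on the voxel lattice (see
#' Details) so the comparison is exchangeable under the null.
#'
#' @details Classification uses a precomputed dilated-mask lookup: a punctum
#' counts as apposed when the voxel containing it lies within `threshold_um`
#' (anisotropic Euclidean distance between voxel centers) of a mask voxel.
#' This differs from the exact continuous distances of
#' [appositionFraction()] by at most half a voxel.
#'
#' @param scene a [NeuriteScene-class].
#' @param nIter number of randomizations (a warning below 100).
#' @param threshold_um apposition criterion, micrometres.
#' @param seed RNG seed.
#' @param lookup optional precomputed dilation lookup from
#'   [dilationLookup()], to amortize its cost over repeated calls on the same
#'   mask and threshold.
#' @return list with `observed`, `nullFractions`, `nullMean`, `nullSd`, `p`.
#' @export
randomizedNull <- function(scene, nIter = 1000, threshold_um = 0.5,
                           seed = 1L, lookup = NULL) {
  .assert(nrow(scene@puncta) > 0, "scene has no puncta")
  if (nIter < 100)
    warning("fewer than 100 Monte Carlo iterations: p-value resolution is poor")
  dims <- dim(scene@mask)
  vs <- scene@voxelSize
  if (is.null(lookup)) lookup <- .dilatedLookup(scene@mask, vs, threshold_um)
  observed <- .lookupFraction(lookup, dims, vs, scene@puncta)
  vol <- dims * vs
  zlo <- max(scene@layerBounds[1], 0)
  zhi <- min(scene@layerBounds[2], vol[3])
  n <- nrow(scene@puncta)
  nullFractions <- .withSeed(seed, function()
    vapply(seq_len(nIter), function(i) {
      pts <- cbind(stats::runif(n, 0, vol[1]), stats::runif(n, 0, vol[2]),
                   stats::runif(n, zlo, zhi))
      .lookupFraction(lookup, dims, vs, pts)
    }, numeric(1)))
  list(observed = observed, nullFractions = nullFractions,
       nullMean = mean(nullFractions), nullSd = stats::sd(nullFractions),
       p = mean(nullFractions >= observed))
}

#' Dilation lookup for repeated Monte Carlo calls
#'
#' Precomputes the voxel-lattice classification used by [randomizedNull()]
#' (TRUE where a voxel center lies within `threshold_um` of a mask voxel
#' center, anisotropic Euclidean distance).
#'
#' @inheritParams randomizedNull
#' @return 3D logical array matching the mask dimensions.
#' @export
dilationLookup <- function(scene, threshold_um = 0.5)
  .dilatedLookup(scene@mask, scene@voxelSize, threshold_um)

#' Volume fraction of the threshold-dilated neurite mask
#'
#' Fraction of the synaptic-layer volume whose voxels lie within
#' `threshold_um` of the neurite mask — the expected apposition fraction for
#' puncta placed uniformly at random in the layer.
#'
#' @inheritParams randomizedNull
#' @return a fraction in \[0, 1\].
#' @export
dilatedVolumeFraction <- function(scene, threshold_um = 0.5) {
  lookup <- .dilatedLookup(scene@mask, scene@voxelSize, threshold_um)
  vs <- scene@voxelSize
  zIdx <- which((seq_len(dim(lookup)[3]) - 0.5) * vs[3] >=
                  scene@layerBounds[1] &
                (seq_len(dim(lookup)[3]) - 0.5) * vs[3] <=
                  scene@layerBounds[2])
  mean(lookup[, , zIdx])
}
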
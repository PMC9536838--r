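#' Otsu threshold of an intensity array
#'
#' Global Otsu threshold (maximal between-class variance) computed over all
#' voxels of a 2D or 3D intensity array, returned on the array's own
#' intensity scale. A constant (e.g. all-zero) channel has no foreground;
#' the returned threshold then sits at the constant value so that no voxel
#' exceeds it.
#'
#' @param x numeric array of non-negative intensities.
#' @return scalar threshold; voxels with `x > threshold` are foreground.
#' @export
otsu_threshold <- function(x) {
  v <- as.numeric(x)
  if (any(!is.finite(v)) || any(v < 0))
    stop("intensities must be finite and >= 0")
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[2])
  scaled <- (v - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1)))
  rng[1] + thr * (rng[2] - rng[1])
}

check_same_dim <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("channels must share dimensions (got ",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")")
}

#' Colocalization mask: focus signal restricted to the mitochondrial network
#'
#' Nucleoid foci are only counted where the focus channel colocalizes with
#' the mitochondrial channel: the mask is the AND of the two per-channel
#' foreground masks. Thresholds default to per-channel Otsu (the original
#' manual ImageJ thresholds are not parameterized); pass numbers to
#' override, and any override is recorded as an attribute of the mask.
#'
#' @param foci_channel,mito_channel arrays of identical dimensions.
#' @param foci_threshold,mito_threshold `"otsu"` or a numeric threshold.
#' @return logical array; attributes `foci_threshold` / `mito_threshold`
#'   record the values used.
#' @export
colocalization_mask <- function(foci_channel, mito_channel,
                                foci_threshold = "otsu",
                                mito_threshold = "otsu") {
  check_same_dim(foci_channel, mito_channel)
  thr_a <- if (identical(foci_threshold, "otsu"))
    otsu_threshold(foci_channel) else as.numeric(foci_threshold)
  thr_b <- if (identical(mito_threshold, "otsu"))
    otsu_threshold(mito_channel) else as.numeric(mito_threshold)
  mask <- (foci_channel > thr_a) & (mito_channel > thr_b)
  attr(mask, "foci_threshold") <- thr_a
  attr(mask, "mito_threshold") <- thr_b
  mask
}

# Logical array of voxels that are >= all of their 26-connected neighbors.
local_maxima_26 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 3)
  is_max <- array(TRUE, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    z1 <- max(1, 1 - dz); z2 <- min(d[1], d[1] - dz)
    y1 <- max(1, 1 - dy); y2 <- min(d[2], d[2] - dy)
    x1 <- max(1, 1 - dx); x2 <- min(d[3], d[3] - dx)
    if (z1 > z2 || y1 > y2 || x1 > x2) next
    a <- x[z1:z2, y1:y2, x1:x2, drop = FALSE]
    b <- x[(z1 + dz):(z2 + dz), (y1 + dy):(y2 + dy),
           (x1 + dx):(x2 + dx), drop = FALSE]
    is_max[z1:z2, y1:y2, x1:x2] <- is_max[z1:z2, y1:y2, x1:x2] & (a >= b)
  }
  is_max
}

#' Count nucleoid foci as 3D local maxima inside a mask
#'
#' Reimplements 3D-maxima-style focus counting: the channel is first
#' smoothed with a 3x3x3 box filter (single-voxel noise spikes otherwise
#' masquerade as maxima); candidate foci are then voxels that are local
#' intensity maxima over their 26-connected neighborhood, lie inside the
#' (colocalization) mask, and exceed a minimum intensity.
#' Candidates are then suppressed within a minimum separation — anisotropic
#' by default, reflecting the coarser axial sampling of confocal stacks: a
#' candidate is dropped if a brighter accepted focus lies within
#' `min_distance["xy"]` voxels laterally *and* `min_distance["z"]` voxels
#' axially.
#'
#' @param foci_channel 3D intensity array, ordered `[z, y, x]`.
#' @param mask logical array of the same dimensions (e.g. from
#'   [colocalization_mask()]); an empty mask yields zero foci.
#' @param min_distance named numeric, `c(z = 1, xy = 3)` by default.
#' @param min_intensity intensity floor for candidates, applied on the
#'   (smoothed) channel: a number, a string `"q<p>"` (e.g. `"q0.9"`) for a
#'   quantile of in-mask intensity, or the default `"otsu"` — an Otsu
#'   split of in-mask intensities, which separates the residual noise
#'   plateau from spot peaks.
#' @param cell_labels optional integer array of cell ROI labels (0 =
#'   outside any cell) for a per-cell focus tally; cells were outlined
#'   manually in the original workflow, so labels are supplied, not
#'   segmented.
#' @param smooth apply the 3x3x3 box filter before maxima detection
#'   (default `TRUE`).
#' @return object of class `foci_count`: list with `n_foci`,
#'   `coordinates` (data frame `z`, `y`, `x`, `intensity`), and `per_cell`
#'   (named vector) when `cell_labels` is given.
#' @export
count_foci_3d <- function(foci_channel, mask,
                          min_distance = c(z = 1, xy = 3),
                          min_intensity = "otsu", cell_labels = NULL,
                          smooth = TRUE) {
  check_same_dim(foci_channel, array(0, dim(mask)))
  if (smooth) foci_channel <- box_smooth_3(foci_channel)
  if (!any(mask)) {
    return(structure(list(n_foci = 0L,
                          coordinates = data.frame(z = integer(0),
                                                   y = integer(0),
                                                   x = integer(0),
                                                   intensity = numeric(0)),
                          per_cell = NULL),
                     class = "foci_count"))
  }
  if (identical(min_intensity, "otsu")) {
    min_intensity <- otsu_threshold(foci_channel[mask])
  } else if (is.character(min_intensity)) {
    p <- as.numeric(sub("^q", "", min_intensity))
    min_intensity <- stats::quantile(foci_channel[mask], p, names = FALSE)
  }
  cand <- which(local_maxima_26(foci_channel) & mask &
                  foci_channel > min_intensity)
  if (!length(cand)) {
    return(structure(list(n_foci = 0L,
                          coordinates = data.frame(z = integer(0),
                                                   y = integer(0),
                                                   x = integer(0),
                                                   intensity = numeric(0)),
                          per_cell = NULL),
                     class = "foci_count"))
  }
  co <- arrayInd(cand, dim(foci_channel))
  int <- foci_channel[cand]
  ord <- order(int, decreasing = TRUE)
  co <- co[ord, , drop = FALSE]; int <- int[ord]
  keep <- logical(length(int))
  for (i in seq_along(int)) {
    acc <- which(keep)
    if (!length(acc)) { keep[i] <- TRUE; next }
    close_z <- abs(co[acc, 1] - co[i, 1]) <= min_distance[["z"]]
    close_y <- abs(co[acc, 2] - co[i, 2]) <= min_distance[["xy"]]
    close_x <- abs(co[acc, 3] - co[i, 3]) <= min_distance[["xy"]]
    if (!any(close_z & close_y & close_x)) keep[i] <- TRUE
  }
  co <- co[keep, , drop = FALSE]; int <- int[keep]
  coords <- data.frame(z = co[, 1], y = co[, 2], x = co[, 3],
                       intensity = int)
  per_cell <- NULL
  if (!is.null(cell_labels)) {
    lab <- cell_labels[cbind(coords$z, coords$y, coords$x)]
    per_cell <- table(factor(lab[lab > 0]))
    per_cell <- setNames(as.integer(per_cell), names(per_cell))
  }
  structure(list(n_foci = nrow(coords), coordinates = coords,
                 per_cell = per_cell),
            class = "foci_count")
}

#' @export
print.foci_count <- function(x, ...) {
  cat(sprintf("<foci_count> %d foci\n", x$n_foci))
  invisible(x)
}

#' Manders colocalization coefficient (M1)
#'
#' Fraction of one channel's intensity residing in voxels where the second
#' channel is above threshold:
#' `M1 = sum(A[B > thr]) / sum(A)` over the region of interest. Always in
#' `[0, 1]`; 1 when channel A lies entirely inside B-positive voxels, 0
#' when the channels are disjoint.
#'
#' @param channel_a,channel_b intensity arrays of identical dimensions.
#' @param roi optional logical array restricting the computation.
#' @param threshold_b `"otsu"` or a numeric threshold for channel B.
#' @return M1, a fraction in `[0, 1]`.
#' @export
manders_coefficient <- function(channel_a, channel_b, roi = NULL,
                                threshold_b = "otsu") {
  check_same_dim(channel_a, channel_b)
  if (is.null(roi)) roi <- array(TRUE, dim(channel_a))
  check_same_dim(channel_a, array(0, dim(roi)))
  if (!any(roi)) stop("empty region of interest")
  thr <- if (identical(threshold_b, "otsu"))
    otsu_threshold(channel_b) else as.numeric(threshold_b)
  total <- sum(channel_a[roi])
  if (total == 0) stop("channel A carries no intensity in the ROI")
  sum(channel_a[roi & (channel_b > thr)]) / total
}

#' Green-to-red intensity ratio of one or two regions of interest
#'
#' Mitochondrial acidification quenches the pH-sensitive green reporter but
#' not the red one, so the green/red mean-intensity ratio reports
#' lysosomal digestion. Two ROIs are conventionally compared — one around
#' cannibalized lobe debris and one around cell-body mitochondria — with a
#' paired-ratio t test across animals delegated to the statistics layer.
#'
#' @param green,red intensity arrays of identical dimensions.
#' @param roi logical array; must select at least one voxel, with positive
#'   mean red signal.
#' @param roi_label label recorded in the result.
#' @return data frame row: `roi_label`, `green_mean`, `red_mean`, `ratio`.
#' @export
acidification_ratio <- function(green, red, roi,
                                roi_label = "roi") {
  check_same_dim(green, red)
  check_same_dim(green, array(0, dim(roi)))
  if (!any(roi)) stop("empty region of interest: ", roi_label)
  gm <- mean(green[roi]); rm_ <- mean(red[roi])
  if (rm_ <= 0) stop("no red signal in ROI '", roi_label,
                     "': ratio undefined")
  data.frame(roi_label = roi_label, green_mean = gm, red_mean = rm_,
             ratio = gm / rm_, stringsAsFactors = FALSE)
}

# 3D connected-component labelling of a logical array (26-connectivity).
# No installed package labels 3D components, so this is a hand-rolled
# flood fill over voxel coordinates.
label_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  labels <- array(0L, d)
  vox <- which(mask)
  if (!length(vox)) return(labels)
  co <- arrayInd(vox, d)
  idx <- array(0L, d)       # voxel -> row in `co`, 0 elsewhere
  idx[vox] <- seq_along(vox)
  visited <- logical(length(vox))
  lab <- 0L
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (s in seq_along(vox)) {
    if (visited[s]) next
    lab <- lab + 1L
    stack <- s; visited[s] <- TRUE
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      labels[co[i, 1], co[i, 2], co[i, 3]] <- lab
      nb <- sweep(offs, 2, co[i, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      j <- idx[nb]
      j <- j[j > 0]
      j <- j[!visited[j]]
      if (length(j)) { visited[j] <- TRUE; stack <- c(stack, j) }
    }
  }
  labels
}

# 3x3x3 box smoothing (borders renormalized), used to stabilize per-voxel
# ratios before region detection.
box_smooth_3 <- function(x) {
  d <- dim(x)
  acc <- array(0, d); cnt <- array(0, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    z1 <- max(1, 1 - dz); z2 <- min(d[1], d[1] - dz)
    y1 <- max(1, 1 - dy); y2 <- min(d[2], d[2] - dy)
    x1 <- max(1, 1 - dx); x2 <- min(d[3], d[3] - dx)
    acc[z1:z2, y1:y2, x1:x2] <- acc[z1:z2, y1:y2, x1:x2] +
      x[(z1 + dz):(z2 + dz), (y1 + dy):(y2 + dy), (x1 + dx):(x2 + dx)]
    cnt[z1:z2, y1:y2, x1:x2] <- cnt[z1:z2, y1:y2, x1:x2] + 1
  }
  acc / cnt
}

#' Detect acidified regions by the twofold green/red rule
#'
#' A region of the mitochondrial network is scored as acidified when its
#' local green-to-red ratio is at least twofold less than the ratio of the
#' greater network. The reference ratio is `mean(green)/mean(red)` over
#' the whole network mask (including any candidate region, so a region
#' sitting exactly at half the surrounding ratio falls just short of the
#' threshold and is not flagged; detection requires genuinely deeper
#' acidification). Candidate voxels satisfy
#' `ratio <= reference / fold` (inclusive) after 3x3x3 box smoothing of
#' both channels; 26-connected components smaller than `min_size` voxels
#' are discarded as noise. The categorical flag — does the image contain
#' any acidified region — is what feeds contingency-table scoring.
#'
#' @param green,red intensity arrays of identical dimensions.
#' @param network_mask logical array of the mitochondrial network.
#' @param fold detection fold change (default 2).
#' @param min_size minimum region size in voxels (default 5).
#' @param smooth apply 3x3x3 box smoothing before the per-voxel ratio.
#' @return list with `flag` (any region present), `n_regions`, `regions`
#'   (data frame `label`, `n_voxels`, `mean_ratio`), `network_ratio`, and
#'   `labels` (integer array of region labels).
#' @export
detect_acidified_regions <- function(green, red, network_mask, fold = 2,
                                     min_size = 5, smooth = TRUE) {
  check_same_dim(green, red)
  check_same_dim(green, array(0, dim(network_mask)))
  if (!any(network_mask)) stop("degenerate network: empty mask")
  net_ratio <- mean(green[network_mask]) / mean(red[network_mask])
  g <- if (smooth) box_smooth_3(green) else green
  r <- if (smooth) box_smooth_3(red) else red
  ratio <- array(Inf, dim(green))
  pos <- r > 0
  ratio[pos] <- g[pos] / r[pos]
  cand <- network_mask & (ratio <= net_ratio / fold)
  labels <- label_components_3d(cand)
  keep <- integer(0)
  if (max(labels) > 0) {
    sizes <- tabulate(labels[labels > 0])
    keep <- which(sizes >= min_size)
  }
  relab <- array(0L, dim(labels))
  regions <- data.frame(label = integer(0), n_voxels = integer(0),
                        mean_ratio = numeric(0))
  for (i in seq_along(keep)) {
    sel <- labels == keep[i]
    relab[sel] <- i
    regions <- rbind(regions, data.frame(
      label = i, n_voxels = sum(sel), mean_ratio = mean(ratio[sel])))
  }
  list(flag = length(keep) > 0, n_regions = length(keep),
       regions = regions, network_ratio = net_ratio, labels = relab)
}

#' Fraction of mitochondrial signal inside the cell body
#'
#' Mitochondrial content is measured as the count of mitochondria-positive
#' voxels; the cell-body fraction is the share of those voxels lying inside
#' the supplied cell-body ROI (the remainder sits in lobes).
#'
#' @param mito_channel intensity array.
#' @param body_roi logical array, same dimensions.
#' @param threshold `"otsu"` or numeric threshold defining
#'   mitochondria-positive voxels.
#' @return fraction in `[0, 1]`.
#' @export
cell_body_fraction <- function(mito_channel, body_roi, threshold = "otsu") {
  check_same_dim(mito_channel, array(0, dim(body_roi)))
  thr <- if (identical(threshold, "otsu"))
    otsu_threshold(mito_channel) else as.numeric(threshold)
  positive <- mito_channel > thr
  if (!any(positive)) stop("no mitochondria-positive voxels")
  sum(positive & body_roi) / sum(positive)
}

#' Ellipsoid and sphere volumes from measured axes
#'
#' Whole embryos approximate an ellipsoid measured by its three semi-axes
#' (`V = 4/3 pi a b c`); sorted cells in suspension approximate a sphere
#' measured by its diameter (`V = 4/3 pi (d/2)^3`).
#'
#' @param a,b,c ellipsoid semi-axes (radii) in micrometers, all > 0.
#' @return volume in cubic micrometers.
#' @export
#' @examples
#' ellipsoid_volume(30, 15, 15)
#' sphere_volume(8.2)
ellipsoid_volume <- function(a, b, c) {
  if (any(c(a, b, c) <= 0)) stop("all radii must be > 0")
  4 / 3 * pi * a * b * c
}

#' @rdname ellipsoid_volume
#' @param diameter sphere diameter in micrometers, > 0.
#' @export
sphere_volume <- function(diameter) {
  if (any(diameter <= 0)) stop("'diameter' must be > 0")
  4 / 3 * pi * (diameter / 2)^3
}
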
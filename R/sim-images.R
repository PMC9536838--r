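#' Two-channel 3D image stack with optional ground truth
#'
#' Container for synthetic (or imported) confocal-style stacks: two
#' channels as 3D arrays ordered `[z, y, x]`, voxel dimensions in
#' micrometers, and — for synthetic stacks — the generating truth (focus
#' coordinates and/or an acidified-region mask) used as the oracle in
#' validation.
#'
#' @param channel_a,channel_b 3D arrays of finite, non-negative
#'   intensities with identical dimensions.
#' @param voxel_size named numeric `c(z=, y=, x=)` in micrometers.
#' @param truth optional list; recognized fields are `foci` (data frame
#'   `z`, `y`, `x`, voxel coordinates inside the grid) and `mask` (logical
#'   array of truth voxels).
#' @return object of class `image_stack`.
#' @export
image_stack <- function(channel_a, channel_b,
                        voxel_size = c(z = 0.5, y = 0.1, x = 0.1),
                        truth = NULL) {
  check_same_dim(channel_a, channel_b)
  if (length(dim(channel_a)) != 3) stop("channels must be 3D arrays")
  for (ch in list(channel_a, channel_b))
    if (any(!is.finite(ch)) || any(ch < 0))
      stop("intensities must be finite and >= 0")
  if (!is.null(truth$foci)) {
    d <- dim(channel_a)
    ok <- truth$foci$z >= 1 & truth$foci$z <= d[1] &
      truth$foci$y >= 1 & truth$foci$y <= d[2] &
      truth$foci$x >= 1 & truth$foci$x <= d[3]
    if (!all(ok)) stop("truth focus coordinates fall outside the grid")
  }
  structure(list(channel_a = channel_a, channel_b = channel_b,
                 voxel_size = voxel_size, truth = truth),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %s voxels (z,y,x), voxel %s um\n",
              paste(dim(x$channel_a), collapse = "x"),
              paste(x$voxel_size, collapse = "x")))
  if (!is.null(x$truth$foci))
    cat(sprintf("  truth: %d foci\n", nrow(x$truth$foci)))
  if (!is.null(x$truth$mask))
    cat(sprintf("  truth: %d mask voxels\n", sum(x$truth$mask)))
  invisible(x)
}

# Ellipsoidal "mitochondrial region" mask centered in the grid.
ellipsoid_mask <- function(dim3, semi = dim3 / 2 - 2) {
  ctr <- (dim3 + 1) / 2
  z <- slice.index(array(0, dim3), 1)
  y <- slice.index(array(0, dim3), 2)
  x <- slice.index(array(0, dim3), 3)
  ((z - ctr[1]) / semi[1])^2 + ((y - ctr[2]) / semi[2])^2 +
    ((x - ctr[3]) / semi[3])^2 <= 1
}

# Add one anisotropic Gaussian spot of peak height `peak` at voxel `ctr`.
add_gaussian_spot <- function(img, ctr, sigma, peak) {
  d <- dim(img)
  half <- ceiling(3 * sigma)
  z <- max(1, ctr[1] - half[1]):min(d[1], ctr[1] + half[1])
  y <- max(1, ctr[2] - half[2]):min(d[2], ctr[2] + half[2])
  x <- max(1, ctr[3] - half[3]):min(d[3], ctr[3] + half[3])
  gz <- exp(-((z - ctr[1])^2) / (2 * sigma[1]^2))
  gy <- exp(-((y - ctr[2])^2) / (2 * sigma[2]^2))
  gx <- exp(-((x - ctr[3])^2) / (2 * sigma[3]^2))
  img[z, y, x] <- img[z, y, x] + peak * (gz %o% gy %o% gx)
  img
}

#' Generate a synthetic nucleoid-focus stack with known truth
#'
#' Builds a two-channel stack emulating nucleoid imaging: `channel_b`
#' renders an ellipsoidal mitochondrial region as intensity, and
#' `channel_a` contains `n_foci` Gaussian spots at recorded truth
#' coordinates plus Gaussian background noise. Foci are placed by
#' rejection sampling with a minimum pairwise separation; a fraction can
#' deliberately be placed *outside* the mitochondrial region to exercise
#' colocalization masking (such foci are recorded in the truth with
#' `in_mask = FALSE` and must be excluded downstream).
#'
#' @param n_foci number of foci (>= 0).
#' @param dim3 stack dimensions `c(z, y, x)`.
#' @param psf_sigma Gaussian spot widths in voxels, `c(z, y, x)`.
#' @param snr peak-to-noise ratio: background noise sd is `peak / snr`.
#' @param peak spot peak intensity.
#' @param min_separation minimum separation between foci, `c(z=, xy=)`
#'   voxels.
#' @param frac_outside fraction of foci placed outside the mitochondrial
#'   region.
#' @param voxel_size voxel lengths in micrometers.
#' @return an [image_stack()] whose `truth$foci` has columns `z`, `y`,
#'   `x`, `in_mask`.
#' @export
#' @examples
#' set.seed(1)
#' stk <- generate_foci_image(n_foci = 10, snr = 20)
#' nrow(stk$truth$foci)
generate_foci_image <- function(n_foci = 25, dim3 = c(16, 64, 64),
                                psf_sigma = c(z = 1, y = 1.5, x = 1.5),
                                snr = 10, peak = 100,
                                min_separation = c(z = 3, xy = 7),
                                frac_outside = 0,
                                voxel_size = c(z = 0.5, y = 0.1, x = 0.1)) {
  if (n_foci < 0) stop("'n_foci' must be >= 0")
  mask <- ellipsoid_mask(dim3)
  inside <- arrayInd(which(mask), dim3)
  outside <- arrayInd(which(!mask), dim3)
  n_out <- round(n_foci * frac_outside)
  n_in <- n_foci - n_out
  placed <- matrix(numeric(0), ncol = 3)
  in_mask <- logical(0)
  place <- function(cand_pool, n_want, flag) {
    tries <- 0
    while (n_want > 0) {
      tries <- tries + 1
      if (tries > 5000 * max(1, n_want))
        stop("cannot place ", n_want, " more foci at the requested ",
             "minimum separation: region too small")
      p <- cand_pool[sample(nrow(cand_pool), 1), ]
      if (nrow(placed)) {
        clash <- abs(placed[, 1] - p[1]) <= min_separation[["z"]] &
          abs(placed[, 2] - p[2]) <= min_separation[["xy"]] &
          abs(placed[, 3] - p[3]) <= min_separation[["xy"]]
        if (any(clash)) next
      }
      placed <<- rbind(placed, p)
      in_mask <<- c(in_mask, flag)
      n_want <- n_want - 1
    }
  }
  if (n_in > 0) place(inside, n_in, TRUE)
  if (n_out > 0) place(outside, n_out, FALSE)
  ch_a <- array(0, dim3)
  for (i in seq_len(nrow(placed)))
    ch_a <- add_gaussian_spot(ch_a, placed[i, ], psf_sigma, peak)
  noise <- array(abs(rnorm(prod(dim3), 0, peak / snr)), dim3)
  ch_a <- ch_a + noise
  ch_b <- mask * peak + array(abs(rnorm(prod(dim3), 0, peak / 50)), dim3)
  truth <- list(
    foci = if (nrow(placed)) data.frame(z = placed[, 1], y = placed[, 2],
                                        x = placed[, 3], in_mask = in_mask)
           else data.frame(z = integer(0), y = integer(0), x = integer(0),
                           in_mask = logical(0)),
    mask = mask)
  image_stack(ch_a, ch_b, voxel_size, truth)
}

#' Generate a synthetic acidification stack with known truth
#'
#' Emulates the dual-reporter acidification readout: `channel_b` (red,
#' pH-insensitive) renders the mitochondrial network at constant
#' intensity; `channel_a` (green, pH-sensitive) carries ratio
#' `network_ratio` over the network except inside a spherical truth region
#' where the ratio drops to `acidified_ratio` (quenching). Set `n_regions
#' = 0` for a uniform network with no acidified region.
#'
#' @param network_ratio green/red ratio of the bulk network (> 0).
#' @param acidified_ratio green/red ratio inside the acidified region;
#'   must be < `network_ratio`.
#' @param n_regions 0 or 1 acidified regions.
#' @param region_radius radius of the acidified sphere, in voxels.
#' @param dim3 stack dimensions `c(z, y, x)`.
#' @param red_level red-channel intensity over the network.
#' @param noise_sd additive Gaussian noise sd on both channels.
#' @param voxel_size voxel lengths in micrometers.
#' @return an [image_stack()] whose `truth$mask` marks the acidified
#'   voxels (all `FALSE` when `n_regions = 0`).
#' @export
generate_acidified_image <- function(network_ratio = 1,
                                     acidified_ratio = 0.25,
                                     n_regions = 1, region_radius = 3,
                                     dim3 = c(12, 48, 48),
                                     red_level = 100, noise_sd = 1,
                                     voxel_size = c(z = 0.5, y = 0.1,
                                                    x = 0.1)) {
  if (network_ratio <= 0 || acidified_ratio <= 0)
    stop("ratios must be > 0")
  if (n_regions > 0 && acidified_ratio >= network_ratio)
    stop("'acidified_ratio' must be < 'network_ratio'")
  net <- ellipsoid_mask(dim3)
  region <- array(FALSE, dim3)
  if (n_regions > 0) {
    ctr <- round(dim3 / 2 + c(0, dim3[2] %/% 5, 0))
    z <- slice.index(region, 1); y <- slice.index(region, 2)
    x <- slice.index(region, 3)
    region <- ((z - ctr[1])^2 + (y - ctr[2])^2 + (x - ctr[3])^2 <=
                 region_radius^2) & net
  }
  red <- net * red_level
  green <- net * red_level * network_ratio
  green[region] <- red_level * acidified_ratio
  red <- pmax(red + array(rnorm(prod(dim3), 0, noise_sd), dim3), 0)
  green <- pmax(green + array(rnorm(prod(dim3), 0, noise_sd), dim3), 0)
  image_stack(green, red, voxel_size,
              truth = list(mask = region, network_mask = net))
}

#' Write / read an image stack as TIFF with sidecar metadata
#'
#' Each channel is written as a multi-page (one page per z-slice) TIFF;
#' intensities are scaled into `[0, 1]` for storage and the scale factor,
#' voxel size and channel file names are recorded in a JSON sidecar. Truth
#' annotations, when present, are written alongside: focus coordinates as
#' CSV and the truth mask as a 0/1 label TIFF. `read_image_stack()`
#' reverses all of it.
#'
#' @param stack an [image_stack()].
#' @param basename output path prefix (directory must exist); files are
#'   `<basename>_a.tif`, `<basename>_b.tif`, `<basename>_meta.json`, and
#'   optionally `<basename>_truth_foci.csv`, `<basename>_truth_mask.tif`.
#' @return `basename`, invisibly.
#' @export
write_image_stack <- function(stack, basename) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- max(stack$channel_a, stack$channel_b, 1)
  as_pages <- function(ch)
    lapply(seq_len(dim(ch)[1]), function(z) ch[z, , ] / scale)
  tiff::writeTIFF(as_pages(stack$channel_a), paste0(basename, "_a.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(as_pages(stack$channel_b), paste0(basename, "_b.tif"),
                  bits.per.sample = 16)
  meta <- list(intensity_scale = scale, voxel_size = as.list(stack$voxel_size),
               dim = dim(stack$channel_a))
  jsonlite::write_json(meta, paste0(basename, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(stack$truth$foci))
    write.csv(stack$truth$foci, paste0(basename, "_truth_foci.csv"),
              row.names = FALSE)
  if (!is.null(stack$truth$mask))
    tiff::writeTIFF(lapply(seq_len(dim(stack$truth$mask)[1]),
                           function(z) stack$truth$mask[z, , ] * 1),
                    paste0(basename, "_truth_mask.tif"),
                    bits.per.sample = 8)
  invisible(basename)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(basename) {
  meta <- jsonlite::read_json(paste0(basename, "_meta.json"),
                              simplifyVector = TRUE)
  read_ch <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    d <- c(length(pages), dim(pages[[1]]))
    ch <- array(0, d)
    for (z in seq_along(pages)) ch[z, , ] <- pages[[z]]
    ch * meta$intensity_scale
  }
  truth <- NULL
  foci_path <- paste0(basename, "_truth_foci.csv")
  mask_path <- paste0(basename, "_truth_mask.tif")
  if (file.exists(foci_path))
    truth$foci <- read.csv(foci_path, stringsAsFactors = FALSE)
  if (file.exists(mask_path)) {
    pages <- tiff::readTIFF(mask_path, all = TRUE)
    d <- c(length(pages), dim(pages[[1]]))
    m <- array(FALSE, d)
    for (z in seq_along(pages)) m[z, , ] <- pages[[z]] > 0.5
    truth$mask <- m
  }
  image_stack(read_ch(paste0(basename, "_a.tif")),
              read_ch(paste0(basename, "_b.tif")),
              voxel_size = unlist(meta$voxel_size), truth = truth)
}
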
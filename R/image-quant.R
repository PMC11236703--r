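# Per-cell quantification of multi-channel fluorescence frames:
# flatfield correction, local background subtraction, nuclear segmentation,
# cytoplasmic-ring sampling for translocation reporters, whole-cell regions
# and FISH foreground-pixel counting.

#' Flatfield-correct an image
#'
#' Divides by the illumination bias field normalized to mean 1, so a
#' uniform image keeps its mean.
#'
#' @param image numeric matrix.
#' @param bias_field strictly positive matrix of the same shape.
#' @return corrected matrix.
#' @export
flatfield_correct <- function(image, bias_field) {
  if (!all(dim(image) == dim(bias_field)))
    stop("bias field must match image dimensions")
  if (any(bias_field <= 0)) stop("bias field must be strictly positive")
  image / (bias_field / mean(bias_field))
}

#' Estimate an illumination bias field from many frames
#'
#' Per-pixel low percentile across frames (background areas dominate the
#' low tail), smoothed with a wide Gaussian. Supply this when no measured
#' bias is available.
#'
#' @param frames list of matrices (same shape).
#' @param percentile low percentile per pixel (default 0.1).
#' @param smooth_sigma Gaussian smoothing (px, default 32).
#' @return positive matrix (mean 1).
#' @export
estimate_bias_field <- function(frames, percentile = 0.1, smooth_sigma = 32) {
  stopifnot(length(frames) >= 1)
  arr <- simplify2array(frames)
  low <- apply(arr, c(1, 2), stats::quantile, probs = percentile)
  sm <- as.matrix(EBImage::gblur(low, sigma = smooth_sigma))
  sm <- pmax(sm, 1e-6)
  sm / mean(sm)
}

#' Subtract local background
#'
#' Background is the low percentile (default 10th) of each block of
#' `block_size_px`, bilinearly interpolated between block centres and
#' subtracted; negative residuals are clipped to 0. A block larger than
#' the image falls back to a global percentile.
#'
#' @param image numeric matrix.
#' @param block_size_px block edge in pixels (>= 32).
#' @param percentile background percentile in \[0, 1\] (default 0.1).
#' @return background-subtracted matrix (non-negative).
#' @export
subtract_background_local <- function(image, block_size_px = 128,
                                      percentile = 0.1) {
  if (block_size_px < 32) stop("block_size_px must be >= 32")
  nr <- nrow(image); nc <- ncol(image)
  if (block_size_px >= nr || block_size_px >= nc) {
    bgv <- stats::quantile(image, percentile)
    return(pmax(image - bgv, 0))
  }
  ry <- seq(1, nr + 1, by = block_size_px)
  rx <- seq(1, nc + 1, by = block_size_px)
  if (ry[length(ry)] <= nr) ry <- c(ry, nr + 1)
  if (rx[length(rx)] <= nc) rx <- c(rx, nc + 1)
  ny <- length(ry) - 1; nx <- length(rx) - 1
  vals <- matrix(0, ny, nx); cy <- numeric(ny); cx <- numeric(nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      ys <- ry[i]:(ry[i + 1] - 1); xs <- rx[j]:(rx[j + 1] - 1)
      vals[i, j] <- stats::quantile(image[ys, xs], percentile)
    }
  }
  cy <- (ry[-length(ry)] + ry[-1] - 1) / 2
  cx <- (rx[-length(rx)] + rx[-1] - 1) / 2
  bg <- interp_grid(vals, cy, cx, nr, nc)
  pmax(image - bg, 0)
}

#' Segment nuclei from a nuclear-marker channel
#'
#' Global Otsu threshold on the log-intensity, distance-transform watershed
#' to split touching nuclei, and area gating. Labels are contiguous
#' positive integers; components are 8-connected.
#'
#' @param nuclear_channel corrected matrix.
#' @param min_area_px,max_area_px area gate (px).
#' @param watershed_tolerance minimum object-separating depth of the
#'   distance transform (px, default 1).
#' @return integer label matrix with attributes `areas` (px per label) and
#'   `centroids` (matrix with columns x, y).
#' @export
segment_nuclei <- function(nuclear_channel, min_area_px = 40,
                           max_area_px = 5000, watershed_tolerance = 1) {
  img <- pmax(nuclear_channel, 0)
  l <- log1p(img)
  rng <- range(l)
  if (diff(rng) == 0) {
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "areas") <- integer(0)
    attr(out, "centroids") <- matrix(numeric(0), 0, 2,
                                     dimnames = list(NULL, c("x", "y")))
    return(out)
  }
  ln <- (l - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(ln), range = c(0, 1))
  fg <- ln > th
  if (!any(fg)) {
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "areas") <- integer(0)
    attr(out, "centroids") <- matrix(numeric(0), 0, 2,
                                     dimnames = list(NULL, c("x", "y")))
    return(out)
  }
  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  relabel_mask(lab, min_area_px, max_area_px)
}

# drop labels outside the area gate and relabel 1..K; attach areas/centroids
relabel_mask <- function(lab, min_area_px = 0, max_area_px = Inf) {
  labs <- sort(unique(lab[lab > 0]))
  if (!length(labs)) {
    out <- matrix(0L, nrow(lab), ncol(lab))
    attr(out, "areas") <- integer(0)
    attr(out, "centroids") <- matrix(numeric(0), 0, 2,
                                     dimnames = list(NULL, c("x", "y")))
    return(out)
  }
  areas <- tabulate(lab, nbins = max(labs))[labs]
  keep <- labs[areas >= min_area_px & areas <= max_area_px]
  map <- integer(max(labs))
  map[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  sel <- lab > 0
  out[sel] <- map[lab[sel]]
  k <- length(keep)
  cents <- matrix(NA_real_, k, 2, dimnames = list(NULL, c("x", "y")))
  if (k) {
    idx <- which(out > 0, arr.ind = TRUE)
    lb <- out[out > 0]
    cents[, "x"] <- tapply(idx[, 2], lb, mean)
    cents[, "y"] <- tapply(idx[, 1], lb, mean)
  }
  attr(out, "areas") <- tabulate(out, nbins = k)
  attr(out, "centroids") <- cents
  out
}

# Exact Euclidean distance of every background pixel to the nearest nucleus
# (up to max_px) and the label of that nearest nucleus. The nearest nucleus
# pixel of an outside point is always on the nucleus boundary, so distances
# are computed against per-label boundary pixel sets within a bounding box.
.nucleus_distance_owner <- function(mask, max_px) {
  nr <- nrow(mask); nc <- ncol(mask)
  dist2 <- matrix(Inf, nr, nc)
  owner <- matrix(0L, nr, nc)
  labs <- seq_len(max(mask, 0L))
  if (!length(labs)) return(list(distance = dist2, owner = owner))
  # boundary = nucleus pixel with a 4-neighbour of a different label
  on <- mask > 0
  b <- matrix(FALSE, nr, nc)
  b[-nr, ] <- b[-nr, ] | (mask[-nr, ] != mask[-1, ])
  b[-1, ] <- b[-1, ] | (mask[-1, ] != mask[-nr, ])
  b[, -nc] <- b[, -nc] | (mask[, -nc] != mask[, -1])
  b[, -1] <- b[, -1] | (mask[, -1] != mask[, -nc])
  b[c(1, nr), ] <- TRUE; b[, c(1, nc)] <- TRUE
  b <- b & on
  bidx <- which(b, arr.ind = TRUE)
  blab <- mask[b]
  pad <- ceiling(max_px) + 1L
  for (k in labs) {
    sel <- blab == k
    if (!any(sel)) next
    by <- bidx[sel, 1]; bx <- bidx[sel, 2]
    ys <- max(1L, min(by) - pad):min(nr, max(by) + pad)
    xs <- max(1L, min(bx) - pad):min(nc, max(bx) + pad)
    Y <- rep(ys, times = length(xs)); X <- rep(xs, each = length(ys))
    d2 <- rep(Inf, length(Y))
    for (j in seq_along(by))
      d2 <- pmin(d2, (Y - by[j])^2 + (X - bx[j])^2)
    box <- as.matrix(expand.grid(ys, xs))
    upd <- d2 < dist2[box] & mask[box] == 0
    if (any(upd)) {
      dist2[box[upd, , drop = FALSE]] <- d2[upd]
      owner[box[upd, , drop = FALSE]] <- k
    }
  }
  d <- sqrt(dist2)
  d[d > max_px] <- Inf
  owner[!is.finite(d)] <- 0L
  d[on] <- 0
  owner[on] <- mask[on]
  list(distance = d, owner = owner)
}

#' Cytoplasmic sampling rings around nuclei
#'
#' Ring k holds the pixels whose Euclidean distance to nucleus k lies in
#' `(inner_um, outer_um]` (in pixels via the pixel size) and that are
#' closer to nucleus k than to any other nucleus, so rings are pairwise
#' disjoint and disjoint from all nuclei.
#'
#' @param mask integer label mask from [segment_nuclei()].
#' @param pixel_size um per pixel.
#' @param inner_um,outer_um ring radii (default 0.65 and 3.25 um).
#' @return integer label matrix of rings (0 outside); cells whose ring is
#'   empty (crowding or degenerate radii) simply have no pixels.
#' @export
cytoplasm_ring <- function(mask, pixel_size, inner_um = 0.65,
                           outer_um = 3.25) {
  if (outer_um < inner_um) stop("outer_um must be >= inner_um")
  inner_px <- inner_um / pixel_size
  outer_px <- outer_um / pixel_size
  geo <- .nucleus_distance_owner(mask, max_px = outer_px)
  ring <- matrix(0L, nrow(mask), ncol(mask))
  sel <- geo$distance > inner_px & geo$distance <= outer_px & mask == 0
  ring[sel] <- geo$owner[sel]
  ring
}

#' Whole-cell regions by nearest-nucleus expansion
#'
#' Region k is nucleus k plus every pixel within `max_um` of it that is
#' closer to nucleus k than to any other nucleus; regions partition their
#' union.
#'
#' @param mask integer label mask.
#' @param pixel_size um per pixel.
#' @param max_um maximal expansion outside the nuclear mask (default
#'   15.6 um).
#' @return integer label matrix of regions (nucleus included).
#' @export
whole_cell_region <- function(mask, pixel_size, max_um = 15.6) {
  max_px <- max_um / pixel_size
  geo <- .nucleus_distance_owner(mask, max_px = max_px)
  region <- matrix(0L, nrow(mask), ncol(mask))
  sel <- geo$distance <= max_px & mask == 0
  region[sel] <- geo$owner[sel]
  region[mask > 0] <- mask[mask > 0]
  region
}

#' CDK2 activity from a translocation reporter
#'
#' Ratio of the median reporter intensity over the cytoplasmic ring to the
#' mean reporter intensity over the nucleus.
#'
#' @param reporter_channel matrix.
#' @param mask nuclear label mask.
#' @param ring ring label mask from [cytoplasm_ring()].
#' @return data.frame: `cell`, `cdk2_activity`, `nuclear_mean`,
#'   `ring_median`, `reason` (NA unless the value is missing).
#' @export
cdk2_activity <- function(reporter_channel, mask, ring) {
  labs <- sort(unique(mask[mask > 0]))
  out <- data.frame(cell = labs, cdk2_activity = NA_real_,
                    nuclear_mean = NA_real_, ring_median = NA_real_,
                    reason = NA_character_)
  for (i in seq_along(labs)) {
    k <- labs[i]
    nucv <- reporter_channel[mask == k]
    rv <- reporter_channel[ring == k]
    out$nuclear_mean[i] <- mean(nucv)
    if (!length(rv)) { out$reason[i] <- "empty_ring"; next }
    out$ring_median[i] <- stats::median(rv)
    if (!is.finite(out$nuclear_mean[i]) || out$nuclear_mean[i] <= 0) {
      out$reason[i] <- "zero_nuclear_mean"; next
    }
    out$cdk2_activity[i] <- out$ring_median[i] / out$nuclear_mean[i]
  }
  out
}

#' Count FISH foreground pixels per whole-cell region
#'
#' White top-hat filter with a disk kernel (radius `kernel_um`, rounded
#' half away from zero to pixels), absolute-intensity threshold on the
#' filtered image, and per-region count of foreground pixels (pixels, not
#' connected components).
#'
#' @param fish_channel raw FISH matrix.
#' @param region whole-cell region label matrix.
#' @param pixel_size um per pixel.
#' @param kernel_um top-hat kernel radius (default 1.3 um).
#' @param abs_threshold absolute intensity threshold (> 0) applied to the
#'   filtered image.
#' @return data.frame: `cell`, `puncta_pixels`.
#' @export
count_fish_pixels <- function(fish_channel, region, pixel_size,
                              kernel_um = 1.3, abs_threshold) {
  if (missing(abs_threshold) || abs_threshold <= 0)
    stop("abs_threshold must be supplied and > 0")
  r_px <- round_half_up(kernel_um / pixel_size)
  if (r_px < 1) stop("top-hat kernel radius is below 1 px")
  # Euclidean-ball structuring element of radius r_px
  off <- -r_px:r_px
  kern <- 1 * (outer(off^2, off^2, "+") <= r_px^2)
  # EBImage grayscale morphology clips to [0, 1]; rescale around it
  scale <- max(fish_channel, 1e-12)
  th <- scale * as.matrix(
    EBImage::whiteTopHat(EBImage::Image(fish_channel / scale), kern))
  fg <- th > abs_threshold
  labs <- sort(unique(region[region > 0]))
  cnt <- tabulate(region[fg & region > 0], nbins = max(labs, 0))
  data.frame(cell = labs, puncta_pixels = cnt[labs])
}

#' Integer shift registering a moving image onto a reference
#'
#' Cross-correlation via FFT; returns the shift `(dy, dx)` such that the
#' moving image translated by it best overlays the reference (i.e.
#' `moving[y - dy, x - dx]` matches `reference[y, x]`).
#'
#' @param reference_image,moving_image matrices of equal shape.
#' @param min_correlation normalized peak correlation below which the
#'   result is flagged as failed (default 0.2).
#' @return list with `shift` = c(dy, dx), `correlation`, `ok`.
#' @export
register_rounds <- function(reference_image, moving_image,
                            min_correlation = 0.2) {
  stopifnot(all(dim(reference_image) == dim(moving_image)))
  a <- reference_image - mean(reference_image)
  b <- moving_image - mean(moving_image)
  nr <- nrow(a); nc <- ncol(a)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  peak <- which.max(cc)
  py <- (peak - 1) %% nr
  px <- (peak - 1) %/% nr
  dy <- if (py > nr / 2) py - nr else py
  dx <- if (px > nc / 2) px - nc else px
  denom <- sqrt(sum(a^2) * sum(b^2)) * length(a)
  corr <- if (denom > 0) cc[peak] / denom else 0
  list(shift = c(dy = dy, dx = dx), correlation = corr,
       ok = corr >= min_correlation)
}

#' Match fixed-round cells onto live-round labels by shifted centroids
#'
#' @param live_centroids,fixed_centroids matrices with columns x, y.
#' @param shift c(dy, dx) mapping fixed coordinates onto live (from
#'   [register_rounds()] with the live round as reference).
#' @param max_dist maximal matching distance (px, default 10).
#' @return data.frame: `live`, `fixed`, `distance` (unmatched live cells
#'   have NA fixed).
#' @export
match_rounds <- function(live_centroids, fixed_centroids, shift = c(0, 0),
                         max_dist = 10) {
  n <- nrow(live_centroids)
  out <- data.frame(live = seq_len(n), fixed = NA_integer_,
                    distance = NA_real_)
  if (!nrow(fixed_centroids)) return(out)
  fx <- fixed_centroids[, "x"] + shift[2]
  fy <- fixed_centroids[, "y"] + shift[1]
  for (i in seq_len(n)) {
    d <- sqrt((fx - live_centroids[i, "x"])^2 +
              (fy - live_centroids[i, "y"])^2)
    j <- which.min(d)
    if (d[j] <= max_dist) {
      out$fixed[i] <- j
      out$distance[i] <- d[j]
    }
  }
  out
}

#' Quantify one multi-channel frame into per-cell records
#'
#' Runs segmentation on the nuclear channel, builds rings and whole-cell
#' regions, and measures nuclear means for every channel, the CDK2
#' activity ratio, and (if a FISH channel and threshold are given) the
#' puncta pixel count.
#'
#' @param channels named list of matrices; must include `nuclear`.
#' @param pixel_size um per pixel.
#' @param cdk2_channel name of the translocation-reporter channel
#'   (default "cdk2"; NULL to skip).
#' @param fish_channel name of the FISH channel (NULL to skip).
#' @param fish_threshold absolute threshold for FISH foreground.
#' @param bias_field optional illumination bias for [flatfield_correct()],
#'   applied to every channel first.
#' @param background_subtract apply [subtract_background_local()] to every
#'   channel before measuring (default TRUE); a residual background offset
#'   would otherwise bias the cytoplasm/nucleus ratio towards 1.
#' @param ... passed to [segment_nuclei()].
#' @return list with `records` (data.frame, one row per cell), `mask`,
#'   `ring`, `region`.
#' @export
quantify_frame <- function(channels, pixel_size, cdk2_channel = "cdk2",
                           fish_channel = NULL, fish_threshold = NULL,
                           bias_field = NULL, background_subtract = TRUE,
                           ...) {
  stopifnot("nuclear" %in% names(channels))
  if (!is.null(bias_field))
    channels <- lapply(channels, flatfield_correct, bias_field = bias_field)
  if (background_subtract)
    channels <- lapply(channels, subtract_background_local)
  mask <- segment_nuclei(channels$nuclear, ...)
  cents <- attr(mask, "centroids")
  labs <- seq_len(max(mask, 0))
  rec <- data.frame(cell = labs,
                    x = cents[, "x"], y = cents[, "y"],
                    area_px = attr(mask, "areas"))
  for (ch in names(channels)) {
    rec[[paste0("nuc_mean_", ch)]] <-
      vapply(labs, function(k) mean(channels[[ch]][mask == k]), numeric(1))
  }
  ring <- region <- NULL
  if (!is.null(cdk2_channel) && cdk2_channel %in% names(channels)) {
    ring <- cytoplasm_ring(mask, pixel_size)
    act <- cdk2_activity(channels[[cdk2_channel]], mask, ring)
    rec$cdk2_activity <- act$cdk2_activity[match(rec$cell, act$cell)]
  }
  if (!is.null(fish_channel) && fish_channel %in% names(channels)) {
    region <- whole_cell_region(mask, pixel_size)
    cnt <- count_fish_pixels(channels[[fish_channel]], region, pixel_size,
                             abs_threshold = fish_threshold)
    rec$puncta_pixels <- cnt$puncta_pixels[match(rec$cell, cnt$cell)]
  }
  list(records = rec, mask = mask, ring = ring, region = region)
}
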
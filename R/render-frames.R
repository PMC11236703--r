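# Rendering synthetic multi-channel fluorescence frames with truth masks.
#
# Geometry convention: images are numeric matrices indexed [row, col] =
# [y, x], 1-based, with coordinates measured at pixel centres. Channels are
# assigned by pixel centre (a pixel belongs to the nucleus iff its centre
# lies within the disk), so compartment intensities are exact; an optional
# Gaussian PSF is applied to the nuclear-marker and FISH channels only,
# where sub-pixel softness matters for segmentation realism. The
# translocation-reporter channel is left unblurred and its nuclear
# compartment extends 2 px beyond the chromatin disk: the chromatin
# (Hoechst/H2B) mask is biologically smaller than the nuclear envelope, and
# this guard band means a segmentation mask within ~1.5 px of the chromatin
# boundary still samples pure nuclear reporter signal.

#' Place non-overlapping cells in a frame
#'
#' Cells are laid out on a jittered grid so that nuclei (and their
#' cytoplasmic rings) never overlap; positions, radii, intensities and
#' planted CDK2 activities are drawn per cell.
#'
#' @param n_cells number of cells; must fit the grid capacity.
#' @param frame_dim c(rows, cols) in pixels.
#' @param config a [sim_config()] object (nucleus radius, pixel size).
#' @param cdk2_activities optional vector of planted cytoplasm/nucleus
#'   ratios (recycled); default drawn uniform in \[0.4, 1.6\].
#' @param seed integer seed.
#' @return data.frame: `cell`, `x`, `y` (px), `nucleus_radius_px`,
#'   `cyto_radius_px`, `nuclear_intensity`, `cdk2_activity`.
#' @export
place_cells <- function(n_cells, frame_dim = c(512, 512), config = sim_config(),
                        cdk2_activities = NULL, seed = config$seed) {
  set.seed(seed)
  r_px <- config$optics$nucleus_radius_um / config$pixel_size_um
  cyto_px <- r_px + 8 / config$pixel_size_um   # cytoplasm reaches ~8 um out
  pitch <- ceiling(2 * cyto_px + 6)
  margin <- ceiling(cyto_px + 2)
  gx <- seq(margin, frame_dim[2] - margin, by = pitch)
  gy <- seq(margin, frame_dim[1] - margin, by = pitch)
  capacity <- length(gx) * length(gy)
  if (n_cells > capacity)
    stop(sprintf("frame holds at most %d non-overlapping cells", capacity))
  slots <- expand.grid(x = gx, y = gy)
  pick <- slots[sample.int(capacity, n_cells), ]
  jit <- (pitch - 2 * cyto_px - 2) / 2
  act <- if (is.null(cdk2_activities)) stats::runif(n_cells, 0.4, 1.6)
         else rep_len(cdk2_activities, n_cells)
  data.frame(cell = seq_len(n_cells),
             x = round(pick$x + stats::runif(n_cells, -jit, jit)),
             y = round(pick$y + stats::runif(n_cells, -jit, jit)),
             nucleus_radius_px = r_px,
             cyto_radius_px = cyto_px,
             nuclear_intensity = 500 * lnorm_noise(n_cells, 0.15),
             cdk2_activity = act)
}

#' Place FISH spots at integer pixel centres
#'
#' @param n_spots number of spots.
#' @param frame_dim c(rows, cols) px.
#' @param amplitude peak amplitude (a.u.).
#' @param sigma_px Gaussian spot width (px).
#' @param min_sep minimum centre-to-centre separation (px).
#' @param seed integer seed.
#' @return data.frame: `x`, `y`, `amplitude`, `sigma_px`.
#' @export
place_spots <- function(n_spots, frame_dim = c(512, 512), amplitude = 200,
                        sigma_px = 1.2, min_sep = 12, seed = 1L) {
  set.seed(seed)
  margin <- ceiling(4 * sigma_px + min_sep)
  xs <- ys <- integer(0)
  tries <- 0
  while (length(xs) < n_spots && tries < 200 * n_spots) {
    cx <- sample(margin:(frame_dim[2] - margin), 1)
    cy <- sample(margin:(frame_dim[1] - margin), 1)
    if (!length(xs) || all((xs - cx)^2 + (ys - cy)^2 >= min_sep^2)) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
    tries <- tries + 1
  }
  if (length(xs) < n_spots) stop("could not place spots without overlap")
  data.frame(x = xs, y = ys, amplitude = amplitude, sigma_px = sigma_px)
}

# paint values onto img within a disk around (cx, cy); pixel-centre rule
.paint_disk <- function(img, cx, cy, radius, value, replace = TRUE) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- max(1, floor(cx - radius)); x1 <- min(nc, ceiling(cx + radius))
  y0 <- max(1, floor(cy - radius)); y1 <- min(nr, ceiling(cy + radius))
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  sel <- d2 <= radius^2
  block <- img[ys, xs, drop = FALSE]
  if (replace) block[sel] <- value else block[sel] <- block[sel] + value
  img[ys, xs] <- block
  img
}

#' Render multi-channel frames from planted cells
#'
#' Produces a named list of channels (`nuclear`, `cdk2`, `e2f`, `fish`),
#' the ground-truth nuclear label mask, and the vignetting field used.
#' The CDK2-reporter channel is drawn so that the true cytoplasm/nucleus
#' intensity ratio equals each cell's planted activity.
#'
#' @param cells a [place_cells()] table (ground truth).
#' @param config a [sim_config()] object.
#' @param frame_dim c(rows, cols) px.
#' @param spots optional [place_spots()] table for the FISH channel.
#' @param vignetting apply the multiplicative vignetting field (default
#'   FALSE).
#' @param noise apply Poisson shot noise (via `optics$photon_gain`) and
#'   Gaussian read noise (default FALSE).
#' @param psf apply the Gaussian PSF to the nuclear and FISH channels
#'   (default TRUE).
#' @param seed seed for the noise draw.
#' @return list with `channels` (named list of matrices), `mask` (integer
#'   truth label matrix), `vignette` (matrix), `cells`, `spots`.
#' @export
render_frames <- function(cells, config = sim_config(),
                          frame_dim = c(512, 512), spots = NULL,
                          vignetting = FALSE, noise = FALSE, psf = TRUE,
                          seed = config$seed) {
  nr <- frame_dim[1]; nc <- frame_dim[2]
  r_max <- cells$nucleus_radius_px + cells$cyto_radius_px
  if (any(cells$x < 1 | cells$x > nc | cells$y < 1 | cells$y > nr))
    stop("cell centres must lie within the frame")
  blank <- matrix(0, nr, nc)
  nuc_ch <- cdk2_ch <- e2f_ch <- fish_ch <- blank
  mask <- matrix(0L, nr, nc)
  bg <- 10  # dim uniform background so Otsu has two classes

  # pairwise overlap check on chromatin disks
  if (nrow(cells) > 1) {
    dmat <- as.matrix(stats::dist(cells[, c("x", "y")]))
    diag(dmat) <- Inf
    rr <- outer(cells$nucleus_radius_px, cells$nucleus_radius_px, "+")
    if (any(dmat < rr))
      warning("overlapping nuclei in ground truth layout")
  }

  e2f_int <- cells$e2f_intensity %||% rep(300, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    R <- cells$nucleus_radius_px[i]
    I_n <- cells$nuclear_intensity[i]
    nuc_ch <- .paint_disk(nuc_ch, cells$x[i], cells$y[i], R, I_n)
    # reporter: cytoplasm first, nuclear compartment (R + 2 guard) on top
    cdk2_ch <- .paint_disk(cdk2_ch, cells$x[i], cells$y[i],
                           cells$cyto_radius_px[i],
                           I_n * cells$cdk2_activity[i])
    cdk2_ch <- .paint_disk(cdk2_ch, cells$x[i], cells$y[i], R + 2, I_n)
    e2f_ch <- .paint_disk(e2f_ch, cells$x[i], cells$y[i], R, e2f_int[i])
    mask <- .paint_disk(mask, cells$x[i], cells$y[i], R, i)
  }
  if (!is.null(spots)) {
    for (i in seq_len(nrow(spots))) {
      s <- spots$sigma_px[i]
      ext <- ceiling(5 * s)
      xs <- max(1, spots$x[i] - ext):min(nc, spots$x[i] + ext)
      ys <- max(1, spots$y[i] - ext):min(nr, spots$y[i] + ext)
      g <- spots$amplitude[i] *
        exp(-outer((ys - spots$y[i])^2, (xs - spots$x[i])^2, "+") / (2 * s^2))
      fish_ch[ys, xs] <- fish_ch[ys, xs] + g
    }
  }
  nuc_ch <- nuc_ch + bg
  cdk2_ch <- cdk2_ch + bg
  e2f_ch <- e2f_ch + bg

  psf_px <- config$optics$psf_sigma_um / config$pixel_size_um
  if (psf && psf_px > 0.05) {
    nuc_ch <- as.matrix(EBImage::gblur(nuc_ch, sigma = psf_px))
    fish_ch <- as.matrix(EBImage::gblur(fish_ch, sigma = psf_px))
  }

  vig <- matrix(1, nr, nc)
  if (vignetting && config$optics$vignetting_amplitude > 0) {
    cyc <- (nr + 1) / 2; cxc <- (nc + 1) / 2
    r2 <- outer(((seq_len(nr) - cyc))^2, ((seq_len(nc) - cxc))^2, "+")
    vig <- 1 - config$optics$vignetting_amplitude * r2 / max(r2)
  }
  channels <- list(nuclear = nuc_ch * vig, cdk2 = cdk2_ch * vig,
                   e2f = e2f_ch * vig, fish = fish_ch * vig)
  if (noise) {
    set.seed(seed)
    gain <- config$optics$photon_gain
    rn <- config$optics$read_noise_sd
    channels <- lapply(channels, function(ch) {
      if (gain > 0)
        ch <- matrix(stats::rpois(length(ch), lambda = ch * gain) / gain,
                     nrow(ch), ncol(ch))
      if (rn > 0)
        ch <- ch + matrix(stats::rnorm(length(ch), 0, rn), nrow(ch), ncol(ch))
      pmax(ch, 0)
    })
  }
  list(channels = channels, mask = mask, vignette = vig,
       cells = cells, spots = spots)
}

#' Write a rendered frame set as a multi-page TIFF with sidecars
#'
#' One 16-bit page per channel, a CSV truth table and a JSON sidecar of the
#' configuration.
#'
#' @param frames a [render_frames()] result.
#' @param config the [sim_config()] used.
#' @param dir output directory (created if needed).
#' @param name basename for the files.
#' @return invisibly, the paths written.
#' @export
write_frameset <- function(frames, config, dir, name = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- 65535
  pages <- lapply(frames$channels, function(ch) pmin(ch / scale, 1))
  tif <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(pages, tif, bits.per.sample = 16)
  msk <- file.path(dir, paste0(name, "_mask.tif"))
  tiff::writeTIFF(pmin(frames$mask / scale, 1), msk, bits.per.sample = 16)
  csv <- file.path(dir, paste0(name, "_truth.csv"))
  utils::write.csv(frames$cells, csv, row.names = FALSE)
  js <- file.path(dir, paste0(name, "_config.json"))
  jsonlite::write_json(
    list(channel_names = names(frames$channels), intensity_scale = scale,
         config = unclass(config)),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tif = tif, mask = msk, truth = csv, config = js))
}

#' Read a frame set written by [write_frameset()]
#'
#' @param dir directory containing the files.
#' @param name basename used at write time.
#' @return list with `channels`, `mask`, `cells`, `meta`.
#' @export
read_frameset <- function(dir, name = "frame") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, "_config.json")),
                              simplifyVector = TRUE)
  scale <- meta$intensity_scale
  pages <- tiff::readTIFF(file.path(dir, paste0(name, ".tif")), all = TRUE)
  channels <- lapply(pages, function(p) p * scale)
  names(channels) <- meta$channel_names
  mask <- round(tiff::readTIFF(file.path(dir, paste0(name, "_mask.tif"))) *
                  scale)
  storage.mode(mask) <- "integer"
  cells <- utils::read.csv(file.path(dir, paste0(name, "_truth.csv")))
  list(channels = channels, mask = mask, cells = cells, meta = meta)
}
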
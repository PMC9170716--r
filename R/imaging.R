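# Conventions: arrays are indexed [channel, z, y, x]; pixel coordinates are
# (y, x); z indices reported in z_index_map are 0-based; label 0 = background.

#' Construct a multi-channel image stack
#'
#' @param pixels numeric array `[channel, z, y, x]`; channel dimnames
#'   should include `dna`, `actin`, `permeability`.
#' @param pixel_size pixel size in micrometres.
#' @param z_step z-step in micrometres (default 5).
#' @param metadata free-form list (well, field, ...).
#' @return object of class `ImageStack`.
#' @export
image_stack <- function(pixels, pixel_size = 1, z_step = 5,
                        metadata = list()) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 4)
  if (any(pixels < 0)) stop("intensities must be non-negative")
  structure(list(pixels = pixels, pixel_size = pixel_size, z_step = z_step,
                 metadata = metadata),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageStack: %d channel(s) x %d slices x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Illumination correction by flatfield division
#'
#' Divides every z-slice of each channel pixelwise by a per-channel
#' flatfield gain image and renormalizes so the channel's mean intensity
#' is preserved. With `flatfield = "estimate"` a smooth gain surface is
#' estimated per channel from the stack itself (local quadratic trend of
#' the mean z-projection), a single-stack analogue of prospective
#' shading correction.
#'
#' @param stack an [image_stack()].
#' @param flatfield `"estimate"`, or a numeric `y x x` matrix applied to
#'   all channels, or an array `[channel, y, x]`.
#' @return corrected `ImageStack`.
#' @export
correct_illumination <- function(stack, flatfield = "estimate") {
  px <- stack$pixels
  d <- dim(px)
  nch <- d[1]
  get_ff <- function(ch) {
    if (is.character(flatfield) && flatfield == "estimate") {
      avg <- apply(px[ch, , , , drop = FALSE], c(3, 4), mean)
      df <- data.frame(v = as.numeric(avg),
                       y = as.numeric(row(avg)), x = as.numeric(col(avg)))
      fit <- stats::loess(v ~ y + x, data = df, degree = 2, span = 1,
                          normalize = FALSE)
      ff <- matrix(stats::predict(fit, df), d[3], d[4])
      ff <- pmax(ff, 1e-8)
      ff / mean(ff)
    } else if (is.matrix(flatfield)) {
      flatfield
    } else if (is.array(flatfield) && length(dim(flatfield)) == 3) {
      flatfield[ch, , ]
    } else stop("unsupported flatfield specification")
  }
  out <- px
  for (ch in seq_len(nch)) {
    ff <- get_ff(ch)
    if (!all(dim(ff) == d[3:4])) stop("flatfield shape mismatch")
    if (any(ff <= 0)) stop("flatfield gain must be strictly positive")
    old_mean <- mean(px[ch, , , ])
    for (z in seq_len(d[2])) out[ch, z, , ] <- px[ch, z, , ] / ff
    new_mean <- mean(out[ch, , , ])
    if (new_mean > 0) out[ch, , , ] <- out[ch, , , ] * (old_mean / new_mean)
  }
  image_stack(out, pixel_size = stack$pixel_size, z_step = stack$z_step,
              metadata = stack$metadata)
}

# local (population) variance of a matrix in a w x w window, truncated at
# image borders: per pixel, variance over the in-image neighbours.
local_variance <- function(m, window) {
  r <- (window - 1L) %/% 2L
  ny <- nrow(m); nx <- ncol(m)
  s <- matrix(0, ny, nx); s2 <- matrix(0, ny, nx); cnt <- matrix(0, ny, nx)
  for (dy in -r:r) {
    ys <- max(1, 1 + dy):min(ny, ny + dy)   # target rows
    yo <- ys - dy                            # source rows
    for (dx in -r:r) {
      xs <- max(1, 1 + dx):min(nx, nx + dx)
      xo <- xs - dx
      s[ys, xs] <- s[ys, xs] + m[yo, xo]
      s2[ys, xs] <- s2[ys, xs] + m[yo, xo]^2
      cnt[ys, xs] <- cnt[ys, xs] + 1
    }
  }
  mu <- s / cnt
  pmax(s2 / cnt - mu^2, 0)
}

#' Maximum-contrast projection of a z-stack
#'
#' Projects a multi-channel 3D stack onto a plane by retaining, per
#' channel and per pixel, the value from the z-slice with the strongest
#' local contrast. Contrast is the intensity variance in the
#' `window x window` neighbourhood of that pixel within the slice
#' (truncated at image borders); ties are broken toward the lowest z.
#' The slice of origin of every projected pixel is recorded (0-based).
#'
#' @param stack an [image_stack()].
#' @param window odd neighbourhood width in pixels (default 3).
#' @return object of class `ProjectedImage`: list with `pixels`
#'   (`[channel, y, x]`) and `z_index_map` (`[channel, y, x]`, 0-based).
#' @export
max_contrast_project <- function(stack, window = 3) {
  if (window %% 2 == 0 || window < 1) stop("window must be odd and >= 1")
  px <- stack$pixels
  d <- dim(px)
  if (window > min(d[3], d[4])) stop("window exceeds image extent")
  chans <- dimnames(px)[[1]]
  proj <- array(0, dim = d[c(1, 3, 4)], dimnames = list(chans, NULL, NULL))
  zmap <- array(0L, dim = d[c(1, 3, 4)], dimnames = list(chans, NULL, NULL))
  for (ch in seq_len(d[1])) {
    best <- matrix(-Inf, d[3], d[4])
    for (z in seq_len(d[2])) {
      sl <- matrix(px[ch, z, , ], d[3], d[4])
      v <- local_variance(sl, window)
      take <- v > best            # strict: first max wins -> lowest z
      best[take] <- v[take]
      pz <- matrix(proj[ch, , ], d[3], d[4])
      mz <- matrix(zmap[ch, , ], d[3], d[4])
      pz[take] <- sl[take]
      mz[take] <- z - 1L
      proj[ch, , ] <- pz
      zmap[ch, , ] <- mz
    }
  }
  structure(list(pixels = proj, z_index_map = zmap,
                 pixel_size = stack$pixel_size, metadata = stack$metadata),
            class = "ProjectedImage")
}

#' @export
print.ProjectedImage <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ProjectedImage: %d channel(s) x %d x %d px\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Intensity-based organoid segmentation with watershed splitting
#'
#' Foreground is an automatic (Otsu) threshold on a Gaussian-smoothed
#' composite of the DNA and actin channels; touching organoids are split
#' by a distance-transform watershed whose seeds are local maxima of the
#' distance map separated by at least `min_seed_distance`. Labels are
#' re-compacted to contiguous positive integers.
#'
#' @param img a `ProjectedImage` with `dna` and `actin` channels.
#' @param smoothing_sd Gaussian smoothing sd in pixels (default 2).
#' @param threshold_method `"otsu"` (default) or a numeric threshold on
#'   the normalized composite.
#' @param min_seed_distance minimum distance between watershed seeds in
#'   pixels (default 5).
#' @return `LabelMask`: integer matrix (y, x); 0 = background.
#' @export
segment_organoids <- function(img, smoothing_sd = 2,
                              threshold_method = "otsu",
                              min_seed_distance = 5) {
  chans <- dimnames(img$pixels)[[1]]
  if (!all(c("dna", "actin") %in% chans))
    stop("projected image must have dna and actin channels")
  comp <- img$pixels["dna", , ] + img$pixels["actin", , ]
  rng <- range(comp)
  if (rng[2] - rng[1] < 1e-12) {
    if (rng[1] > 0.5) {          # saturated everywhere
      warning("all-saturated image: returning a single component")
      return(matrix(1L, nrow(comp), ncol(comp)))
    }
    return(matrix(0L, nrow(comp), ncol(comp)))
  }
  comp <- (comp - rng[1]) / (rng[2] - rng[1])
  eb <- EBImage::Image(t(comp))  # EBImage uses (x, y)
  if (smoothing_sd > 0) eb <- EBImage::gblur(eb, sigma = smoothing_sd)
  thr <- if (identical(threshold_method, "otsu"))
    EBImage::otsu(eb, range = c(0, 1)) else as.numeric(threshold_method)
  bin <- eb > thr
  if (sum(bin) == 0) return(matrix(0L, nrow(comp), ncol(comp)))
  dm <- EBImage::distmap(bin)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = max(1L, as.integer(min_seed_distance)))
  mask <- t(EBImage::imageData(ws))
  relabel_mask(mask)
}

# re-compact labels to 1..K preserving order of first appearance
relabel_mask <- function(mask) {
  labs <- sort(unique(as.integer(mask[mask > 0])))
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_along(labs)) out[mask == labs[i]] <- i
  out
}

#' Remove small segmented objects
#'
#' Removes every labelled object whose pixel area is less than or equal
#' to `max_removed_area` (area 301 is retained at the default 300), the
#' model-free outlier rule separating organoids from debris. Remaining
#' labels are re-compacted; surviving objects' pixels are untouched.
#'
#' @param mask integer `LabelMask`.
#' @param max_removed_area objects with area <= this are removed
#'   (default 300).
#' @return filtered `LabelMask`.
#' @export
filter_small_objects <- function(mask, max_removed_area = 300) {
  if (max_removed_area < 0) stop("max_removed_area must be >= 0")
  if (all(mask == 0)) return(mask)
  areas <- tabulate(mask[mask > 0])
  drop <- which(areas > 0 & areas <= max_removed_area)
  out <- mask
  out[out %in% drop] <- 0L
  relabel_mask(out)
}
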
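#' Synthetic ground-truth sections
#'
#' Generates digitized two-color vertical sections with known pattern
#' metrics, so the metric pipeline can be validated without any microscopy
#' data.  Three canonical patterns are provided:
#'
#' * `columnar`: alternating single-color columns (fully segregated);
#'   intermixing index 0 and patch size equal to the height.
#' * `layered`: one horizontal interface in every column; intermixing
#'   index 1.
#' * `periodic_intermixed`: horizontal layers of thickness `lambda`
#'   alternating up each column; `lambda` must divide the height so the
#'   closed forms are exact: IM `= h/lambda - 1` and patch size
#'   `-> lambda`.
#'
#' @param pattern one of `"columnar"`, `"layered"`, `"periodic_intermixed"`.
#' @param width,height section size in pixels.
#' @param lambda layer thickness in pixels (periodic pattern).
#' @param pixel_size pixel edge in micrometres.
#' @return a list with `section` (a `section_image`) and `expected` (a data
#'   frame with `im`, `patch_size`, `height`).
#' @examples
#' fx <- make_section("periodic_intermixed", width = 20, height = 40,
#'                    lambda = 4)
#' fx$expected$im  # 9
#' @export
make_section <- function(pattern = c("columnar", "layered",
                                     "periodic_intermixed"),
                         width = 50, height = 40, lambda = 4,
                         pixel_size = 1) {
  pattern <- match.arg(pattern)
  stopifnot(width >= 1, height >= 1, lambda >= 1)
  m <- switch(pattern,
    columnar = {
      cols <- rep(c(1L, -1L), length.out = width)
      matrix(rep(cols, height), width, height)
    },
    layered = {
      half <- height %/% 2
      if (half == 0) stop("layered pattern needs height >= 2")
      t(matrix(rep(c(rep(1L, half), rep(-1L, height - half)), width),
               height, width))
    },
    periodic_intermixed = {
      if (height %% lambda != 0)
        stop("lambda must divide height so the expected metrics are exact")
      zcol <- rep(rep(c(1L, -1L), each = lambda),
                  length.out = height)
      t(matrix(rep(zcol, width), height, width))
    })
  expected <- switch(pattern,
    columnar = data.frame(im = 0, patch_size = height * pixel_size,
                          height = height * pixel_size),
    layered = data.frame(im = 1,
                         patch_size = pixel_size * height^2 / (2 * height),
                         height = height * pixel_size),
    periodic_intermixed = data.frame(im = height / lambda - 1,
                                     patch_size = lambda * pixel_size,
                                     height = height * pixel_size))
  list(section = section_from_matrix(m, pixel_size), expected = expected)
}

#' Render a digitized section as two noisy fluorescence channels
#'
#' The inverse of [digitize()]: +1 pixels are bright in the green channel,
#' -1 in the red channel, 0 pixels carry only background; Gaussian noise of
#' standard deviation `noise_sigma * signal` is added to both channels (and
#' to the background, emulating detector noise).
#'
#' @param section a `section_image`.
#' @param noise_sigma relative noise level (fraction of the signal level).
#' @param background background intensity (default 100).
#' @param signal signal intensity of a labeled pixel (default 1000).
#' @return list with `channel_r` and `channel_g` intensity matrices.
#' @export
render_channels <- function(section, noise_sigma = 0, background = 100,
                            signal = 1000) {
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  f <- unclass(section)
  g <- matrix(background, nrow(f), ncol(f))
  r <- matrix(background, nrow(f), ncol(f))
  g[f == 1] <- signal
  r[f == -1] <- signal
  if (noise_sigma > 0) {
    g <- g + stats::rnorm(length(g), 0, noise_sigma * signal)
    r <- r + stats::rnorm(length(r), 0, noise_sigma * signal)
    g[g < 0] <- 0
    r[r < 0] <- 0
  }
  list(channel_r = r, channel_g = g)
}

#' Initial cell layouts
#'
#' Random uniform surface inoculation (the default used throughout the
#' simulations) or a dense circular inoculation spot of given area filled
#' to a number of cell layers, for center-versus-edge experiments.
#'
#' @param dims lattice dimensions `c(X, Y, Z)`.
#' @param density cells/mm^2 (random arrangement).
#' @param ratio per-population relative abundances.
#' @param arrangement `"random"` or `"spot"`.
#' @param spot_area_mm2 area of the inoculation spot (default 2 mm^2).
#' @param spot_layers filled depth of the spot in cell layers (default 10).
#' @param site_size site edge (um).
#' @return a [cell_lattice()].
#' @export
make_initial_layout <- function(dims, density = 500, ratio = c(1, 1),
                                arrangement = c("random", "spot"),
                                spot_area_mm2 = 2, spot_layers = 10,
                                site_size = 5) {
  arrangement <- match.arg(arrangement)
  if (arrangement == "random")
    return(seed_lattice(dims, density, ratio, site_size))
  lat <- cell_lattice(dims, site_size)
  radius_sites <- sqrt(spot_area_mm2 / pi) * 1000 / site_size
  cx <- (dims[1] + 1) / 2
  cy <- (dims[2] + 1) / 2
  xy <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
  inside <- (xy$x - cx)^2 + (xy$y - cy)^2 <= radius_sites^2
  if (!any(inside)) stop("spot smaller than one site")
  if (spot_layers > dims[3]) stop("spot deeper than the lattice")
  n_in <- sum(inside)
  p <- ratio / sum(ratio)
  for (z in seq_len(spot_layers)) {
    pops <- sample(seq_along(p), n_in, replace = TRUE, prob = p)
    plane <- integer(prod(dims[1:2]))
    plane[which(inside)] <- pops
    lat$sites[, , z] <- plane
  }
  lat
}

#' Write a set of reference fixtures to disk
#'
#' Writes PNG channel pairs for the three canonical patterns together with
#' a manifest CSV of their expected metrics; the round trip through
#' [digitize()] and the pattern metrics is the package's primary
#' regression surface.
#'
#' @param dir output directory.
#' @param width,height fixture size (pixels).
#' @param lambda layer thickness for the periodic fixture.
#' @param noise_sigma relative channel noise.
#' @return the manifest data frame (invisibly).
#' @export
make_fixtures <- function(dir, width = 50, height = 40, lambda = 4,
                          noise_sigma = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(c("columnar", "layered", "periodic_intermixed"),
                 function(p) {
    fx <- make_section(p, width, height, lambda)
    ch <- render_channels(fx$section, noise_sigma)
    png::writePNG(t(ch$channel_r / max(ch$channel_r)),
                  file.path(dir, paste0(p, "_red.png")))
    png::writePNG(t(ch$channel_g / max(ch$channel_g)),
                  file.path(dir, paste0(p, "_green.png")))
    cbind(pattern = p, fx$expected)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
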
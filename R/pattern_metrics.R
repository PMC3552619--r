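#' Digitize a two-channel vertical-section image
#'
#' Converts a pair of fluorescence intensity images (red and green channels
#' of the same vertical cross-section) into a digitized section f(x, z) with
#' values +1 (population 1, green), -1 (population 2, red) and 0 (no
#' signal).  Pixels with both channels below `(1 + no_signal_frac)` times
#' the channel background are no-signal.  The remaining pixels are
#' normalized per channel by the channel's 90th-percentile intensity over
#' signal pixels and labeled by the larger normalized value; exact ties map
#' to 0 for determinism.
#'
#' @param channel_r,channel_g numeric intensity matrices of equal shape,
#'   rows = lateral position, columns = z with column 1 at the surface.
#'   Intensities are assumed comparable per unit exposure time.
#' @param background per-channel background levels `c(red, green)`, or
#'   `"auto"` to estimate each as the mode of the rounded intensities.
#' @param no_signal_frac no-signal threshold as a fraction above background
#'   (default 0.15, the middle of the 10--20% range).
#' @param pixel_size pixel edge in micrometres.
#' @return a `section_image` (+1/-1/0 matrix).
#' @export
digitize <- function(channel_r, channel_g, background = "auto",
                     no_signal_frac = 0.15, pixel_size = 5) {
  stopifnot(all(dim(channel_r) == dim(channel_g)))
  if (identical(background, "auto"))
    background <- c(intensity_mode(channel_r), intensity_mode(channel_g))
  thr <- (1 + no_signal_frac) * background
  signal <- channel_r >= thr[1] | channel_g >= thr[2]
  out <- matrix(0L, nrow(channel_r), ncol(channel_r))
  if (!any(signal)) {
    warning("image is all background; returning an all-zero section")
  } else {
    p90_r <- stats::quantile(channel_r[signal], 0.9, names = FALSE)
    p90_g <- stats::quantile(channel_g[signal], 0.9, names = FALSE)
    nr <- channel_r / p90_r
    ng <- channel_g / p90_g
    # a pixel can only take a color whose own channel is above threshold;
    # exact ties between two above-threshold channels stay 0
    above_r <- channel_r >= thr[1]
    above_g <- channel_g >= thr[2]
    out[signal & above_g & (!above_r | ng > nr)] <- 1L
    out[signal & above_r & (!above_g | nr > ng)] <- -1L
  }
  structure(out, pixel_size = pixel_size, encoding = "signed",
            class = c("section_image", "matrix", "array"))
}

intensity_mode <- function(x) {
  tab <- table(round(as.numeric(x)))
  as.numeric(names(tab)[which.max(tab)])
}

signed_section <- function(section, pair = NULL) {
  enc <- attr(section, "encoding")
  if (!is.null(enc) && enc == "ids") {
    if (is.null(pair))
      stop("a multi-population section needs a `pair` of population ids")
    return(pairwise_view(section, pair))
  }
  if (is.null(enc) && !all(section %in% c(-1L, 0L, 1L)))
    stop("section values must be in {-1, 0, +1}")
  section
}

#' Per-column local heights and color-change counts
#'
#' For each lateral position x of a digitized section, `h(x)` is one plus
#' the z-index of the topmost nonzero pixel (0 for an empty column) and
#' `c(x)` is the number of sign alternations along the column read from the
#' surface up, with zero pixels skipped: an internal gap does not itself
#' count as a change, and internal gaps still count toward the height.
#'
#' @param section a digitized `section_image` (values in `{-1, 0, +1}`).
#' @param pair for a multi-population section, the two population ids to
#'   compare (others become no-signal).
#' @return a data frame with columns `x`, `h` (pixels), `c`.
#' @examples
#' s <- section_from_matrix(matrix(c(1, 0, -1, 0, 0, -1), nrow = 1))
#' column_stats(s)  # h = 6, c = 1
#' @export
column_stats <- function(section, pair = NULL) {
  f <- signed_section(section, pair)
  n <- nrow(f)
  h <- integer(n)
  cc <- integer(n)
  for (i in seq_len(n)) {
    v <- f[i, ]
    nz <- which(v != 0)
    if (length(nz) == 0) next
    h[i] <- max(nz)
    s <- v[nz]
    cc[i] <- sum(s[-1] != s[-length(s)])
  }
  data.frame(x = seq_len(n), h = h, c = cc)
}

#' Intermixing index of a vertical cross-section
#'
#' The height-weighted mean number of cell-type transitions along the
#' vertical columns of a section:
#' \deqn{IM = \frac{\sum_x c(x)\,h(x)}{\sum_x h(x)}}
#' Segregated columnar patterns give 0, a single layered interface gives 1,
#' and successive patches accumulating on top of each other give large
#' values.  Taller columns get more weight since they have gone through more
#' interaction-regulated growth.
#'
#' @inheritParams column_stats
#' @return the dimensionless intermixing index.
#' @examples
#' s <- section_from_matrix(rbind(c(1, -1, 1, -1), c(1, 1, -1, -1)))
#' intermixing_index(s)
#' @export
intermixing_index <- function(section, pair = NULL) {
  st <- column_stats(section, pair)
  if (sum(st$h) == 0) stop("empty section: intermixing index is undefined")
  sum(st$c * st$h) / sum(st$h)
}

#' Characteristic vertical patch size of a section
#'
#' The height-weighted mean vertical extent of single-type patches:
#' \deqn{\lambda_z^* = \frac{\sum_x h(x)^2 / [1 + c(x)]}{\sum_x h(x)}}
#' in micrometres when the section carries a pixel size (pixels otherwise).
#'
#' @inheritParams column_stats
#' @export
patch_size <- function(section, pair = NULL) {
  st <- column_stats(section, pair)
  if (sum(st$h) == 0) stop("empty section: patch size is undefined")
  px <- attr(section, "pixel_size")
  if (is.null(px)) px <- 1
  px * sum(st$h^2 / (1 + st$c)) / sum(st$h)
}

#' Community height of a section or lattice
#'
#' The value below which 90% of the local column heights fall (linear
#' interpolation percentile), which excludes artifacts such as isolated
#' height spikes.
#'
#' @param x a `section_image`, a list of sections, or a [cell_lattice()].
#' @param pair passed to [column_stats()] for multi-population sections.
#' @return height in micrometres when a pixel/site size is known, else in
#'   pixels.
#' @export
community_height <- function(x, pair = NULL) {
  if (inherits(x, "cell_lattice")) {
    h <- as.numeric(column_heights(x))
    px <- x$site_size
  } else {
    if (inherits(x, "section_image")) x <- list(x)
    h <- unlist(lapply(x, function(s) column_stats(s, pair)$h))
    px <- attr(x[[1]], "pixel_size")
    if (is.null(px)) px <- 1
  }
  if (length(h) == 0 || all(h == 0)) stop("empty input: height is undefined")
  px * stats::quantile(h, 0.9, names = FALSE)
}

#' Linearly normalize an intermixing index to a reference height
#'
#' Since the intermixing index of a cooperative community grows in
#' proportion to community height, indexes measured at different heights are
#' compared after linear rescaling to a common reference height.
#'
#' @param im intermixing index.
#' @param height community height at which `im` was measured.
#' @param reference_height target height, in the same units (default 40 cell
#'   layers expressed in those units).
#' @export
normalize_im <- function(im, height, reference_height = 40) {
  if (any(height <= 0)) stop("height must be positive")
  im * reference_height / height
}

#' Reduce a multi-population section to a two-color view
#'
#' Pixels of population `pair[1]` map to +1, `pair[2]` to -1, and all other
#' populations to no-signal, so two focal colors are analyzed at a time.
#'
#' @param section a `section_image` with `ids` encoding (or any id matrix).
#' @param pair two distinct population ids.
#' @export
pairwise_view <- function(section, pair) {
  stopifnot(length(pair) == 2, pair[1] != pair[2])
  enc <- attr(section, "encoding")
  if (!is.null(enc) && enc == "signed") {
    # already two-color: +1 is population 1, -1 is population 2
    if (!all(sort(pair) == c(1, 2))) stop("unknown population id")
    if (pair[1] == 1) return(section)
    m <- -unclass(section)
    return(structure(m, pixel_size = attr(section, "pixel_size"),
                     encoding = "signed", class = class(section)))
  }
  ids <- unclass(section)
  present <- setdiff(unique(abs(as.integer(ids))), 0L)
  if (length(present) > 0 && !any(pair %in% present))
    stop("neither population id occurs in the section")
  m <- matrix(0L, nrow(ids), ncol(ids))
  m[ids == pair[1]] <- 1L
  m[ids == pair[2]] <- -1L
  structure(m, pixel_size = attr(section, "pixel_size"), encoding = "signed",
            class = c("section_image", "matrix", "array"))
}

#' Summarize a section
#'
#' @inheritParams column_stats
#' @return a one-row data frame with `im`, `patch_size`, `height` (the
#'   90th-percentile community height) and `width` (pixels).
#' @export
analyze_section <- function(section, pair = NULL) {
  data.frame(im = intermixing_index(section, pair),
             patch_size = patch_size(section, pair),
             height = community_height(section, pair = pair),
             width = nrow(section))
}

#' Tile a section into fixed-width analysis units
#'
#' Splits a wide section into non-overlapping windows of `window_width`
#' micrometres (default 0.7 mm, one camera field of view) and summarizes
#' each window independently; a partial trailing window is dropped.
#'
#' @inheritParams column_stats
#' @param window_width window width in micrometres (default 700).
#' @return a data frame with one row per window (columns of
#'   [analyze_section()] plus `window`).
#' @export
tile_analysis_units <- function(section, window_width = 700, pair = NULL) {
  px <- attr(section, "pixel_size")
  if (is.null(px)) px <- 1
  wpix <- floor(window_width / px)
  if (wpix < 1) stop("window narrower than one pixel")
  n <- nrow(section)
  nwin <- max(1L, n %/% wpix)
  if (n < wpix) nwin <- 1L
  out <- lapply(seq_len(nwin), function(w) {
    rows <- if (n < wpix) seq_len(n) else ((w - 1) * wpix + 1):(w * wpix)
    sub <- structure(unclass(section)[rows, , drop = FALSE],
                     pixel_size = px, encoding = attr(section, "encoding"),
                     class = class(section))
    cbind(window = w, analyze_section(sub, pair))
  })
  do.call(rbind, out)
}

#' Wrap a plain matrix as a digitized section
#'
#' @param m matrix with values in `{-1, 0, +1}` (rows = lateral position,
#'   columns = z, column 1 at the surface).
#' @param pixel_size pixel edge in micrometres (default 1: pixel units).
#' @export
section_from_matrix <- function(m, pixel_size = 1) {
  if (!all(m %in% c(-1, 0, 1))) stop("values must be in {-1, 0, +1}")
  structure(matrix(as.integer(m), nrow(m), ncol(m)),
            pixel_size = pixel_size, encoding = "signed",
            class = c("section_image", "matrix", "array"))
}

#' Export a section as an indexed PNG image
#'
#' Green for +1, red for -1 (or a palette for id-encoded sections), black
#' background; the image is written with z increasing upward.
#'
#' @param section a `section_image`.
#' @param path output PNG file.
#' @export
export_section_png <- function(section, path) {
  img <- section_to_rgb(section)
  png::writePNG(img, path)
  invisible(path)
}

#' Export sections as a multi-page TIFF
#'
#' @param sections a `section_image` or list of them.
#' @param path output TIFF file.
#' @export
export_section_tiff <- function(sections, path) {
  if (inherits(sections, "section_image")) sections <- list(sections)
  tiff::writeTIFF(lapply(sections, section_to_rgb), path)
  invisible(path)
}

section_to_rgb <- function(section) {
  m <- t(unclass(section))[rev(seq_len(ncol(section))), , drop = FALSE]
  img <- array(0, dim = c(nrow(m), ncol(m), 3))
  enc <- attr(section, "encoding")
  if (is.null(enc) || enc == "signed") {
    img[, , 1][m == -1] <- 1
    img[, , 2][m == 1] <- 1
  } else {
    pal <- grDevices::rainbow(max(abs(m), 1))
    for (k in seq_along(pal)) {
      rgbk <- grDevices::col2rgb(pal[k]) / 255
      for (ch in 1:3) img[, , ch][abs(m) == k] <- rgbk[ch]
    }
  }
  img
}
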
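#' Create an empty cell lattice
#'
#' The shared 3D occupancy grid used by both simulators.  Sites are cubes of
#' `site_size` micrometres; the grid is periodic in x and y and `z = 1` is the
#' colonization surface.  Each site holds at most one cell, encoded as a
#' signed population code: `0` empty, `+k` a live cell of population `k`,
#' `-k` a dead cell of population `k` (diffusion model only).  After any
#' public operation no occupied site has an empty site below it in the same
#' column.
#'
#' @param dims integer vector `c(X, Y, Z)` of site counts.
#' @param site_size edge length of one site in micrometres (a cell diameter).
#' @return An object of class `cell_lattice`.
#' @examples
#' lat <- cell_lattice(c(20, 20, 30))
#' live_cell_count(lat)
#' @export
cell_lattice <- function(dims, site_size = 5) {
  stopifnot(length(dims) == 3, all(dims >= 1))
  structure(
    list(sites = array(0L, dim = as.integer(dims)),
         site_size = site_size),
    class = "cell_lattice")
}

as_cell_lattice <- function(sites, site_size = 5) {
  stopifnot(length(dim(sites)) == 3)
  structure(list(sites = sites, site_size = site_size),
            class = "cell_lattice")
}

#' @export
print.cell_lattice <- function(x, ...) {
  d <- dim(x$sites)
  cat(sprintf("<cell_lattice %d x %d x %d sites (%g um each): %d live, %d dead>\n",
              d[1], d[2], d[3], x$site_size,
              sum(x$sites > 0), sum(x$sites < 0)))
  invisible(x)
}

#' @export
dim.cell_lattice <- function(x) dim(x$sites)

#' Number of live cells on a lattice
#' @param lattice a [cell_lattice()].
#' @param population optional population id to count; default all.
#' @export
live_cell_count <- function(lattice, population = NULL) {
  s <- lattice$sites
  if (is.null(population)) sum(s > 0L) else sum(s == population)
}

#' Per-column community heights
#'
#' The local height `h(x,y)` is one plus the z-index of the topmost occupied
#' site (live or dead) of each column, or 0 for an empty column.
#'
#' @param lattice a [cell_lattice()].
#' @return an X-by-Y integer matrix of heights in cell layers.
#' @export
column_heights <- function(lattice) {
  s <- lattice$sites != 0L
  d <- dim(s)
  zmat <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  apply(zmat * s, c(1, 2), max)
}

#' Occupancy fractions in the cubic interaction neighborhood
#'
#' For each population `i` the fraction `phi_i` of sites in the cubic
#' three-axial neighborhood of halfwidth `l` around `site` that are occupied
#' by live cells of `i`.  The cube extends `l` sites left/right/front/back/
#' above/below, wraps in x and y, and is clipped at the z bounds; the
#' denominator is the clipped cube size, and the focal cell itself counts.
#'
#' @param lattice a [cell_lattice()].
#' @param site integer `c(x, y, z)`, 1-based.
#' @param l interaction halfwidth in sites (default 3).
#' @param npop number of populations; defaults to the largest code present.
#' @return numeric vector of fractions with attribute `cube_sites`.
#' @export
occupancy_fractions <- function(lattice, site, l = 3, npop = NULL) {
  stopifnot(l >= 1)
  if (is.null(npop)) npop <- max(abs(lattice$sites), 1L)
  occ_fractions_cpp(lattice$sites, site[1], site[2], site[3], as.integer(l),
                    as.integer(npop))
}

#' Nearest empty coplanar site within the confinement radius
#'
#' Finds an empty site in the same z-plane within Euclidean distance `n`
#' (x,y wrapped) of an occupied focal site; among equidistant candidates the
#' choice is uniform at random.  Returns `NULL` when the confinement
#' neighborhood is fully occupied.
#'
#' @inheritParams occupancy_fractions
#' @param n confinement radius in sites (default 2).
#' @return integer `c(x, y, z)` or `NULL`.
#' @export
nearest_empty_coplanar <- function(lattice, site, n = 2) {
  stopifnot(n >= 1)
  res <- nearest_empty_cpp(lattice$sites, site[1], site[2], site[3],
                           as.integer(n))
  if (length(res) == 0) NULL else res
}

#' Place a daughter cell next to its mother
#'
#' With a coplanar empty `target` (as returned by
#' [nearest_empty_coplanar()]), cells along the straight lattice path from
#' mother to target each shift one step toward the target and the daughter
#' takes the site adjacent to the mother on that path; a shifted cell left
#' unsupported is lowered until it lands on another cell or the surface.
#' With `target = NULL` (full confinement) the mother's column above her
#' shifts up one site and the daughter is placed directly above the mother.
#' A push-up beyond the lattice top is an error.
#'
#' @inheritParams occupancy_fractions
#' @param mother occupied site `c(x, y, z)`.
#' @param target empty coplanar site or `NULL`.
#' @return the updated `cell_lattice`, with attribute `daughter` giving the
#'   daughter's site.
#' @export
place_daughter <- function(lattice, mother, target = NULL) {
  res <- place_daughter_cpp(lattice$sites, as.integer(mother),
                            if (is.null(target)) NULL else as.integer(target))
  out <- as_cell_lattice(res$lattice, lattice$site_size)
  attr(out, "daughter") <- res$daughter
  out
}

#' Check the gravity invariant
#'
#' Full scan asserting that below every occupied site all sites of the same
#' column down to the surface are occupied.
#'
#' @param lattice a [cell_lattice()].
#' @return `TRUE` (invisibly) or an error describing the floating cell.
#' @export
validate_lattice <- function(lattice) {
  s <- lattice$sites != 0L
  d <- dim(s)
  if (d[3] > 1) {
    for (z in 2:d[3]) {
      bad <- s[, , z] & !s[, , z - 1]
      if (any(bad)) {
        w <- which(bad, arr.ind = TRUE)[1, ]
        stop(sprintf("floating cell at (%d,%d,%d)", w[1], w[2], z))
      }
    }
  }
  invisible(TRUE)
}

#' Extract digitized vertical cross-sections
#'
#' Cuts single-cell-thick (or thicker) vertical sections perpendicular to
#' `axis` and digitizes them as f(x, z) matrices.  With two populations the
#' encoding is +1 (population 1), -1 (population 2), 0 (no cell); with more
#' populations the matrix holds population ids and [pairwise_view()] reduces
#' it to a two-color section.  Dead cells keep their population color.
#' Consecutive returned sections are at least `min_separation` sections
#' apart, which de-correlates sections sampled from the same community.
#'
#' @param lattice a [cell_lattice()].
#' @param axis `"y"` (default) to cut planes of constant y, or `"x"`.
#' @param thickness section thickness in sites; thicker sections are
#'   collapsed by majority vote per pixel (default 1, single-cell thickness).
#' @param min_separation minimum number of sections between consecutive
#'   samples (default 7).
#' @return a list of `section_image` matrices (rows = lateral position,
#'   columns = z) with attributes `pixel_size` and `encoding`.
#' @export
vertical_sections <- function(lattice, axis = c("y", "x"), thickness = 1,
                              min_separation = 7) {
  axis <- match.arg(axis)
  d <- dim(lattice$sites)
  nslice <- if (axis == "y") d[2] else d[1]
  if (thickness < 1 || thickness > nslice)
    stop("thickness must be between 1 and the lattice width")
  npop <- max(abs(lattice$sites), 1L)
  starts <- seq(1, nslice - thickness + 1, by = min_separation + thickness)
  lapply(starts, function(s0) {
    sl <- s0:(s0 + thickness - 1)
    slab <- if (axis == "y") lattice$sites[, sl, , drop = FALSE] else
      aperm(lattice$sites[sl, , , drop = FALSE], c(2, 1, 3))
    m <- apply(abs(slab), c(1, 3), function(v) {
      v <- v[v != 0L]
      if (length(v) == 0) 0L else as.integer(names(which.max(table(v))))
    })
    section_image(m, pixel_size = lattice$site_size,
                  encoding = if (npop <= 2) "signed" else "ids")
  })
}

section_image <- function(m, pixel_size = 5, encoding = c("signed", "ids")) {
  encoding <- match.arg(encoding)
  if (encoding == "signed" && any(m > 2))
    stop("signed encoding requires at most two populations")
  if (encoding == "signed") {
    m <- ifelse(m == 1L, 1L, ifelse(m == 2L, -1L, 0L))
  }
  structure(m, pixel_size = pixel_size, encoding = encoding,
            class = c("section_image", class(m)))
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image %d x %d pixels (%g um), %s encoding>\n",
              nrow(x), ncol(x), attr(x, "pixel_size"), attr(x, "encoding")))
  invisible(x)
}

#' Write a lattice to a plain-text site list
#'
#' Serializes the occupied sites as a CSV of `x,y,z,code` rows (signed
#' population codes), with the dimensions and site size in header comments.
#'
#' @param lattice a [cell_lattice()].
#' @param path output file.
#' @export
write_lattice_csv <- function(lattice, path) {
  d <- dim(lattice$sites)
  occ <- which(lattice$sites != 0L, arr.ind = TRUE)
  df <- data.frame(x = occ[, 1], y = occ[, 2], z = occ[, 3],
                   code = lattice$sites[occ])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dims %d %d %d", d[1], d[2], d[3]),
               sprintf("# site_size %g", lattice$site_size),
               "x,y,z,code"), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a lattice written by [write_lattice_csv()]
#' @param path file written by [write_lattice_csv()].
#' @return a [cell_lattice()].
#' @export
read_lattice_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  dims <- as.integer(strsplit(sub("# dims ", "", hdr[1]), " ")[[1]])
  site_size <- as.numeric(sub("# site_size ", "", hdr[2]))
  df <- utils::read.csv(path, comment.char = "#")
  lat <- cell_lattice(dims, site_size)
  lat$sites[cbind(df$x, df$y, df$z)] <- as.integer(df$code)
  lat
}
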
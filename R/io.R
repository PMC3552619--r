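#' Read a simulation configuration file
#'
#' Configurations are single YAML or JSON documents.  A `preset` key plus
#' overrides builds a [diffusion_config()]; a `model: fitness` document
#' supplies `r0`, `rmat` (or per-cell `effects` with `l`), `dims`,
#' `density`, `ratio`, `chi`, `l`, `n`, `dt`, `stop` and `seed`.
#'
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return the parsed configuration list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
  else stop("config must be a .yaml or .json file")
}

#' Read a two-channel section image pair
#'
#' Reads 8/16-bit grayscale PNG or TIFF channel images as intensity
#' matrices oriented for [digitize()] (rows = lateral position, column 1 at
#' the surface).
#'
#' @param path_r,path_g image files (red and green channels).
#' @return list with `channel_r`, `channel_g`.
#' @export
read_channel_images <- function(path_r, path_g) {
  rd <- function(p) {
    img <- if (grepl("\\.png$", p, ignore.case = TRUE)) png::readPNG(p)
           else tiff::readTIFF(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    t(img)   # image rows are z from the top; transpose to (x, z)
  }
  list(channel_r = rd(path_r), channel_g = rd(path_g))
}

#' Write per-section pattern statistics to CSV
#'
#' @param sections list of `section_image`s.
#' @param path output CSV; one row per (section, column) with `section`,
#'   `x`, `h`, `c`, plus a summary CSV alongside (suffix `_summary.csv`)
#'   with per-section `im`, `patch_size`, `height`.
#' @param pair optional focal pair for multi-population sections.
#' @export
write_section_stats <- function(sections, path, pair = NULL) {
  if (inherits(sections, "section_image")) sections <- list(sections)
  per_col <- do.call(rbind, lapply(seq_along(sections), function(i)
    cbind(section = i, column_stats(sections[[i]], pair))))
  utils::write.csv(per_col, path, row.names = FALSE)
  summ <- do.call(rbind, lapply(seq_along(sections), function(i) {
    res <- tryCatch(analyze_section(sections[[i]], pair),
                    error = function(e)
                      data.frame(im = NA_real_, patch_size = NA_real_,
                                 height = NA_real_,
                                 width = nrow(sections[[i]])))
    cbind(section = i, res)
  }))
  utils::write.csv(summ, sub("\\.csv$", "_summary.csv", path),
                   row.names = FALSE)
  invisible(summ)
}
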
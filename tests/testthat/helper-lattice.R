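# shared helpers: small lattices, brute-force oracles, section summaries

lattice_with <- function(dims, cells, site_size = 5) {
  lat <- cell_lattice(dims, site_size)
  for (cl in cells) lat$sites[cl[1], cl[2], cl[3]] <- as.integer(cl[4])
  lat
}

# brute-force occupancy fractions by explicit triple loop with wrapping
brute_phi <- function(lat, site, l, npop) {
  d <- dim(lat$sites)
  counts <- numeric(npop)
  total <- 0
  for (dz in -l:l) {
    z <- site[3] + dz
    if (z < 1 || z > d[3]) next
    for (dy in -l:l) for (dx in -l:l) {
      x <- ((site[1] + dx - 1) %% d[1]) + 1
      y <- ((site[2] + dy - 1) %% d[2]) + 1
      total <- total + 1
      v <- lat$sites[x, y, z]
      if (v > 0 && v <= npop) counts[v] <- counts[v] + 1
    }
  }
  counts / total
}

random_lattice <- function(dims, fill = 0.4, npop = 2) {
  # gravity-respecting random lattice: random column heights
  lat <- cell_lattice(dims)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2])) {
    h <- rbinom(1, dims[3], fill)
    if (h > 0)
      lat$sites[x, y, seq_len(h)] <- sample.int(npop, h, replace = TRUE)
  }
  lat
}

median_section_im <- function(lat, min_separation = 7) {
  s <- vertical_sections(lat, min_separation = min_separation)
  ims <- vapply(s, function(x)
    tryCatch(intermixing_index(x), error = function(e) NA_real_), numeric(1))
  stats::median(ims, na.rm = TRUE)
}

pop_counts <- function(lat, npop = 2)
  vapply(seq_len(npop), function(p) sum(abs(lat$sites) == p), numeric(1))
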
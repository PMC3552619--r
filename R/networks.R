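#' Draw a random multi-species interaction network
#'
#' Each unordered pair of species receives one of the six ecological
#' interaction types uniformly at random.  Basal fitnesses are drawn
#' uniformly from 0.03--0.05/hr; each non-neutral directed effect is a
#' per-partner-cell benefit or harm of 2--3% of the recipient's basal
#' fitness (strong interaction); initial fractions are random with every
#' species at least 5% of the total.
#'
#' @param n_species number of species (default 5).
#' @return a list of class `network_spec`: `n_species`, `pairs` (data frame
#'   with `a`, `b`, `type`), `r0`, `rmat` (interaction matrix in per-hour
#'   units, converted from per-cell effects for `l = 3`),
#'   `effects_per_cell`, `initial_fractions`.
#' @examples
#' set.seed(1)
#' net <- random_network(5)
#' nrow(net$pairs)  # choose(5, 2) = 10
#' @export
random_network <- function(n_species = 5) {
  stopifnot(n_species >= 2)
  types <- c("~~", "++", "~+", "~-", "--", "-+")
  pr <- t(utils::combn(n_species, 2))
  pair_types <- sample(types, nrow(pr), replace = TRUE)
  r0 <- stats::runif(n_species, 0.03, 0.05)
  eff <- matrix(0, n_species, n_species)   # eff[i, j]: per-cell effect of j on i
  for (k in seq_len(nrow(pr))) {
    a <- pr[k, 1]; b <- pr[k, 2]
    s <- strsplit(pair_types[k], "")[[1]]  # effect received by (a, b)
    sg <- c("~" = 0, "+" = 1, "-" = -1)
    if (sg[[s[1]]] != 0)
      eff[a, b] <- sg[[s[1]]] * stats::runif(1, 0.02, 0.03) * r0[a]
    if (sg[[s[2]]] != 0)
      eff[b, a] <- sg[[s[2]]] * stats::runif(1, 0.02, 0.03) * r0[b]
  }
  repeat {
    f <- stats::runif(n_species)
    f <- f / sum(f)
    if (all(f >= 0.05)) break
  }
  structure(list(n_species = n_species,
                 pairs = data.frame(a = pr[, 1], b = pr[, 2],
                                    type = pair_types),
                 r0 = r0,
                 effects_per_cell = eff,
                 rmat = per_cell_effect_to_rij(eff, l = 3),
                 initial_fractions = f),
            class = "network_spec")
}

#' Simulate a network and score per-pair intermixing
#'
#' Runs the fitness model for the given interaction network, extracts
#' vertical cross-sections of the final community, and computes the
#' intermixing index of every species pair on its two-color
#' [pairwise_view()].  A pair is scored as intermixed when its median
#' sectional intermixing index reaches the threshold.
#'
#' @param net a [random_network()] spec.
#' @param dims lattice dimensions (default `c(50, 50, 100)`).
#' @param density inoculation density (cells/mm^2).
#' @param generations stop after this many community doublings (default 10).
#' @param threshold intermixing threshold (default 6).
#' @param params a [fitness_params()].
#' @param min_separation section spacing (default 7).
#' @return a data frame of class `pair_scores` with columns `a`, `b`,
#'   `type`, `im` (median over sections) and `intermixed`.
#' @export
run_network_experiment <- function(net, dims = c(50, 50, 100),
                                   density = 500, generations = 10,
                                   threshold = 6,
                                   params = fitness_params(),
                                   min_separation = 7) {
  init <- seed_lattice(dims, density = density,
                       ratio = net$initial_fractions)
  run <- run_fitness(init, net$r0, net$rmat, params,
                     stop = list(generations = generations),
                     record_every = 0)
  secs <- vertical_sections(run$lattice, min_separation = min_separation)
  scores <- net$pairs
  scores$im <- vapply(seq_len(nrow(scores)), function(k) {
    ims <- vapply(secs, function(s)
      tryCatch(intermixing_index(pairwise_view(s, c(scores$a[k],
                                                    scores$b[k]))),
               error = function(e) NA_real_), numeric(1))
    stats::median(ims, na.rm = TRUE)
  }, numeric(1))
  scores$intermixed <- scores$im >= threshold
  attr(scores, "threshold") <- threshold
  attr(scores, "generations") <- run$generations
  class(scores) <- c("pair_scores", class(scores))
  scores
}

#' Tabulate intermixing by interaction type
#'
#' @param scores one `pair_scores` data frame or a list of them (one per
#'   community); lists are summed elementwise.
#' @return a table of counts, interaction type by intermixed status.
#' @export
summarize_batch <- function(scores) {
  if (is.data.frame(scores)) scores <- list(scores)
  all <- do.call(rbind, lapply(scores, function(s)
    as.data.frame(s)[, c("type", "intermixed")]))
  table(type = factor(all$type,
                      levels = c("~~", "++", "~+", "~-", "--", "-+")),
        intermixed = factor(all$intermixed, levels = c(FALSE, TRUE)))
}

#' Run a batch of independent random-network communities
#'
#' @param n_communities number of independent networks (the full protocol
#'   uses 24 five-species networks, i.e. 240 pairwise interactions).
#' @param n_species species per network.
#' @param ... passed to [run_network_experiment()].
#' @return a list of `pair_scores` with attribute `summary` (the
#'   [summarize_batch()] table).
#' @export
run_network_batch <- function(n_communities, n_species = 5, ...) {
  scores <- lapply(seq_len(n_communities), function(i) {
    s <- run_network_experiment(random_network(n_species), ...)
    s$community <- i
    s
  })
  attr(scores, "summary") <- summarize_batch(scores)
  scores
}
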
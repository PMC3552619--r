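#' Parameters for the interaction-length-scale calculation
#'
#' Describes one exchanged metabolite in a cross-feeding community: how much
#' a release event delivers, how much a consumer needs to divide, how fast
#' the metabolite diffuses, and how often release events occur.  The
#' defaults describe lysine exchange in an engineered cooperative yeast
#' community: they are documented reconstructions consistent with the
#' published kinetics of such strains (release of a few divisions' worth of
#' metabolite per dying cell, ~2 fmole per division, a minimum doubling
#' time of 2 hr, death ~2.5%/hr), not direct measurements.
#'
#' @param beta amount released per release event (fmole).
#' @param alpha amount required per division (fmole).
#' @param D1 diffusion constant within the community (um^2/s); 360 is the
#'   agarose/water-like value, ~20 the value measured for a fluorescent
#'   tracer inside a yeast community.
#' @param T_double minimum doubling time of the consumer (s).
#' @param c cell diameter (um).
#' @param death_rate release-event (death) rate per releasing cell (per s).
#' @return a list of class `length_scale_params`.
#' @export
length_scale_params <- function(beta = 8, alpha = 2, D1 = 360,
                                T_double = 7200, c = 5,
                                death_rate = 0.025 / 3600) {
  vals <- c(beta = beta, alpha = alpha, D1 = D1, T_double = T_double, c = c,
            death_rate = death_rate)
  if (any(vals <= 0)) stop("all length-scale parameters must be positive")
  structure(as.list(vals), class = "length_scale_params")
}

#' Characteristic interaction length of a released metabolite
#'
#' Distance a released packet of metabolite diffuses before being consumed.
#' A release event delivers `beta` fmole into a spherical diffusion domain
#' of radius `l` holding `N_u = (2l/c)^3` consuming cells; the packet
#' survives `t_c = l^2 / (2 D1)` and each consumer takes up at most
#' `v = alpha / T` per second.  Setting `beta = N_u v t_c` and solving for
#' `l` gives the fifth-root scale
#' \deqn{l = [(\beta/\alpha)\, D_1\, T\, c^3 / 4]^{1/5}}
#' (about 50 um for the default parameters at `D1 = 360` um^2/s, and about
#' 30 um at the in-community value of 20 um^2/s).  Because of the 1/5
#' power, even large changes in the diffusion constant move `l` only
#' weakly: multiplying `D1` by 32 doubles `l`.
#'
#' @param p a [length_scale_params()].
#' @return interaction length in micrometres.
#' @examples
#' interaction_length(length_scale_params())           # ~50 um
#' interaction_length(length_scale_params(D1 = 20))    # ~30 um
#' @export
interaction_length <- function(p = length_scale_params()) {
  ((p$beta / p$alpha) * p$D1 * p$T_double * p$c^3 / 4)^(1 / 5)
}

#' Statistics of one diffusion domain
#'
#' For an interaction length `l`: the number of consuming cells in the
#' domain `N_u = (2l/c)^3`, the consumption time `t_c = l^2/(2 D1)`, and the
#' expected number of further release events within the domain during `t_c`,
#' `N_u t_c d_G`.  A small expectation (about 0.2 for the defaults) means a
#' second release rarely lands in the same domain before the first packet is
#' consumed, so `l` is a genuine interaction length scale.
#'
#' @param l interaction length (um), e.g. from [interaction_length()].
#' @param p a [length_scale_params()].
#' @return a list of class `length_scale_result`: `l`, `n_u`, `t_c` (s),
#'   `expected_release_events`.
#' @export
diffusion_domain_stats <- function(l = interaction_length(p),
                                   p = length_scale_params()) {
  stopifnot(l > 0)
  n_u <- (2 * l / p$c)^3
  t_c <- l^2 / (2 * p$D1)
  structure(list(l = l, n_u = n_u, t_c = t_c,
                 expected_release_events = n_u * t_c * p$death_rate),
            class = "length_scale_result")
}

#' @export
print.length_scale_result <- function(x, ...) {
  cat(sprintf("interaction length l = %.3g um\n", x$l))
  cat(sprintf("  consuming cells in domain N_u = %.4g\n", x$n_u))
  cat(sprintf("  consumption time t_c = %.3g s\n", x$t_c))
  cat(sprintf("  expected release events in domain during t_c = %.3g\n",
              x$expected_release_events))
  invisible(x)
}
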
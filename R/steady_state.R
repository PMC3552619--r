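#' Parameters of a pairwise ecological interaction
#'
#' Describes two populations G and R engaging in one of the six ecological
#' interaction classes.  The type is written `G[s_G s_R]R` where `s_G` is
#' the net fitness effect *received* by G from R and `s_R` the effect
#' received by R from G: `~` neutral, `+` beneficial, `-` inhibitory.  Both
#' non-neutral effects share a single magnitude `r_int`.
#'
#' Accepted type spellings: `"~~"`/`"competition"`, `"++"`/`"cooperation"`,
#' `"~+"`/`"commensalism"`, `"~-"`/`"amensalism"`, `"--"`/`"antagonism"`,
#' `"-+"`/`"exploitation"` (G inhibited, R benefited), optionally in
#' brackets (`"[~+]"`).
#'
#' @param type interaction type (see Details).
#' @param r_g0,r_r0 basal fitnesses of G and R (per hour).
#' @param r_int interaction magnitude (per hour, >= 0).
#' @return a list of class `pair_params` with canonical `type` and signs
#'   `s_g`, `s_r`.
#' @export
pair_params <- function(type, r_g0, r_r0, r_int = 0) {
  type <- canonical_type(type)
  stopifnot(r_g0 >= 0, r_r0 >= 0, r_int >= 0)
  if (type == "~~" && r_int != 0)
    stop("competition [~~] has no interaction term; r_int must be 0")
  if (type != "~~" && r_int <= 0)
    stop("non-neutral interactions need r_int > 0")
  signs <- c("~" = 0, "+" = 1, "-" = -1)
  s <- strsplit(type, "")[[1]]
  structure(list(type = type, r_g0 = r_g0, r_r0 = r_r0, r_int = r_int,
                 s_g = unname(signs[s[1]]), s_r = unname(signs[s[2]])),
            class = "pair_params")
}

canonical_type <- function(type) {
  key <- tolower(gsub("[][ ]", "", type))
  map <- c("~~" = "~~", "competition" = "~~", "comp" = "~~",
           "++" = "++", "cooperation" = "++", "coop" = "++",
           "~+" = "~+", "commensalism" = "~+", "commensal" = "~+",
           "~-" = "~-", "amensalism" = "~-", "amensal" = "~-",
           "--" = "--", "antagonism" = "--", "mutual_antagonism" = "--",
           "-+" = "-+", "exploitation" = "-+", "exploit" = "-+")
  if (!key %in% names(map))
    stop("unknown interaction type: ", type,
         " (exploitation is written with G as the inhibited partner: \"-+\")")
  map[[key]]
}

#' Mean-field fitness difference between the two partners
#'
#' Assuming the interaction neighborhood is saturated (`phi_G + phi_R = 1`),
#' the crowding factor is common to both populations and cancels from the
#' comparison, leaving the reduced fitnesses
#' `r^_i = r_i0 + s_i * r_int * phi_j * (1 - phi_i)` (the `form = "quadratic"`
#' default, the same interaction term the simulator uses) or the simplified
#' linear form `r^_i = r_i0 + s_i * r_int * phi_j`.  For cooperation the two
#' forms coincide exactly, by the identity `(1-phi)^2 - phi^2 = 1 - 2 phi`.
#'
#' @param phi_g occupancy fraction of G, in `[0, 1]`.
#' @param p a [pair_params()].
#' @param form `"quadratic"` (full interaction term) or `"linear"`.
#' @return `r^_G - r^_R` in per hour.
#' @export
fitness_difference <- function(phi_g, p, form = c("quadratic", "linear")) {
  form <- match.arg(form)
  if (any(phi_g < 0 | phi_g > 1)) stop("phi_g must lie in [0, 1]")
  phi_r <- 1 - phi_g
  if (form == "quadratic") {
    (p$r_g0 + p$s_g * p$r_int * phi_r * (1 - phi_g)) -
      (p$r_r0 + p$s_r * p$r_int * phi_g * (1 - phi_r))
  } else {
    (p$r_g0 + p$s_g * p$r_int * phi_r) - (p$r_r0 + p$s_r * p$r_int * phi_g)
  }
}

#' Steady-state composition of a pairwise community
#'
#' Solves `r^_G = r^_R` for the steady-state occupancy `phi_G*` of the
#' mean-field pair dynamics, classifies its stability from the sign of the
#' fitness difference around the root, and reports the existence condition.
#' Cooperation admits `phi_G* = (r_G0 - r_R0 + r_int) / (2 r_int)` when
#' `r_int > |r_G0 - r_R0|` (globally stable); mutual antagonism has the
#' mirrored root but unstable; exploitation has an upper, locally stable
#' root `1/2 + sqrt((r_G0 - r_R0)/(2 r_int) - 1/4)` together with the
#' critical basin boundary `phi_Gc` (the lower, unstable root), requiring
#' `r_int > r_G0 - r_R0 > 0` and `r_int < 2 (r_G0 - r_R0)`.  Commensalism
#' and amensalism have square-root fixed points under the full quadratic
#' form and the linear fixed points `(r_G0 - r_R0)/r_int` /
#' `(r_R0 - r_G0)/r_int` under `form = "linear"`; the existence conditions
#' agree between the two forms.
#'
#' @param p a [pair_params()].
#' @param form `"quadratic"` (default) or `"linear"`; see
#'   [fitness_difference()].
#' @return a list of class `steady_state_result`: `phi_star`, `exists`,
#'   `condition` (human-readable), `stability` (`"globally_stable"`,
#'   `"locally_stable"` or `"unstable"`), `phi_crit` (exploitation only).
#' @examples
#' analyze_steady_state(pair_params("coop", 0.3, 0.4, 0.5))$phi_star  # 0.4
#' @export
analyze_steady_state <- function(p, form = c("quadratic", "linear")) {
  form <- match.arg(form)
  dg <- p$r_g0 - p$r_r0
  phi <- NA_real_
  phi_c <- NA_real_
  ok <- FALSE
  stab <- "unstable"
  cond <- ""
  note <- NULL
  switch(p$type,
    "~~" = {
      cond <- "r_G0 = r_R0 (any phi_G is then a fixed point)"
      ok <- dg == 0
      stab <- "unstable"
    },
    "++" = {
      cond <- "r_int > |r_G0 - r_R0|"
      ok <- p$r_int > abs(dg)
      phi <- (dg + p$r_int) / (2 * p$r_int)
      stab <- "globally_stable"
    },
    "--" = {
      cond <- "r_int > |r_G0 - r_R0|"
      ok <- p$r_int > abs(dg)
      phi <- (-dg + p$r_int) / (2 * p$r_int)
      stab <- "unstable"
    },
    "~+" = {
      cond <- "r_int > r_G0 - r_R0 > 0"
      ok <- dg > 0 && p$r_int > dg
      if (ok)
        phi <- if (form == "quadratic") sqrt(dg / p$r_int) else dg / p$r_int
      stab <- "globally_stable"
      if (form == "quadratic")
        note <- "full-form fixed point sqrt((r_G0-r_R0)/r_int); linear form gives (r_G0-r_R0)/r_int"
    },
    "~-" = {
      cond <- "r_int > r_R0 - r_G0 > 0"
      ok <- dg < 0 && p$r_int > -dg
      if (ok)
        phi <- if (form == "quadratic") sqrt(-dg / p$r_int) else -dg / p$r_int
      stab <- "unstable"
      if (form == "quadratic")
        note <- "full-form fixed point sqrt((r_R0-r_G0)/r_int); linear form gives (r_R0-r_G0)/r_int"
    },
    "-+" = {
      cond <- "r_int > r_G0 - r_R0 > 0 and r_int < 2 (r_G0 - r_R0)"
      if (form == "linear") {
        ok <- FALSE
        note <- "the linear form has a constant fitness difference for exploitation; use the quadratic form"
      } else {
        disc <- dg / (2 * p$r_int) - 0.25
        ok <- dg > 0 && p$r_int > dg && disc >= 0
        if (ok) {
          phi <- 0.5 + sqrt(disc)
          phi_c <- 0.5 - sqrt(disc)
        }
        stab <- "locally_stable"
      }
    },
    stop("unsupported type: ", p$type))
  if (!ok) {
    phi <- NA_real_
    phi_c <- NA_real_
  }
  structure(list(type = p$type, phi_star = phi, exists = ok,
                 condition = cond,
                 stability = if (ok) stab else NA_character_,
                 phi_crit = phi_c, form = form, note = note),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("G[%s]R steady state (%s form)\n", x$type, x$form))
  if (x$exists) {
    cat(sprintf("  phi_G* = %.6g  (%s)\n", x$phi_star, x$stability))
    if (!is.na(x$phi_crit))
      cat(sprintf("  phi_Gc = %.6g (basin boundary: start above it)\n",
                  x$phi_crit))
  } else {
    cat("  no interior fixed point\n")
  }
  cat(sprintf("  condition: %s\n", x$condition))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Mean-field dynamics of the partner ratio
#'
#' Integrates the replicator-form dynamics of the G fraction,
#' `dphi/dt = phi (1 - phi) (r^_G - r^_R)` (from `d ln N_i/dt = r^_i`; the
#' shared crowding factor cancels in the difference), with classical
#' fourth-order Runge-Kutta steps.  A step producing a jump larger than
#' 0.25 in `phi` is rejected as a step-size error.
#'
#' @param phi0 initial fraction of G, in `(0, 1)`.
#' @param p a [pair_params()].
#' @param horizon integration horizon in hours.
#' @param dt step in hours (default `horizon / 2000`).
#' @param form passed to [fitness_difference()].
#' @return a data frame with columns `time` (hours) and `phi_g`.
#' @export
ratio_dynamics <- function(phi0, p, horizon = 500, dt = NULL,
                           form = c("quadratic", "linear")) {
  form <- match.arg(form)
  stopifnot(phi0 > 0, phi0 < 1, horizon > 0)
  if (is.null(dt)) dt <- horizon / 2000
  nstep <- ceiling(horizon / dt)
  phi <- numeric(nstep + 1)
  phi[1] <- phi0
  f <- function(x) {
    x <- min(max(x, 0), 1)
    x * (1 - x) * fitness_difference(x, p, form)
  }
  for (k in seq_len(nstep)) {
    x <- phi[k]
    k1 <- f(x)
    k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    step <- dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (abs(step) > 0.25)
      stop("step size too large: phi jumped by ", signif(abs(step), 3),
           " in one step; reduce dt")
    phi[k + 1] <- min(max(x + step, 0), 1)
  }
  data.frame(time = seq(0, by = dt, length.out = nstep + 1), phi_g = phi)
}
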
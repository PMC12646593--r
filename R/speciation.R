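#' Henderson-Hasselbalch species fractions at a pH
#'
#' Computes the equilibrium fractions of the net-charge states of an
#' ionizable chemical. Each acid group is a two-state system (protonated,
#' neutral contribution; deprotonated, -1) with relative deprotonation
#' weight `10^(pH - pKa)`; each base group analogously carries weight
#' `10^(pKa - pH)` for its protonated (+1) state. Groups ionize
#' independently, so the net-charge distribution is the convolution of the
#' per-group two-state distributions, normalized over all microstates. All
#' net-neutral microstates, including zwitterions, are pooled into
#' `f_neutral`.
#'
#' @param profile An [ionization_profile()].
#' @param ph pH at which to speciate, in `[0, 14]`. Default 7.4, the
#'   physiological pH used throughout the bioassay models.
#' @return An object of class `species_fractions`: a list with fields
#'   `f_neutral`, `f_minus`, `f_minus2`, `f_plus`, `f_plus2` (summing to 1)
#'   and `ph`.
#' @examples
#' # monoprotic acid at its pKa: half neutral, half anionic
#' species_fractions(ionization_profile(7.4, "acid"), ph = 7.4)
#' # a base with pKa 9.4 is ~99% protonated at pH 7.4
#' species_fractions(ionization_profile(9.4, "base"), ph = 7.4)
#' @export
species_fractions <- function(profile, ph = 7.4) {
  if (!inherits(profile, "ionization_profile")) {
    ct_abort("`profile` must be an ionization_profile", class = "bad_input")
  }
  assert_scalar_num(ph, "ph", 0, 14)

  # weight vector over net charges -2..+2, built by convolving per-group
  # two-state weights; index = charge + 3
  w <- c(0, 0, 1, 0, 0)
  for (i in seq_along(profile$pka)) {
    pka <- profile$pka[i]
    if (profile$kind[i] == "acid") {
      step <- c(`0` = 1, `-1` = 10^(ph - pka))
    } else {
      step <- c(`0` = 1, `1` = 10^(pka - ph))
    }
    w <- convolve_charges(w, step)
  }
  w <- w / sum(w)
  structure(
    list(f_neutral = w[3], f_minus = w[2], f_minus2 = w[1],
         f_plus = w[4], f_plus2 = w[5], ph = ph),
    class = "species_fractions"
  )
}

convolve_charges <- function(w, step) {
  out <- numeric(5)
  charges <- as.integer(names(step))
  for (j in seq_along(step)) {
    dc <- charges[j]
    for (c0 in -2:2) {
      if (w[c0 + 3] == 0) next
      c1 <- c0 + dc
      # profiles are capped at 2 groups per kind, so c1 stays in -2..2
      out[c1 + 3] <- out[c1 + 3] + w[c0 + 3] * step[j]
    }
  }
  out
}

#' @export
print.species_fractions <- function(x, ...) {
  cat(sprintf(
    "<species_fractions pH %.2f: neutral %.4f, -1 %.4f, -2 %.4f, +1 %.4f, +2 %.4f>\n",
    x$ph, x$f_neutral, x$f_minus, x$f_minus2, x$f_plus, x$f_plus2
  ))
  invisible(x)
}

# build species_fractions directly from known fractions (used by tests and
# by callers that obtained fractions elsewhere)
#' Construct species fractions from known values
#'
#' @param f_neutral,f_minus,f_minus2,f_plus,f_plus2 Fractions in `[0, 1]`,
#'   summing to 1 within `1e-9`.
#' @param ph pH the fractions refer to.
#' @return A `species_fractions` object.
#' @export
make_species_fractions <- function(f_neutral = 1, f_minus = 0, f_minus2 = 0,
                                   f_plus = 0, f_plus2 = 0, ph = 7.4) {
  f <- c(f_neutral, f_minus, f_minus2, f_plus, f_plus2)
  if (any(f < -1e-12) || any(f > 1 + 1e-12) || abs(sum(f) - 1) > 1e-9) {
    ct_abort("species fractions must lie in [0,1] and sum to 1",
             class = "bad_input")
  }
  structure(
    list(f_neutral = f_neutral, f_minus = f_minus, f_minus2 = f_minus2,
         f_plus = f_plus, f_plus2 = f_plus2, ph = ph),
    class = "species_fractions"
  )
}

#' Ionization-corrected air-water distribution ratio
#'
#' Only the neutral species has appreciable vapor pressure, so the
#' air-water distribution ratio at a pH is the neutral-species partition
#' constant scaled by the neutral fraction: `D_aw(pH) = K_aw * f_neutral`.
#'
#' @param log_kaw log10 air-water partition coefficient of the neutral
#'   species (dimensionless).
#' @param fractions A [species_fractions()] object.
#' @return `D_aw` on the linear (not log) scale.
#' @examples
#' # fully neutral volatile: D_aw equals K_aw
#' daw_at_ph(log10(0.40), make_species_fractions())
#' @export
daw_at_ph <- function(log_kaw, fractions) {
  if (is.na(log_kaw)) {
    ct_abort("`log_kaw` is absent; cannot compute D_aw", class = "missing_input")
  }
  assert_scalar_num(log_kaw, "log_kaw")
  stopifnot(inherits(fractions, "species_fractions"))
  10^log_kaw * fractions$f_neutral
}
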
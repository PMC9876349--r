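#' Spheroid structure snapshot
#'
#' A single spheroid observation: outer radius `R_o`, necrotic radius `R_n`,
#' inhibited radius `R_i`, and optionally the hypoxic radius `R_p` and the
#' observation time. In the growth regime modelled here the radii are nested,
#' `0 <= R_n <= R_i <= R_o` and `R_n <= R_p <= R_o`. Noisy measurements with
#' `R_i < R_n` are admitted (flagged, not rejected); profile evaluation clips
#' them to `R_i = R_n`.
#'
#' @param R_o outer radius \[um\], positive.
#' @param R_n necrotic radius \[um\]; 0 before the core forms.
#' @param R_i inhibited radius \[um\]; 0 before the inhibited region forms.
#' @param R_p hypoxic radius \[um\], optional.
#' @param t observation time \[days\], optional.
#'
#' @return An object of class `spheroid_structure` with fields `R_o`, `R_n`,
#'   `R_i`, `R_p`, `t` and derived fractions `xi_n`, `xi_i`, `xi_p`.
#' @export
spheroid_structure <- function(R_o, R_n = 0, R_i = 0, R_p = NA_real_,
                               t = NA_real_) {
  stopifnot(is.finite(R_o), R_o > 0, is.finite(R_n), R_n >= 0,
            is.finite(R_i), R_i >= 0)
  if (R_n > R_o) stop("R_n exceeds R_o")
  if (R_i > R_o) stop("R_i exceeds R_o")
  if (!is.na(R_p) && (R_p < 0 || R_p > R_o))
    stop("R_p must lie in [0, R_o]")
  structure(list(R_o = R_o, R_n = R_n, R_i = R_i, R_p = R_p, t = t,
                 xi_n = R_n / R_o, xi_i = R_i / R_o,
                 xi_p = if (is.na(R_p)) NA_real_ else R_p / R_o,
                 R_i_below_R_n = R_i > 0 && R_i < R_n),
            class = "spheroid_structure")
}

#' Growth phase of a spheroid snapshot
#'
#' Phase (i): exponential growth, no internal structure. Phase (ii): an
#' inhibited region is present but no necrotic core. Phase (iii): a necrotic
#' core is present.
#'
#' @param structure a [spheroid_structure()].
#' @return One of `"phase_i"`, `"phase_ii"`, `"phase_iii"`.
#' @export
classify_phase <- function(structure) {
  if (structure$R_n > 0) return("phase_iii")
  if (structure$R_i > 0) return("phase_ii")
  "phase_i"
}

#' Oxygen parameters in lumped form
#'
#' The steady-state oxygen field depends only on the ambient pressure
#' `p_inf` and the gradient coefficient `a = Omega * alpha / (6 k)`
#' \[pressure um^-2\]. Equivalently `a = p_inf / R_c^2`, so either `a` or the
#' critical radius `R_c` may be supplied.
#'
#' @param p_inf external oxygen partial pressure (any fixed unit; percent of
#'   atmosphere by convention).
#' @param a gradient coefficient \[pressure um^-2\].
#' @param R_c critical outer radius \[um\]; used to derive `a` when `a` is
#'   missing.
#' @param p_n necrotic threshold pressure; 0 in this model.
#' @return An object of class `oxygen_params`.
#' @export
oxygen_params <- function(p_inf, a = NULL, R_c = NULL, p_n = 0) {
  stopifnot(p_inf > 0)
  if (is.null(a)) {
    stopifnot(!is.null(R_c), R_c > 0)
    a <- p_inf / R_c^2
  }
  stopifnot(a > 0)
  structure(list(p_inf = p_inf, a = a, p_n = p_n, R_c = sqrt(p_inf / a)),
            class = "oxygen_params")
}

#' Waste parameters in lumped form
#'
#' The steady-state waste field depends only on `b = P / (6 kappa)`
#' \[concentration um^-2\]; the inhibition threshold `beta_i` enters through
#' the lumped radius `Rbar = sqrt(6 beta_i kappa / P)`, the outer radius at
#' which the inhibited region first forms.
#'
#' @param b production-to-diffusion ratio `P / (6 kappa)`
#'   \[mol um^-3 um^-2\].
#' @param Rbar inhibition-onset outer radius \[um\]; with `b` it fixes
#'   `beta_i = b * Rbar^2`.
#' @return An object of class `waste_params`.
#' @export
waste_params <- function(b, Rbar) {
  stopifnot(b > 0, Rbar > 0)
  structure(list(b = b, Rbar = Rbar, beta_i = b * Rbar^2),
            class = "waste_params")
}

# shared algebraic kernel: R_o^2 - r^2 - 2 R_n^3 (1/r - 1/R_o), with the
# harmonic term vanishing when R_n = 0 (including at r = 0)
profile_kernel <- function(r, R_o, R_n) {
  harm <- if (R_n > 0) 2 * R_n^3 * (1 / r - 1 / R_o) else 0
  R_o^2 - r^2 - harm
}

#' Steady-state oxygen partial pressure inside a spheroid
#'
#' Closed-form solution of the quasi-steady oxygen diffusion-consumption
#' problem in a sphere with a non-consuming necrotic core of radius `R_n`:
#' `p(r) = max(0, p_inf - a * (R_o^2 - r^2 - 2 R_n^3 (1/r - 1/R_o)))` for
#' `R_n <= r <= R_o`, with `p = p_n = 0` inside the core. The boundary value
#' `p(R_o) = p_inf` holds exactly and the profile is non-decreasing in `r`.
#'
#' @param r radial position(s) \[um\], `0 <= r <= R_o`.
#' @param R_o outer radius \[um\].
#' @param R_n necrotic radius \[um\], `0 <= R_n < R_o`.
#' @param oxy an [oxygen_params()] object.
#' @return Partial pressure(s), same unit as `oxy$p_inf`.
#' @export
oxygen_profile <- function(r, R_o, R_n, oxy) {
  stopifnot(inherits(oxy, "oxygen_params"), R_o > 0, R_n >= 0, R_n < R_o)
  if (any(!is.finite(r)) || any(r < 0) || any(r > R_o))
    stop("r must lie in [0, R_o]")
  p <- pmax(0, oxy$p_inf - oxy$a * profile_kernel(pmax(r, R_n), R_o, R_n))
  ifelse(r < R_n, oxy$p_n, p)
}

#' Steady-state metabolic waste concentration inside a spheroid
#'
#' Closed-form solution of the quasi-steady waste production-diffusion
#' problem with zero surface concentration:
#' `beta(r) = b * (R_o^2 - r^2 - 2 R_n^3 (1/r - 1/R_o))` on `[R_n, R_o]`,
#' held constant at its `r = R_n` value inside the core. Monotone
#' non-increasing in `r` with `beta(R_o) = 0`.
#'
#' @inheritParams oxygen_profile
#' @param waste a [waste_params()] object.
#' @return Concentration(s) \[mol um^-3\].
#' @export
waste_profile <- function(r, R_o, R_n, waste) {
  stopifnot(inherits(waste, "waste_params"), R_o > 0, R_n >= 0, R_n < R_o)
  if (any(!is.finite(r)) || any(r < 0) || any(r > R_o))
    stop("r must lie in [0, R_o]")
  waste$b * profile_kernel(pmax(r, R_n), R_o, R_n)
}

#' Necrotic radius from the oxygen structure constraint
#'
#' Inverts `R_c^2 = R_o^2 - R_n^2 - (2 R_n^2 / R_o)(R_o - R_n)` for the
#' unique root `R_n` in `[0, R_o)`; returns 0 when `R_o <= R_c` (core not yet
#' formed). Bisection-safeguarded Newton iteration, absolute tolerance well
#' below 1e-9 um.
#'
#' @param R_o outer radius \[um\] (vectorised).
#' @param R_c critical outer radius \[um\].
#' @return Necrotic radius \[um\].
#' @export
necrotic_radius <- function(R_o, R_c) {
  if (any(!is.finite(R_o)) || any(!is.finite(R_c)))
    stop("non-finite inputs")
  stopifnot(all(R_o > 0), all(R_c > 0))
  cpp_necrotic_root(as.numeric(R_o), as.numeric(R_c))
}

#' Inhibited radius from the waste structure constraint
#'
#' Inverts `Rbar^2 = R_o^2 - R_i^2 - 2 R_n^3 (1/R_i - 1/R_o)` for the root
#' `R_i` in `[R_n, R_o)`. Returns 0 when `R_o <= Rbar` (inhibited region not
#' yet formed) or when the waste maximum (attained at `r = R_n`) is below the
#' inhibition threshold.
#'
#' @param R_o outer radius \[um\] (vectorised).
#' @param R_n necrotic radius \[um\], `0 <= R_n < R_o`.
#' @param Rbar inhibition-onset outer radius \[um\].
#' @return Inhibited radius \[um\].
#' @export
inhibited_radius <- function(R_o, R_n, Rbar) {
  if (any(!is.finite(R_o)) || any(!is.finite(R_n)) || any(!is.finite(Rbar)))
    stop("non-finite inputs")
  stopifnot(all(R_o > 0), all(R_n >= 0), all(R_n < R_o), all(Rbar > 0))
  cpp_inhibited_root(as.numeric(R_o), as.numeric(R_n), as.numeric(Rbar))
}

#' Predicted hypoxic radius
#'
#' The radius at which the internal oxygen partial pressure equals the
#' hypoxia-marker binding threshold `p_hyp`. Since `p(R_o) = p_inf` the
#' surface is never hypoxic; the root lies in `[R_n, R_o]`, collapsing onto
#' `R_n` as `p_hyp` approaches 0 and onto `R_o` as `p_hyp` approaches
#' `p_inf`. Returns 0 when even the centre is above threshold.
#'
#' @param R_o outer radius \[um\].
#' @param R_n necrotic radius \[um\].
#' @param oxy an [oxygen_params()] object.
#' @param p_hyp threshold partial pressure, `p_n <= p_hyp <= p_inf`
#'   (values above `p_inf` return `R_o` with a warning).
#' @return Hypoxic radius \[um\].
#' @export
predict_hypoxic_radius <- function(R_o, R_n, oxy, p_hyp) {
  stopifnot(inherits(oxy, "oxygen_params"), R_o > 0, R_n >= 0, R_n < R_o,
            p_hyp >= oxy$p_n)
  if (p_hyp > oxy$p_inf) {
    warning("p_hyp exceeds p_inf; the whole spheroid is below threshold ",
            "only at the surface, returning R_o")
    return(R_o)
  }
  if (p_hyp == oxy$p_inf) return(R_o)
  # p(r) = p_hyp is the same algebraic constraint as the inhibited radius
  # with Rbar^2 = (p_inf - p_hyp) / a
  rbar <- sqrt((oxy$p_inf - p_hyp) / oxy$a)
  if (R_o <= rbar) return(0)  # centre pressure still above threshold
  p_at_core <- oxy$p_inf - oxy$a * profile_kernel(max(R_n, 1e-12), R_o, R_n)
  if (R_n > 0 && p_at_core >= p_hyp) return(R_n)
  cpp_inhibited_root(R_o, R_n, rbar)
}

#' Per-spheroid snapshot estimators
#'
#' Inverts the structure constraints at a single measured snapshot to
#' estimate, per spheroid and time point independently: the critical radius
#' `R_c` (requires a necrotic core, phase iii), the oxygen consumption rate
#' `alpha` (from `R_c` and the dimensional constants), the oxygen pressure at
#' the inhibited boundary `p_i` (the oxygen-threshold interpretation of the
#' inhibited region), and the inhibition-onset radius `Rbar` (the
#' waste-threshold interpretation; requires phase ii or iii). Quantities that
#' are not estimable at the snapshot's phase are returned as `NA` with the
#' corresponding `estimable_*` flag set to `FALSE`, never as an error.
#'
#' @param structure a [spheroid_structure()].
#' @param p_inf external oxygen partial pressure \[%\].
#' @param constants an [oxygen_constants()] object (for `alpha`).
#' @return A list with `R_c`, `alpha`, `p_i`, `Rbar` \[um, SI, %, um\],
#'   logical `estimable_Rc` / `estimable_Rbar`, and the snapshot `phase`.
#' @export
snapshot_estimate <- function(structure, p_inf,
                              constants = oxygen_constants()) {
  stopifnot(inherits(structure, "spheroid_structure"), p_inf > 0)
  R_o <- structure$R_o
  R_n <- structure$R_n
  R_i <- structure$R_i
  if (R_i > 0 && R_i < R_n) {
    warning("measured R_i below R_n; clipped to R_i = R_n for estimation")
    R_i <- R_n
  }
  phase <- classify_phase(structure)
  out <- list(R_c = NA_real_, alpha = NA_real_, p_i = NA_real_,
              Rbar = NA_real_, estimable_Rc = FALSE, estimable_Rbar = FALSE,
              phase = phase)
  if (R_n > 0) {
    rc2 <- R_o^2 - 3 * R_n^2 + 2 * R_n^3 / R_o
    out$R_c <- sqrt(max(rc2, 0))
    out$alpha <- alpha_from_critical_radius(out$R_c, constants$k,
                                            constants$Omega,
                                            percent_to_mmHg(p_inf, constants))
    out$estimable_Rc <- TRUE
    if (R_i > 0) {
      oxy <- oxygen_params(p_inf = p_inf, R_c = out$R_c)
      out$p_i <- oxygen_profile(R_i, R_o, R_n, oxy)
    }
  }
  if (R_i > 0) {
    harm <- if (R_n > 0) 2 * R_n^3 * (1 / R_i - 1 / R_o) else 0
    out$Rbar <- sqrt(max(R_o^2 - R_i^2 - harm, 0))
    out$estimable_Rbar <- TRUE
  }
  out
}
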
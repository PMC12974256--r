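#' Photophysical constants of the dual-luminophore sensing film
#'
#' The sensing film contains two luminophores excited by the same LED pulse:
#' a CO2-sensitive fluorophore whose intensity and lifetime are quenched
#' according to the Stern-Volmer relation, and a CO2-insensitive
#' phosphorescent reference with a much longer lifetime. Intensities are
#' expressed directly as photodiode currents, so the optical collection
#' efficiency and photodiode responsivity are folded into the responsivities
#' `s_sen`/`s_ref`.
#'
#' The defaults form a synthetic calibration: the Stern-Volmer constant of
#' the commercial film is not public, and the responsivities are chosen so
#' that an unquenched film under unit excitation produces 500 nA from each
#' luminophore, matching the behavioral operating point used for the error
#' analysis.
#'
#' @param k_sv Stern-Volmer quenching constant, 1/mmHg.
#' @param tau_sen Lifetime of the CO2-sensitive luminophore, seconds
#'   (nanosecond scale).
#' @param tau_ref Lifetime of the reference luminophore, seconds
#'   (microsecond scale); must exceed `tau_sen`.
#' @param s_sen,s_ref Responsivities, amperes of photocurrent per unit of
#'   excitation intensity.
#' @return An object of class `film_params`.
#' @examples
#' film_params()
#' @export
film_params <- function(k_sv = 0.05, tau_sen = 100e-9, tau_ref = 1e-6,
                        s_sen = 500e-9, s_ref = 500e-9) {
  stopifnot(is.numeric(k_sv), is.numeric(tau_sen), is.numeric(tau_ref),
            is.numeric(s_sen), is.numeric(s_ref))
  if (any(c(k_sv, tau_sen, tau_ref, s_sen, s_ref) <= 0))
    stop("all film parameters must be strictly positive", call. = FALSE)
  if (tau_sen >= tau_ref)
    stop("tau_sen must be smaller than tau_ref: the method relies on the ",
         "sensitive lifetime (ns) being much shorter than the reference (us)",
         call. = FALSE)
  structure(list(k_sv = k_sv, tau_sen = tau_sen, tau_ref = tau_ref,
                 s_sen = s_sen, s_ref = s_ref),
            class = "film_params")
}

#' @export
print.film_params <- function(x, ...) {
  cat("Sensing film parameters\n")
  cat(sprintf("  K_SV    : %g /mmHg\n", x$k_sv))
  cat(sprintf("  tau_sen : %g ns\n", x$tau_sen * 1e9))
  cat(sprintf("  tau_ref : %g us\n", x$tau_ref * 1e6))
  cat(sprintf("  S_SEN   : %g nA per excitation unit\n", x$s_sen * 1e9))
  cat(sprintf("  S_REF   : %g nA per excitation unit\n", x$s_ref * 1e9))
  invisible(x)
}

#' LED excitation pulse and measurement-window timing
#'
#' One measurement cycle: the LED turns on at t = 0, the film response is
#' allowed to stabilize for `t_stabilize`, the excitation window `t1`
#' (Count1) follows, the LED turns off at `t_stabilize + t1`, and the decay
#' window (Count2) spans `[t_d_sen, t_d_ref]` measured from LED turn-off.
#' `t_d_sen > 0` skips the fast residual of the sensitive luminophore.
#'
#' @param i_ext Excitation intensity, arbitrary units (cancels out of the
#'   luminescence ratio).
#' @param t_stabilize LED-on stabilization time before counting, seconds.
#' @param t1 Counted excitation window, seconds.
#' @param t_d_sen Start of the decay-count window after LED turn-off, seconds.
#' @param t_d_ref End of the decay-count window after LED turn-off, seconds.
#' @return An object of class `excitation_profile`.
#' @examples
#' excitation_profile()
#' @export
excitation_profile <- function(i_ext = 1, t_stabilize = 10e-6, t1 = 30e-6,
                               t_d_sen = 50e-9, t_d_ref = 6e-6) {
  if (!is.numeric(i_ext) || i_ext <= 0)
    stop("i_ext must be a positive number", call. = FALSE)
  if (t1 <= 0) stop("t1 must be positive", call. = FALSE)
  if (t_stabilize < 0) stop("t_stabilize must be non-negative", call. = FALSE)
  if (t_d_sen < 0 || t_d_sen >= t_d_ref)
    stop("decay window requires 0 <= t_d_sen < t_d_ref", call. = FALSE)
  structure(list(i_ext = i_ext, t_stabilize = t_stabilize, t1 = t1,
                 t_d_sen = t_d_sen, t_d_ref = t_d_ref),
            class = "excitation_profile")
}

#' @export
print.excitation_profile <- function(x, ...) {
  cat("Excitation profile\n")
  cat(sprintf("  i_ext       : %g (a.u.)\n", x$i_ext))
  cat(sprintf("  t_stabilize : %g us\n", x$t_stabilize * 1e6))
  cat(sprintf("  T1          : %g us\n", x$t1 * 1e6))
  cat(sprintf("  decay window: [%g, %g] us after LED-off\n",
              x$t_d_sen * 1e6, x$t_d_ref * 1e6))
  invisible(x)
}

#' Steady-state photocurrents of the two luminophores
#'
#' The sensitive luminophore is quenched following Stern-Volmer,
#' `i_sen = i_ext * s_sen / (1 + k_sv * pco2)`; the reference is
#' CO2-independent, `i_ref = i_ext * s_ref`.
#'
#' @param pco2 CO2 partial pressure, mmHg (non-negative).
#' @param film A [film_params()] object.
#' @param excitation An [excitation_profile()] object.
#' @return List with elements `i_sen` and `i_ref`, amperes.
#' @examples
#' luminophore_intensities(40, film_params(), excitation_profile())
#' @export
luminophore_intensities <- function(pco2, film = film_params(),
                                    excitation = excitation_profile()) {
  if (any(pco2 < 0)) stop("pco2 must be non-negative", call. = FALSE)
  if (excitation$i_ext <= 0) stop("i_ext must be positive", call. = FALSE)
  list(i_sen = excitation$i_ext * film$s_sen / (1 + film$k_sv * pco2),
       i_ref = rep_len(excitation$i_ext * film$s_ref, length(pco2)))
}

#' Time-domain photocurrent of the sensing film
#'
#' During LED-on each luminophore's contribution rises as a first-order
#' approach to its steady photocurrent with its own lifetime; after the LED
#' turns off at `t_stabilize + t1` each contribution decays exponentially
#' with its lifetime. The waveform is continuous at turn-off.
#'
#' @param t Time since LED turn-on, seconds; must lie within one measurement
#'   cycle `[0, t_stabilize + t1 + t_d_ref]`. Vectorized.
#' @inheritParams luminophore_intensities
#' @return Photocurrent, amperes.
#' @examples
#' photocurrent_waveform(c(0, 20e-6, 41e-6), 0)
#' @export
photocurrent_waveform <- function(t, pco2, film = film_params(),
                                  excitation = excitation_profile()) {
  t_off <- excitation$t_stabilize + excitation$t1
  t_end <- t_off + excitation$t_d_ref
  if (any(t < 0 | t > t_end))
    stop(sprintf("t outside the measurement cycle [0, %g] s", t_end),
         call. = FALSE)
  iv <- luminophore_intensities(pco2, film, excitation)
  comp <- function(i0, tau) {
    on <- t <= t_off
    out <- numeric(length(t))
    out[on] <- i0 * (1 - exp(-t[on] / tau))
    amp <- i0 * (1 - exp(-t_off / tau))
    out[!on] <- amp * exp(-(t[!on] - t_off) / tau)
    out
  }
  comp(iv$i_sen, film$tau_sen) + comp(iv$i_ref, film$tau_ref)
}

#' Film response at a given CO2 level
#'
#' Convenience constructor bundling the steady photocurrents with the
#' excitation/decay areas and the luminescence ratio.
#'
#' @inheritParams luminophore_intensities
#' @param mode Area model for the decay window, see [area_a2()].
#' @return Object of class `film_response` with fields `i_sen`, `i_ref`
#'   (amperes), `a1`, `a2` (coulombs) and `lr`.
#' @export
film_response <- function(pco2, film = film_params(),
                          excitation = excitation_profile(),
                          mode = c("approximate", "exact")) {
  mode <- match.arg(mode)
  iv <- luminophore_intensities(pco2, film, excitation)
  resp <- structure(c(iv, list(a1 = NA_real_, a2 = NA_real_, lr = NA_real_)),
                    class = "film_response")
  resp$a1 <- area_a1(resp, excitation)
  resp$a2 <- area_a2(resp, film, excitation, mode)
  resp$lr <- resp$a1 / resp$a2
  resp
}

#' @export
print.film_response <- function(x, ...) {
  cat("Film response\n")
  cat(sprintf("  i_sen = %.4g nA, i_ref = %.4g nA\n",
              x$i_sen * 1e9, x$i_ref * 1e9))
  cat(sprintf("  A1 = %.6g pC, A2 = %.6g pC, LR = %.4f\n",
              x$a1 * 1e12, x$a2 * 1e12, x$lr))
  invisible(x)
}

#' Excitation-window area A1
#'
#' Integrated luminescence charge while the LED is on and the film has
#' stabilized: `A1 = (i_sen + i_ref) * t1`.
#'
#' @param response A list/`film_response` with `i_sen`, `i_ref` (amperes).
#' @param excitation An [excitation_profile()].
#' @return Charge, coulombs.
#' @export
area_a1 <- function(response, excitation = excitation_profile()) {
  (response$i_sen + response$i_ref) * excitation$t1
}

#' Decay-window area A2
#'
#' In `approximate` mode the short-lifetime term is dropped and the decay
#' window is extended to `[0, Inf)`, giving `A2 = i_ref * tau_ref`. In
#' `exact` mode the closed-form integral over the actual window is returned:
#' `i_ref * tau_ref * (exp(-t_d_sen/tau_ref) - exp(-t_d_ref/tau_ref))` plus
#' the analogous sensitive-luminophore term.
#'
#' @inheritParams area_a1
#' @param film A [film_params()] object.
#' @param mode `"approximate"` or `"exact"`.
#' @return Charge, coulombs.
#' @export
area_a2 <- function(response, film = film_params(),
                    excitation = excitation_profile(),
                    mode = c("approximate", "exact")) {
  mode <- match.arg(mode)
  if (excitation$t_d_sen >= excitation$t_d_ref)
    stop("invalid decay window: t_d_sen must be < t_d_ref", call. = FALSE)
  if (mode == "approximate") return(response$i_ref * film$tau_ref)
  decay_int <- function(i0, tau) {
    i0 * tau * (exp(-excitation$t_d_sen / tau) -
                exp(-excitation$t_d_ref / tau))
  }
  decay_int(response$i_ref, film$tau_ref) +
    decay_int(response$i_sen, film$tau_sen)
}

#' Luminescence ratio LR as a function of CO2 partial pressure
#'
#' `LR = A1/A2`. In `approximate` mode this is the textbook ratiometric
#' model `(s_sen/s_ref / (1 + k_sv * pco2) + 1) * t1 / tau_ref`; the
#' excitation intensity cancels exactly, which is the point of dual lifetime
#' referencing. `exact` mode uses the exact decay-window integral of
#' [area_a2()] instead of `i_ref * tau_ref`, which is the quantity a
#' converter counting over a finite decay window actually measures.
#'
#' @inheritParams luminophore_intensities
#' @param mode Decay-area model, see [area_a2()].
#' @return Dimensionless ratio. Vectorized over `pco2`.
#' @examples
#' luminescence_ratio(c(0, 40, 76))
#' @export
luminescence_ratio <- function(pco2, film = film_params(),
                               excitation = excitation_profile(),
                               mode = c("approximate", "exact")) {
  mode <- match.arg(mode)
  iv <- luminophore_intensities(pco2, film, excitation)
  a1 <- (iv$i_sen + iv$i_ref) * excitation$t1
  a2 <- if (mode == "approximate") {
    iv$i_ref * film$tau_ref
  } else {
    dint <- function(tau) exp(-excitation$t_d_sen / tau) -
      exp(-excitation$t_d_ref / tau)
    iv$i_ref * film$tau_ref * dint(film$tau_ref) +
      iv$i_sen * film$tau_sen * dint(film$tau_sen)
  }
  a1 / a2
}

#' Invert the luminescence ratio to a CO2 partial pressure
#'
#' Closed-form inverse of [luminescence_ratio()]. The physical range of LR
#' runs from `t1/tau_ref` (fully quenched, `pco2 -> Inf`, open) up to the
#' unquenched value at `pco2 = 0` (attained, closed); values outside this
#' interval raise an error reporting the interval. In `exact` mode the
#' finite decay window and the short-lifetime contamination are accounted
#' for, so counts measured over the configured windows invert without bias.
#'
#' @param lr Measured luminescence ratio.
#' @inheritParams luminescence_ratio
#' @return CO2 partial pressure, mmHg. Vectorized over `lr`.
#' @examples
#' pco2_from_lr(luminescence_ratio(40))
#' @export
pco2_from_lr <- function(lr, film = film_params(),
                         excitation = excitation_profile(),
                         mode = c("approximate", "exact")) {
  mode <- match.arg(mode)
  lo <- luminescence_ratio(Inf, film, excitation, mode)
  hi <- luminescence_ratio(0, film, excitation, mode)
  tol <- 1e-12 * hi
  if (any(lr <= lo + tol | lr > hi + tol))
    stop(sprintf(
      "lr outside the physical range (%.6g, %.6g]: lower limit is full quenching, upper is pco2 = 0",
      lo, hi), call. = FALSE)
  lr <- pmin(lr, hi)  # clamp floating-point overshoot of the pco2 = 0 bound
  s <- film$s_sen / film$s_ref
  if (mode == "approximate") {
    # lr * tau_ref / t1 - 1 = s / (1 + k_sv * pco2)
    x <- (lr * film$tau_ref / excitation$t1 - 1) / s
  } else {
    dint <- function(tau) exp(-excitation$t_d_sen / tau) -
      exp(-excitation$t_d_ref / tau)
    cr <- film$tau_ref * dint(film$tau_ref)
    cs <- film$tau_sen * dint(film$tau_sen)
    # lr = (s*x + 1) * t1 / (cr + s*x*cs), Moebius in x = 1/(1 + k_sv*pco2)
    x <- (lr * cr - excitation$t1) / (s * (excitation$t1 - lr * cs))
  }
  x <- pmin(x, 1)
  (1 / x - 1) / film$k_sv
}
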
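#' Piecewise-constant bench test current
#'
#' Describes the synthetic test current that stands in for the external
#' current-steering DAC used to characterize the converter: a sequence of
#' constant-current phases, plus the photodiode dark current and optional
#' Gaussian current noise redrawn once per phase per cycle.
#'
#' @param phases Two-column matrix/data.frame or list of `c(duration_s,
#'   current_A)` pairs.
#' @param dark_current Additive dark current, amperes (default 10 pA).
#' @param current_noise_rms RMS of Gaussian current noise added per phase
#'   per cycle, amperes (default 0).
#' @param repeat_cycles Number of cycles the factory will produce before
#'   recycling (bookkeeping only; factories are unlimited).
#' @return Object of class `test_current_spec`.
#' @examples
#' test_current_spec(list(c(25e-6, 5e-6), c(5e-6, 5e-6)))
#' @export
test_current_spec <- function(phases, dark_current = 10e-12,
                              current_noise_rms = 0, repeat_cycles = 1L) {
  if (is.data.frame(phases) || is.matrix(phases)) {
    phases <- lapply(seq_len(nrow(phases)),
                     function(i) as.numeric(phases[i, 1:2]))
  }
  if (length(phases) == 0) stop("at least one phase required", call. = FALSE)
  dur <- vapply(phases, `[`, numeric(1), 1)
  cur <- vapply(phases, `[`, numeric(1), 2)
  if (any(dur <= 0)) stop("phase durations must be positive", call. = FALSE)
  if (any(cur < 0)) stop("phase currents must be non-negative", call. = FALSE)
  if (current_noise_rms < 0) stop("current_noise_rms must be >= 0", call. = FALSE)
  structure(list(durations = dur, currents = cur,
                 dark_current = dark_current,
                 current_noise_rms = current_noise_rms,
                 repeat_cycles = as.integer(repeat_cycles)),
            class = "test_current_spec")
}

# Private RNG stream for a factory, so interleaved factories with the same
# seed produce identical cycle sequences regardless of other RNG use.
rng_stream <- function(seed) {
  if (is.null(seed)) return(NULL)
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env
}

rng_eval <- function(stream, fn) {
  if (is.null(stream)) return(fn())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, globalenv())
  out <- fn()
  stream$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  out
}

new_waveform <- function(current, charge, span, label) {
  structure(list(current = current, charge = charge, span = span,
                 label = label), class = "cdc_waveform")
}

#' @export
print.cdc_waveform <- function(x, ...) {
  cat(sprintf("CDC input waveform [%s], span %g us\n", x$label, x$span * 1e6))
  invisible(x)
}

#' Evaluate a waveform's current at given times
#' @param waveform A `cdc_waveform` object.
#' @param t Times, seconds (vectorized).
#' @return Current, amperes.
#' @export
waveform_current <- function(waveform, t) waveform$current(t)

#' Closed-form charge delivered by a waveform over time intervals
#'
#' Exact integral of the waveform current over `[a, b]`; `a` and `b` may be
#' vectors of interval endpoints. Used by the conversion loop to obtain the
#' per-clock-period input charge without sub-stepping.
#'
#' @param waveform A `cdc_waveform` object.
#' @param a,b Interval endpoints, seconds.
#' @return Charge, coulombs.
#' @export
waveform_charge <- function(waveform, a, b) waveform$charge(a, b)

#' Waveform factory for piecewise-constant bench currents
#'
#' Returns a zero-argument function producing one cycle's waveform per call.
#' With `current_noise_rms > 0` each phase current receives an independent
#' Gaussian perturbation each cycle; with a fixed seed the sequence of
#' waveforms is reproducible.
#'
#' @param spec A [test_current_spec()].
#' @param seed Optional integer seed for the noise draws.
#' @return A function; each call returns a `cdc_waveform` whose time origin
#'   is the start of the first phase.
#' @examples
#' fac <- constant_current_factory(test_current_spec(list(c(30e-6, 1e-6))))
#' wf <- fac()
#' waveform_charge(wf, 0, 30e-6)  # ~30 pC
#' @export
constant_current_factory <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "test_current_spec"))
  stream <- rng_stream(seed)
  edges <- c(0, cumsum(spec$durations))
  span <- edges[length(edges)]
  function() {
    cur <- spec$currents + spec$dark_current
    if (spec$current_noise_rms > 0)
      cur <- cur + rng_eval(stream, function()
        stats::rnorm(length(cur), 0, spec$current_noise_rms))
    cur <- pmax(cur, 0)
    current <- function(t) {
      idx <- findInterval(t, edges, rightmost.closed = TRUE,
                          all.inside = TRUE)
      cur[idx]
    }
    charge <- function(a, b) {
      # integral of a step function: sum over overlapped phases
      vapply(seq_along(a), function(i) {
        lo <- pmax(a[i], edges[-length(edges)])
        hi <- pmin(b[i], edges[-1])
        sum(pmax(hi - lo, 0) * cur)
      }, numeric(1))
    }
    new_waveform(current, charge, span, "piecewise-constant test current")
  }
}

#' Waveform factory for the film's dual-exponential photocurrent
#'
#' Binds the film photophysics to the conversion loop: each call yields one
#' measurement cycle's photocurrent waveform (time origin at LED turn-on).
#' `cycle_jitter` applies an independent uniform relative perturbation of
#' the excitation intensity per cycle, emulating LED intensity fluctuation;
#' the luminescence ratio is invariant to it by construction.
#'
#' @inheritParams luminophore_intensities
#' @param seed Optional integer seed for jitter draws.
#' @param cycle_jitter Half-width of the uniform relative `i_ext`
#'   perturbation (e.g. 0.1 for +/-10 percent); 0 disables it.
#' @return A function; each call returns a `cdc_waveform` spanning
#'   `t_stabilize + t1 + t_d_ref`.
#' @examples
#' fac <- film_waveform_factory(40)
#' wf <- fac()
#' waveform_current(wf, 20e-6)
#' @export
film_waveform_factory <- function(pco2, film = film_params(),
                                  excitation = excitation_profile(),
                                  seed = NULL, cycle_jitter = 0) {
  stopifnot(cycle_jitter >= 0, cycle_jitter < 1)
  stream <- rng_stream(seed)
  t_off <- excitation$t_stabilize + excitation$t1
  span <- t_off + excitation$t_d_ref
  base <- luminophore_intensities(pco2, film, excitation)
  function() {
    scale <- if (cycle_jitter > 0)
      rng_eval(stream, function()
        1 + stats::runif(1, -cycle_jitter, cycle_jitter)) else 1
    i_sen <- base$i_sen * scale
    i_ref <- base$i_ref * scale
    amp <- function(i0, tau) i0 * (1 - exp(-t_off / tau))
    current <- function(t) {
      comp <- function(i0, tau) {
        on <- t <= t_off
        out <- numeric(length(t))
        out[on] <- i0 * (1 - exp(-t[on] / tau))
        out[!on] <- amp(i0, tau) * exp(-(t[!on] - t_off) / tau)
        out
      }
      comp(i_sen, film$tau_sen) + comp(i_ref, film$tau_ref)
    }
    # exact integral of one luminophore's contribution over [a, b]
    comp_charge <- function(i0, tau, a, b) {
      rise <- function(x, y)  # integral of i0*(1 - exp(-t/tau)) on [x, y]
        i0 * ((y - x) + tau * (exp(-y / tau) - exp(-x / tau)))
      decay <- function(x, y) # integral of amp*exp(-(t - t_off)/tau)
        amp(i0, tau) * tau * (exp(-(x - t_off) / tau) -
                              exp(-(y - t_off) / tau))
      lo_on <- pmin(a, t_off); hi_on <- pmin(b, t_off)
      lo_off <- pmax(a, t_off); hi_off <- pmax(b, t_off)
      rise(lo_on, hi_on) + decay(lo_off, hi_off)
    }
    charge <- function(a, b) {
      comp_charge(i_sen, film$tau_sen, a, b) +
        comp_charge(i_ref, film$tau_ref, a, b)
    }
    new_waveform(current, charge, span,
                 sprintf("film photocurrent, pco2 = %g mmHg", pco2))
  }
}

#' Export a waveform as a sampled data frame
#'
#' @param waveform A `cdc_waveform`.
#' @param n Number of equally spaced samples over the waveform span.
#' @return `data.frame` with columns `time_s` and `current_A`.
#' @export
waveform_table <- function(waveform, n = 512) {
  t <- seq(0, waveform$span, length.out = n)
  data.frame(time_s = t, current_A = waveform$current(t))
}
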
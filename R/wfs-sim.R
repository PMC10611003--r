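# Random-phasor model of feedback wavefront shaping through a strongly
# scattering slab. Each SLM segment contributes a complex field t_n
# (i.i.d. circular Gaussian -- fully developed speckle) whose phase is
# controllable; the detected signal is the intensity of the coherent sum,
# optionally with an uncontrollable background floor (residual amplitude
# modulation of a phase-only modulator) and multiplicative detector noise.

#' Theoretical phase-only enhancement
#'
#' Expected intensity enhancement of an optimized focus over the mean
#' speckle background for phase-only control of `N` statistically
#' independent segments:
#' \deqn{\eta = \frac{\pi}{4}(N - 1) + 1.}
#' Fractional `N` is accepted (partial illumination of a single segment
#' maps to an effective segment number below one).
#'
#' @param n_segments segment count `N > 0`, possibly fractional.
#' @return The theoretical enhancement \eqn{\eta}.
#' @examples
#' enhancement_theory(64)    # 50.48
#' @export
enhancement_theory <- function(n_segments) {
  if (any(n_segments <= 0)) stop("'n_segments' must be > 0")
  (pi / 4) * (n_segments - 1) + 1
}

#' Random speckle transmission field for a segmented wavefront
#'
#' Draws the per-segment complex transmission coefficients
#' \eqn{t_n \sim \mathcal{CN}(0, 1)} (independent, fully developed
#' speckle) and bundles the detector model parameters.
#'
#' @param n_segments number of controllable segments `N >= 1`.
#' @param seed explicit RNG seed for the field draw.
#' @param background_leak uncontrollable intensity fraction `beta` in
#'   `[0, 1)`: a floor of `beta` times the mean speckle intensity is added
#'   to every detected signal (models the residual amplitude modulation of
#'   a phase-only SLM; the measured value behind the phantoms is 0.056).
#' @param noise_sigma relative standard deviation of multiplicative
#'   Gaussian detector noise per measurement.
#' @param amplitude optional common scale applied to all `t_n` (e.g. bulk
#'   attenuation by absorption); the enhancement statistics are invariant
#'   under it.
#' @return Object of class `phasor_field`.
#' @export
phasor_field <- function(n_segments, seed, background_leak = 0,
                         noise_sigma = 0, amplitude = 1) {
  stopifnot(n_segments >= 1, background_leak >= 0, background_leak < 1,
            noise_sigma >= 0, amplitude > 0)
  if (missing(seed)) stop("an explicit 'seed' is required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  n <- as.integer(n_segments)
  t <- amplitude * complex(real = rnorm(n), imaginary = rnorm(n)) / sqrt(2)
  structure(list(n_segments = n, t = t, background_leak = background_leak,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phasor_field")
}

# detected intensity for field sum E (vectorized), with leak floor and
# multiplicative noise; the floor scales with the mean speckle intensity so
# the whole detector model is invariant under a common amplitude scale
wfs_detect <- function(field, E, noise = TRUE) {
  i_mean <- sum(Mod(field$t)^2)
  I <- Mod(E)^2 + field$background_leak * i_mean
  if (noise && field$noise_sigma > 0)
    I <- pmax(0, I * (1 + field$noise_sigma * rnorm(length(I))))
  I
}

#' Stepwise sequential optimization of segment phases
#'
#' Runs the stepwise sequential algorithm (SSA): each segment in turn has
#' its phase swept over `n_phase_steps` equispaced values while all other
#' phases are held at the current working pattern; the phase giving the
#' largest detected intensity is committed when the segment's sweep
#' completes. After one full cycle the focus intensity `i_peak` is taken as
#' the largest detected value of a verification sweep of the first segment
#' (the argmax estimator -- with detector noise this reproduces the upward
#' bias of measured enhancements at small `N`), and the background
#' `i_background` as the mean detected intensity over `n_background`
#' uniformly random phase patterns.
#'
#' @param field a [phasor_field()].
#' @param n_phase_steps number of phase steps `K >= 3` per segment sweep.
#' @param n_background number of random patterns `M >= 1` for the
#'   background estimate.
#' @param seed explicit RNG seed for the measurement noise and background
#'   patterns.
#' @return Object of class `wfs_run`: `optimized_phases`, `i_peak`,
#'   `i_background`, `pbr` (= `eta`, the measured enhancement), and the
#'   settings.
#' @export
run_ssa <- function(field, n_phase_steps = 16L, n_background = 100L, seed) {
  stopifnot(inherits(field, "phasor_field"))
  if (n_phase_steps < 3) stop("'n_phase_steps' must be >= 3")
  if (n_background < 1) stop("'n_background' must be >= 1")
  if (missing(seed)) stop("an explicit 'seed' is required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  K <- as.integer(n_phase_steps)
  N <- field$n_segments
  phis <- 2 * pi * (0:(K - 1)) / K
  phases <- numeric(N)
  E_tot <- sum(field$t * exp(1i * phases))
  for (n in seq_len(N)) {
    E_rest <- E_tot - field$t[n] * exp(1i * phases[n])
    I_meas <- wfs_detect(field, E_rest + field$t[n] * exp(1i * phis))
    best <- which.max(I_meas)
    phases[n] <- phis[best]
    E_tot <- E_rest + field$t[n] * exp(1i * phases[n])
  }
  # verification sweep of segment 1: peak = best observed detected value
  E_rest <- E_tot - field$t[1] * exp(1i * phases[1])
  I_fin <- wfs_detect(field, E_rest + field$t[1] * exp(1i * phis))
  i_peak <- max(I_fin)
  phases[1] <- phis[which.max(I_fin)]

  bg <- vapply(seq_len(as.integer(n_background)), function(m) {
    ph <- runif(N, 0, 2 * pi)
    wfs_detect(field, sum(field$t * exp(1i * ph)))
  }, numeric(1))
  i_background <- mean(bg)
  pbr <- i_peak / i_background
  structure(list(optimized_phases = phases, i_peak = i_peak,
                 i_background = i_background, pbr = pbr, eta = pbr,
                 n_segments = N, n_phase_steps = K,
                 n_background = as.integer(n_background),
                 seed = as.integer(seed)),
            class = "wfs_run")
}

#' @export
print.wfs_run <- function(x, ...) {
  cat(sprintf("wfs_run: N = %d, K = %d -> PBR = %.3f (theory %.3f)\n",
              x$n_segments, x$n_phase_steps, x$pbr,
              enhancement_theory(x$n_segments)))
  invisible(x)
}

#' Ensemble of SSA runs
#'
#' Repeats field draw + SSA optimization over independent speckle
#' realizations and summarizes the measured enhancement.
#'
#' @param n_segments segment count per run.
#' @param n_realizations number of independent (field, optimization)
#'   realizations.
#' @param seed base seed; realization `k` uses `seed + k` for the field and
#'   `seed + 50000 + k` for the measurement stream.
#' @param ... further arguments to [phasor_field()] (`background_leak`,
#'   `noise_sigma`, `amplitude`).
#' @param n_phase_steps,n_background forwarded to [run_ssa()].
#' @return List with `pbr` (vector), `mean`, `se`, and `theory`.
#' @export
wfs_ensemble <- function(n_segments, n_realizations = 50L, seed = 1L,
                         n_phase_steps = 16L, n_background = 100L, ...) {
  pbr <- vapply(seq_len(n_realizations), function(k) {
    f <- phasor_field(n_segments, seed = seed + k, ...)
    run_ssa(f, n_phase_steps, n_background, seed = seed + 50000L + k)$pbr
  }, numeric(1))
  list(pbr = pbr, mean = mean(pbr), se = sd(pbr) / sqrt(length(pbr)),
       theory = enhancement_theory(n_segments))
}

#' Laser-power adjustment plan from partial angular transmittances
#'
#' Computes per-sample laser power factors so that the power arriving in
#' the detection aperture is the same for every phantom:
#' `factor_i = T_NA(reference) / T_NA(sample_i)`; the reference sample gets
#' factor 1.
#'
#' @param samples list of [optical_slab()] objects with non-`NULL` `id`s.
#' @param reference_id id of the reference sample.
#' @param aperture a [detection_aperture()].
#' @param order odd P_N truncation order for the transmittance solves.
#' @return Data frame with columns `id`, `t_na`, `power_factor`.
#' @export
power_plan <- function(samples, reference_id, aperture, order = 15L) {
  ids <- vapply(samples, function(s) as.character(s$id %||% NA), character(1))
  if (anyNA(ids)) stop("every sample needs an 'id'")
  if (!reference_id %in% ids)
    stop("reference_id '", reference_id, "' not present in the sample list")
  t_na <- vapply(samples, function(s)
    partial_transmittance(s, aperture, order = order)$t_na, numeric(1))
  if (any(t_na <= 0)) stop("T_NA must be > 0 for every sample")
  ref <- t_na[match(reference_id, ids)]
  data.frame(id = ids, t_na = t_na, power_factor = ref / t_na,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
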
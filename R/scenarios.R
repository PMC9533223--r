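#' Bundled simulation scenarios
#'
#' Fixed desk-scale study conditions used throughout the package's
#' validation: all parameters are rescaled so that the per-generation
#' products `4*N*mu` and `4*N*rho` stay in a realistic range for a
#' perennial outcrossing tree cohort while populations stay small enough
#' to iterate forward in time on a laptop. See the methods vignette for
#' the rationale behind each value.
#'
#' * `scenario_neutral()`: one population, N = 200, L = 500 kb,
#'   mu = 1.5e-7, rho = 5e-7, the baseline for neutral-expectation checks
#'   (`theta = 4*N*mu = 1.2e-4` per bp).
#' * `scenario_sweep()`: two populations `FF`/`SF` (N = 200, L = 1 Mb,
#'   mu = 2e-7, rho = 2.5e-7) split 300 generations ago; optionally a
#'   hard sweep (s = 0.1, additive) injected in `FF` 120 generations
#'   before present at position 250 kb and required to fix, so sampling
#'   happens right after fixation, when the haplotype signal peaks.
#' * `scenario_pulse()`: caterpillar (((P1, P2), P3), OUT) with N = 50,
#'   L = 500 kb, mu = rho = 5e-6, splits at 50/150/300 generations and an
#'   optional one-generation pulse P3 -> P2 (default fraction 0.2) 5
#'   generations before present.
#' * `scenario_divergent()`: two populations `A`/`B` (N = 100, L = 500 kb,
#'   mu = 1e-6) split 100 generations ago; neutral background for
#'   [implant_divergence_segment()].
#'
#' @param seed Master seed.
#' @param sweep Include the hard sweep (`scenario_sweep`).
#' @param rho Recombination rate for the sweep scenario (default 2.5e-7,
#'   giving a sweep footprint of roughly `s / (rho * log(2*N*s))` ~ 110 kb,
#'   comfortably inside one 500-kb ranking window).
#' @param fraction Pulse admixture fraction (`scenario_pulse`); 0 disables
#'   the pulse.
#' @return A [sim_params()] object.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
scenario_neutral <- function(seed) {
  sim_params(L = 5e5, N = 200, mu = 1.5e-7, rho = 5e-7,
             populations = "A", split_times = numeric(0),
             sample_sizes = 20, seed = seed)
}

#' @rdname scenarios
#' @export
scenario_sweep <- function(seed, sweep = TRUE, rho = 2.5e-7) {
  sim_params(L = 1e6, N = 200, mu = 2e-7, rho = rho,
             populations = c("FF", "SF"), split_times = 300,
             sample_sizes = 20,
             sweep = if (sweep) list(pop = "FF", position = 250000, s = 0.1,
                                     start = 120, require_fixation = TRUE),
             seed = seed)
}

#' @rdname scenarios
#' @export
scenario_pulse <- function(seed, fraction = 0.2) {
  sim_params(L = 5e5, N = 50, mu = 5e-6, rho = 5e-6,
             populations = c("P1", "P2", "P3", "OUT"),
             split_times = c(300, 150, 50),
             sample_sizes = 20,
             pulse = if (fraction > 0) list(source = "P3", target = "P2",
                                            fraction = fraction, time = 5),
             seed = seed)
}

#' @rdname scenarios
#' @export
scenario_divergent <- function(seed) {
  sim_params(L = 5e5, N = 100, mu = 1e-6, rho = 1e-6,
             populations = c("A", "B"), split_times = 100,
             sample_sizes = 20, seed = seed)
}
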
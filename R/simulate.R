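#' Simulate multi-contrast k-space data
#'
#' Applies the non-linear forward model to ground-truth parameter maps and
#' adds complex Gaussian noise whose total complex standard deviation is
#' `noise_fraction` times the mean modulus of the noiseless samples
#' (independent real/imaginary components of sd `sigma / sqrt(2)`).
#' `noise_fraction = 0` returns the noiseless data exactly.
#'
#' @param maps ground-truth [parameter_maps()].
#' @param protocol an [acquisition_protocol()].
#' @param schedule a sampling schedule consistent with the protocol.
#' @param noise_fraction non-negative scalar (the study value is 0.05).
#' @param seed integer seed for the noise draw.
#' @param enc optionally, a prebuilt [encoding_operator()] for this schedule
#'   (reused to avoid replanning the NUFFT).
#' @return an object of class `kspace_data`: list with `samples` (list of
#'   complex vectors per contrast, in the *unnormalized* acquisition
#'   convention of the raw encoding), `schedule`, `protocol`, `noise_sigma`,
#'   `noise_fraction`, `seed`.
#' @export
simulate_kspace <- function(maps, protocol, schedule, noise_fraction = 0.05,
                            seed = 1L, enc = NULL) {
  stopifnot(inherits(maps, "parameter_maps"),
            inherits(protocol, "acquisition_protocol"),
            identical(dim(maps$s0),
                      c(protocol$matrix_size, protocol$matrix_size)),
            noise_fraction >= 0)
  if (is.null(enc))
    enc <- encoding_operator(schedule, protocol$matrix_size,
                             protocol$n_contrasts)
  clean <- enc$forward_raw(phase_embed(decay_images(maps, protocol$tsl),
                                       maps$phase))
  sigma <- 0
  samples <- clean
  if (noise_fraction > 0) {
    sigma <- noise_fraction * mean(abs(unlist(clean)))
    samples <- with_seed(seed, lapply(clean, function(m) {
      m + complex(real = stats::rnorm(length(m), sd = sigma / sqrt(2)),
                  imaginary = stats::rnorm(length(m), sd = sigma / sqrt(2)))
    }))
  }
  structure(list(samples = samples, schedule = schedule, protocol = protocol,
                 noise_sigma = sigma, noise_fraction = noise_fraction,
                 seed = as.integer(seed)),
            class = "kspace_data")
}

#' Normalize acquired samples to an encoding operator's scale
#'
#' Raw simulated/acquired samples follow the unnormalized encoding; the
#' solvers work with the unit-norm encoding, so the data vector must be
#' divided by the same norm factor.
#' @param data a `kspace_data` object.
#' @param enc the [encoding_operator()] used for reconstruction.
#' @return list of complex sample vectors on the normalized scale.
#' @export
normalized_samples <- function(data, enc) {
  lapply(data$samples, `/`, enc$norm_factor)
}
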
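# Shared fixtures: small phantoms are built once per run and cached, so the
# heavier tests (segmentation, acceptance) do not regenerate them.
.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(key, ...) {
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(phantom_spec(...))
  .phantom_cache[[key]]
}

noiseless_phantom <- function() {
  cached_phantom("noiseless", grid_shape = c(40L, 40L, 40L),
                 n_lesions = 4L, noise_sd = 0, seed = 42L)
}

# SNR mu_nawm/noise_sd = 100/5 = 20, the lowest SNR the pipeline is
# validated at; k_less = 3 is the weakest lesion contrast in the WMH
# definition.
noisy_phantom <- function() {
  cached_phantom("noisy", grid_shape = c(40L, 40L, 40L),
                 n_lesions = 4L, noise_sd = 5, k_less = 3, seed = 42L)
}

lownoise_phantom <- function() {
  cached_phantom("lownoise", grid_shape = c(40L, 40L, 40L),
                 n_lesions = 4L, noise_sd = 1, seed = 42L)
}

wm_candidate_mask <- function(ph) ph$truth$masks$nawm | ph$truth$masks$wmh_total

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

random_mask <- function(dims, p = 0.3) array(runif(prod(dims)) < p, dim = dims)
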
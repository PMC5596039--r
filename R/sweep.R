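#' Random sweep of the metric over its validity region
#'
#' Draws random parameter sets satisfying the conventions under which the
#' damage metric is defined — WMH mean at least 3 NAWM SDs above the NAWM
#' mean but no higher than the intensity ceiling, NAWM SD at most
#' `(Imax - Imin)/2`, and the NAWM mean between 50% and two-thirds of the
#' ceiling (the NAWM intensity convention for T2W-based sequences) — and
#' evaluates [wm_damage()] on each. Within this region the metric is
#' bounded in \[0, 1\]; the sweep is the empirical check of that bound.
#'
#' @param n Number of random draws.
#' @param seed RNG seed (deterministic given the seed).
#' @param imax Intensity ceiling (the metric is scale-invariant, so the
#'   choice is immaterial).
#' @return A tibble with one row per draw: `i_nawm`, `sd_nawm`, `i_wmh`,
#'   `imin`, `vol_wmh_ml`, `vol_nawm_ml`, `wm_damage`.
#' @examples
#' max(wm_damage_sweep(100, seed = 1)$wm_damage) <= 1
#' @export
wm_damage_sweep <- function(n = 10000L, seed = NULL, imax = 100) {
  draws <- with_seed(seed, {
    imin <- runif(n, 0, 0.25 * imax)
    i_nawm <- runif(n, 0.5 * imax, 2 / 3 * imax)
    sd_max <- pmin((imax - imin) / 2, (imax - i_nawm) / 3)
    sd_nawm <- runif(n, 0, sd_max)
    i_wmh <- runif(n, i_nawm + 3 * sd_nawm, imax)
    vol_wmh <- runif(n, 1e-3, 200)
    vol_nawm <- runif(n, 1e-3, 1500)
    tibble(i_nawm = i_nawm, sd_nawm = sd_nawm, i_wmh = i_wmh, imin = imin,
           vol_wmh_ml = vol_wmh, vol_nawm_ml = vol_nawm)
  })
  draws$wm_damage <- vapply(seq_len(n), function(i) {
    wm_damage(list(mean = draws$i_wmh[i]),
              list(mean = draws$i_nawm[i]),
              vol_wmh_ml = draws$vol_wmh_ml[i],
              vol_nawm_ml = draws$vol_nawm_ml[i])$wm_damage
  }, numeric(1))
  draws
}
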
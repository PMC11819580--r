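#' Aye-aye study cohort: per-trio mutation counts and callable sizes
#'
#' Per-trio summary of the 12-trio aye-aye pedigree cohort: parental ages at
#' conception (years), total autosomal DNMs, read-backed phased counts by
#' parent of origin, and the callability-corrected callable genome size
#' (haploid site count; the diploid factor of two enters the rate
#' denominator). This is the in-package transcription used by the worked
#' examples and the acceptance checks; rates are always recomputed from
#' counts and callable sizes, never stored.
#'
#' @return data.frame with columns `trio_id`, `paternal_age`, `maternal_age`,
#'   `n_mut`, `n_phased`, `n_paternal`, `n_maternal`, `callable_sum` (bp).
#' @seealso [baboon_trios()], [trio_design()]
#' @export
aye_aye_trios <- function() {
  data.frame(
    trio_id = c("100947", "100938", "100950", "100940", "100942", "100939",
                "100935", "100933", "100945", "100944", "100941", "100946"),
    paternal_age = c(22.0, 30.5, 16.8, 9.3, 17.5, 11.3, 8.5, 24.4, 15.6,
                     12.1, 20.7, 17.7),
    maternal_age = c(18.0, 13.7, 14.8, 7.4, 15.6, 9.4, 10.5, 26.5, 17.7,
                     14.1, 9.6, 6.7),
    n_mut = c(117L, 48L, 25L, 30L, 30L, 25L, 44L, 108L, 83L, 75L, 36L, 26L),
    n_phased = c(30L, 10L, 12L, 12L, 11L, 10L, 15L, 39L, 27L, 18L, 12L, 7L),
    n_paternal = c(7L, 9L, 9L, 7L, 11L, 9L, 9L, 16L, 11L, 10L, 11L, 4L),
    n_maternal = c(23L, 1L, 3L, 5L, 0L, 1L, 6L, 23L, 16L, 8L, 1L, 3L),
    callable_sum = c(1.67, 1.78, 1.86, 1.86, 1.85, 1.87, 1.86, 1.86, 1.87,
                     1.83, 1.81, 1.87) * 1e9,
    stringsAsFactors = FALSE
  )
}

#' Olive baboon study cohort: per-trio mutation counts and callable sizes
#'
#' The 21-trio baboon comparison cohort, in the same layout as
#' [aye_aye_trios()] plus mean sequencing depth. Missing parental ages are
#' `NA` (three trios lack one recorded age).
#'
#' @return data.frame with columns `trio_id`, `paternal_age`, `maternal_age`,
#'   `n_mut`, `n_phased`, `n_paternal`, `n_maternal`, `mean_depth`,
#'   `callable_sum` (bp).
#' @export
baboon_trios <- function() {
  data.frame(
    trio_id = c("39990", "39992", "40001", "40005", "16517", "19181",
                "26988", "28246", "15444", "16413", "17199", "18385",
                "19348", "7267", "8395", "7311", "10173", "11885",
                "14068", "14012", "13951"),
    paternal_age = c(5.5, 14.7, 9.9, 7.0, 9.5, 12.2, 14.5, 15.5, 8.2, 9.4,
                     10.4, 11.3, 12.5, 7.9, 9.5, 8.0, NA, 15.2, 18.6, 18.5,
                     18.4),
    maternal_age = c(6.1, 15.4, 6.5, 6.9, 6.0, 8.7, 10.9, 11.9, 8.7, 9.9,
                     11.0, 11.8, 13.0, NA, NA, 5.3, 12.9, 7.2, 10.7, 9.0,
                     10.4),
    n_mut = c(29L, 22L, 32L, 18L, 18L, 20L, 31L, 29L, 23L, 13L, 24L, 26L,
              11L, 35L, 17L, 18L, 23L, 33L, 39L, 24L, 34L),
    n_phased = c(16L, 14L, 19L, 12L, 12L, 8L, 13L, 16L, 11L, 7L, 10L, 17L,
                 5L, 19L, 11L, 10L, 16L, 10L, 13L, 7L, 10L),
    n_paternal = c(11L, 13L, 15L, 8L, 10L, 3L, 12L, 13L, 10L, 6L, 10L, 14L,
                   5L, 10L, 9L, 7L, 15L, 7L, 12L, 6L, 9L),
    n_maternal = c(5L, 1L, 4L, 4L, 2L, 5L, 1L, 3L, 1L, 1L, 0L, 3L, 0L, 9L,
                   2L, 3L, 1L, 3L, 1L, 1L, 1L),
    mean_depth = c(41.3, 41.7, 39.6, 40.8, 45.0, 49.9, 47.6, 45.3, 48.2,
                   48.4, 49.0, 53.6, 50.2, 48.3, 30.7, 30.4, 41.8, 55.9,
                   44.8, 30.9, 29.1),
    callable_sum = c(2.01, 1.99, 1.98, 2.03, 1.62, 1.48, 1.53, 1.64, 1.70,
                     1.71, 1.69, 1.64, 1.72, 1.67, 1.41, 1.49, 1.50, 1.65,
                     2.00, 1.56, 1.29) * 1e9,
    stringsAsFactors = FALSE
  )
}
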
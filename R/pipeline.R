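#' Run the full pedigree mutation analysis on a simulated or loaded cohort
#'
#' Orchestrates calling, callability-corrected rate estimation, read-traced
#' phasing, the parental-age regressions and the phasing summaries for one
#' cohort, returning a single report list. When `outdir` is given, the
#' per-trio table (study-table layout), fit summaries and the resolved
#' settings are written as TSV/JSON.
#'
#' @param gt cohort [genotype_table()].
#' @param ped a [pedigree()].
#' @param ages ages table (`child_id`, `paternal_age`, `maternal_age`).
#' @param evidence read-evidence table for phasing (optional; without it
#'   all mutations stay unphased).
#' @param depth_pass_sites haploid depth-passing site count per trio
#'   (scalar or named by child).
#' @param settings thresholds list; defaults mirror the published screen
#'   (`min_depth` 15, `gq_min` 60, `ab_min` 0.35, ABHet in [0.2, 0.8],
#'   phasing window 1000 bp, `max_depth_mode` "sigma4").
#' @param outdir optional output directory.
#' @return list of class `pedmut_report`: `mutations`, `per_trio`
#'   (counts, callability, callable size, rate, phased counts), `cohort`
#'   (rate/age summary), `phasing` (pooled), `alpha`, and `fits` (total +
#'   phased regressions, when enough trios have ages).
#' @export
run_pipeline <- function(gt, ped, ages, evidence = NULL,
                         depth_pass_sites, settings = list(),
                         outdir = NULL) {
  s <- utils::modifyList(list(min_depth = 15, gq_min = 60, ab_min = 0.35,
                              window = 1000, max_depth_mode = "sigma4",
                              min_votes = 1), settings)
  trios <- enumerate_trios(ped, ages)
  depth_means <- colMeans(gt$dp, na.rm = TRUE)

  called <- call_dnms(gt, trios, depth_means = depth_means,
                      min_depth = s$min_depth, gq_min = s$gq_min,
                      ab_min = s$ab_min, max_depth_mode = s$max_depth_mode)
  muts <- called$mutations
  if (!is.null(evidence) && nrow(muts))
    muts <- phase_mutations(muts, trios, gt, evidence, window = s$window,
                            min_votes = s$min_votes)

  dps <- if (length(depth_pass_sites) == 1L)
    stats::setNames(rep(depth_pass_sites, nrow(trios)), trios$child_id)
  else depth_pass_sites

  per <- lapply(seq_len(nrow(trios)), function(i) {
    trio <- trios[i, ]
    cb <- estimate_callability(trio, gt, depth_means,
                               min_depth = s$min_depth, gq_min = s$gq_min,
                               ab_min = s$ab_min,
                               max_depth_mode = s$max_depth_mode)
    n <- sum(muts$child_id == trio$child_id)
    callable <- dps[[trio$child_id]] * cb$callability
    r <- compute_trio_rate(n, callable, trio$child_id)
    cbind(r, callability = cb$callability,
          paternal_age = trio$paternal_age,
          maternal_age = trio$maternal_age)
  })
  per <- do.call(rbind, per)

  ph <- summarize_phasing(muts)
  per <- merge(per, ph$per_trio[, c("trio_id", "n_paternal", "n_maternal",
                                    "n_unphased")],
               by = "trio_id", all.x = TRUE)
  for (cc in c("n_paternal", "n_maternal", "n_unphased"))
    per[[cc]][is.na(per[[cc]])] <- 0L
  alpha <- if (ph$pooled$n_maternal > 0)
    pedigree_alpha(ph$per_trio) else list(alpha = NA_real_)

  fits <- NULL
  if (sum(stats::complete.cases(trios[c("paternal_age", "maternal_age")])) >= 4 &&
      nrow(muts)) {
    design <- trio_design(data.frame(
      trio_id = per$trio_id, paternal_age = per$paternal_age,
      maternal_age = per$maternal_age, n_mut = per$n_mut,
      n_phased = per$n_paternal + per$n_maternal,
      n_paternal = per$n_paternal, n_maternal = per$n_maternal,
      callable_sum = per$callable_sum))
    fits <- list(total = tryCatch(fit_total_regression(design),
                                  error = function(e) NULL))
    ok_phased <- all(design$n_mut > 0)
    if (ok_phased) {
      fits$paternal <- tryCatch(fit_phased_regression(design, "paternal"),
                                error = function(e) NULL)
      fits$maternal <- tryCatch(fit_phased_regression(design, "maternal"),
                                error = function(e) NULL)
    }
  }

  report <- structure(list(
    mutations = muts, per_trio = per,
    cohort = cohort_summary(per, trios),
    phasing = ph$pooled, alpha = alpha, fits = fits,
    settings = s, audit = called$audit), class = "pedmut_report")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(per, file.path(outdir, "per_trio.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(muts, file.path(outdir, "mutations.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(cohort = report$cohort, phasing = report$phasing,
           alpha = report$alpha["alpha"], settings = s),
      file.path(outdir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.pedmut_report <- function(x, ...) {
  cat(sprintf("pedmut report: %d trios, %d mutations\n",
              x$cohort$n_trios, nrow(x$mutations)))
  cat(sprintf("  mean rate %.3g /bp/gen; mean parental age %.1f y\n",
              x$cohort$mean_rate, x$cohort$mean_parental_age))
  cat(sprintf("  phased %d/%d (%.1f%%), alpha %.2f\n",
              x$phasing$n_paternal + x$phasing$n_maternal,
              x$phasing$n_total, 100 * x$phasing$fraction_phased,
              x$alpha$alpha))
  invisible(x)
}
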
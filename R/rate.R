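#' Estimate per-trio callability from high-confidence genotypes
#'
#' Callability is the probability that a true DNM genotype configuration
#' would survive the calling filters; it is estimated per trio member from
#' genotype configurations whose truth is effectively guaranteed by the
#' rest of the trio, assuming independence across members.
#'
#' * Child: at sites where one parent is homref and the other homalt, the
#'   child must be het. `c_child` is the fraction of such child calls that
#'   pass the child-specific candidate filters (depth bounds, GQ,
#'   concordance, strand support, allelic balance).
#' * Father/mother: at sites where that parent is homref, the other parent
#'   homalt and the child het, the parent's homref call is high confidence.
#'   `c_parent` is the fraction passing the parent-specific filters (depth
#'   bounds, GQ, zero alt reads).
#'
#' The trio-level callability is the product `c_child * c_father *
#' c_mother`.
#'
#' @param trio a trio row (`child_id`, `father_id`, `mother_id`).
#' @param gt cohort [genotype_table()].
#' @param depth_means named per-sample mean depths; computed when missing.
#' @param min_depth,gq_min,ab_min,max_depth_mode filter thresholds matching
#'   the DNM screen.
#' @return list of class `callability_estimate`: `c_child`, `c_father`,
#'   `c_mother`, `callability` (their product), and per-member
#'   `n_filtered` / `n_all` counts.
#' @export
estimate_callability <- function(trio, gt, depth_means = NULL,
                                 min_depth = 15, gq_min = 60, ab_min = 0.35,
                                 max_depth_mode = c("sigma4", "fivex")) {
  max_depth_mode <- match.arg(max_depth_mode)
  ch <- trio$child_id; fa <- trio$father_id; mo <- trio$mother_id
  if (is.null(depth_means)) depth_means <- colMeans(gt$dp, na.rm = TRUE)
  maxd <- max_depth_cutoff(depth_means[c(ch, fa, mo)], max_depth_mode)

  depth_ok <- function(s, lim) !is.na(gt$dp[, s]) & gt$dp[, s] >= min_depth &
    gt$dp[, s] <= lim
  gq_ok <- function(s) !is.na(gt$gq[, s]) & gt$gq[, s] > gq_min

  opp_hom <- (gt$gt[, fa] %in% 0 & gt$gt[, mo] %in% 2) |
    (gt$gt[, fa] %in% 2 & gt$gt[, mo] %in% 0)

  # child: het is guaranteed by opposite-homozygote parents
  child_sites <- which(opp_hom & !is.na(gt$gt[, ch]))
  ab <- gt$ad_alt[, ch] / (gt$ad_ref[, ch] + gt$ad_alt[, ch])
  child_pass <- gt$gt[, ch] %in% 1 &
    depth_ok(ch, maxd[1]) & gq_ok(ch) &
    !is.na(gt$concordant[, ch]) & gt$concordant[, ch] &
    !is.na(gt$fwd_alt[, ch]) & gt$fwd_alt[, ch] >= 1 &
    !is.na(gt$rev_alt[, ch]) & gt$rev_alt[, ch] >= 1 &
    !is.na(ab) & ab > ab_min

  parent_call <- function(p, other) {
    conf <- which(gt$gt[, p] %in% 0 & gt$gt[, other] %in% 2 &
                    gt$gt[, ch] %in% 1)
    lim <- maxd[if (p == fa) 2 else 3]
    pass <- depth_ok(p, lim) & gq_ok(p) &
      !is.na(gt$ad_alt[, p]) & gt$ad_alt[, p] == 0
    c(n_filtered = sum(pass[conf]), n_all = length(conf))
  }

  n_child <- c(n_filtered = sum(child_pass[child_sites]),
               n_all = length(child_sites))
  n_father <- parent_call(fa, mo)
  n_mother <- parent_call(mo, fa)
  if (n_child["n_all"] == 0 || n_father["n_all"] == 0 ||
      n_mother["n_all"] == 0)
    stop("callability undefined for trio ", ch,
         ": no informative high-confidence sites")
  cc <- n_child["n_filtered"] / n_child["n_all"]
  cf <- n_father["n_filtered"] / n_father["n_all"]
  cm <- n_mother["n_filtered"] / n_mother["n_all"]
  structure(list(trio_id = ch,
                 c_child = unname(cc), c_father = unname(cf),
                 c_mother = unname(cm),
                 callability = unname(cc * cf * cm),
                 counts = rbind(child = n_child, father = n_father,
                                mother = n_mother)),
            class = "callability_estimate")
}

#' Per-generation mutation rate for a trio
#'
#' `mu = n_mut / (2 * callable_sum)`, where `callable_sum` is the number of
#' callable (haploid) sites: depth-passing sites times the trio callability
#' product. The factor of two converts to a per-base, per-generation rate
#' on the diploid genome.
#'
#' @param n_mut DNM count for the trio.
#' @param callable_sum callable haploid site count (bp); must be positive.
#' @param trio_id optional label.
#' @return data.frame row: `trio_id`, `n_mut`, `callable_sum`, `rate`.
#' @examples
#' compute_trio_rate(117, 1.67e9)$rate  # 3.50e-8
#' @export
compute_trio_rate <- function(n_mut, callable_sum, trio_id = NA_character_) {
  if (any(callable_sum <= 0)) stop("callable_sum must be positive")
  if (any(n_mut < 0)) stop("n_mut must be non-negative")
  data.frame(trio_id = trio_id, n_mut = n_mut, callable_sum = callable_sum,
             rate = n_mut / (2 * callable_sum), stringsAsFactors = FALSE)
}

#' Cohort-level rate and age summary
#'
#' The cohort rate is the unweighted mean of per-trio rates (pooling counts
#' over pooled callable sites is deliberately not used: the per-trio mean
#' is the estimand matching a per-generation rate). The cohort parental age
#' is the mean of the paternal and maternal mean ages.
#'
#' @param rates data.frame from [compute_trio_rate()] (stacked).
#' @param trios data.frame with `paternal_age`, `maternal_age`.
#' @return list: `mean_rate`, `mean_paternal_age`, `mean_maternal_age`,
#'   `mean_parental_age`, `n_trios`.
#' @export
cohort_summary <- function(rates, trios) {
  stopifnot(nrow(rates) >= 1)
  pa <- mean(trios$paternal_age, na.rm = TRUE)
  ma <- mean(trios$maternal_age, na.rm = TRUE)
  list(mean_rate = mean(rates$rate),
       mean_paternal_age = pa, mean_maternal_age = ma,
       mean_parental_age = mean(c(pa, ma)),
       n_trios = nrow(rates))
}
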
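#' Site-level allelic-balance prefilter
#'
#' Removes SNVs whose mean heterozygote allelic balance
#' `ABHet = ref / (ref + alt)` across het-called samples falls below 0.2 or
#' above 0.8 (a reference-bias screen applied cohort-wide before candidate
#' discovery). Sites with no het carrier are retained and marked
#' not-evaluable.
#'
#' @param gt a [genotype_table()].
#' @param lower,upper exclusion bounds on ABHet.
#' @return the filtered [genotype_table()], with attributes
#'   `n_removed_abhet` and `abhet` (per-site value for the retained sites).
#' @export
prefilter_sites <- function(gt, lower = 0.2, upper = 0.8) {
  het <- gt$gt == 1
  tot <- gt$ad_ref + gt$ad_alt
  abh <- ifelse(het & tot > 0, gt$ad_ref / tot, NA_real_)
  site_ab <- rowMeans(abh, na.rm = TRUE)  # NaN when no het carrier
  drop <- !is.nan(site_ab) & (site_ab < lower | site_ab > upper)
  out <- gt[!drop]
  attr(out, "n_removed_abhet") <- sum(drop)
  attr(out, "abhet") <- site_ab[!drop]
  if (any(drop)) message(sum(drop), " site(s) removed by ABHet prefilter")
  out
}

#' Find Mendelian-violation candidate DNMs in a trio
#'
#' Candidates are exactly the autosomal sites where both parents are called
#' homozygous reference and the child heterozygous; any other configuration
#' (including a het parent or a homalt child) is excluded to minimise
#' error. Sites with a missing genotype in any trio member are skipped.
#'
#' @param trio one row of [enumerate_trios()] output (or a list with
#'   `child_id`, `father_id`, `mother_id`).
#' @param gt a [genotype_table()], ideally after [prefilter_sites()].
#' @param exclude_contigs contigs (e.g. X-linked from [classify_contigs()])
#'   to skip.
#' @return data.frame of candidates: site columns plus per-member evidence
#'   (`*_dp`, `*_gq`, `*_ad_ref`, `*_ad_alt`, child strand counts and
#'   concordance).
#' @export
find_mendelian_violations <- function(trio, gt, exclude_contigs = character()) {
  ch <- trio$child_id; fa <- trio$father_id; mo <- trio$mother_id
  stopifnot(all(c(ch, fa, mo) %in% gt$samples))
  ok_contig <- !(gt$sites$contig %in% exclude_contigs)
  sel <- which(ok_contig &
                 gt$gt[, fa] %in% 0 & gt$gt[, mo] %in% 0 & gt$gt[, ch] %in% 1)
  s <- gt$sites[sel, , drop = FALSE]
  out <- data.frame(
    child_id = rep(ch, length(sel)), contig = s$contig, pos = s$pos,
    ref = s$ref, alt = s$alt,
    child_dp = gt$dp[sel, ch], father_dp = gt$dp[sel, fa],
    mother_dp = gt$dp[sel, mo],
    child_gq = gt$gq[sel, ch], father_gq = gt$gq[sel, fa],
    mother_gq = gt$gq[sel, mo],
    child_ad_ref = gt$ad_ref[sel, ch], child_ad_alt = gt$ad_alt[sel, ch],
    father_ad_alt = gt$ad_alt[sel, fa], mother_ad_alt = gt$ad_alt[sel, mo],
    child_fwd_alt = gt$fwd_alt[sel, ch], child_rev_alt = gt$rev_alt[sel, ch],
    child_concordant = gt$concordant[sel, ch],
    stringsAsFactors = FALSE)
  attr(out, "site_index") <- sel
  rownames(out) <- NULL
  out
}

#' Maximum-depth cutoff for the depth filter
#'
#' @param depth_mean per-sample mean depth.
#' @param mode `"sigma4"` (default): `mean + 4 * sqrt(mean)`, a Poisson
#'   four-sigma bound; `"fivex"`: `5 * mean`.
#' @return numeric cutoff(s).
#' @export
max_depth_cutoff <- function(depth_mean, mode = c("sigma4", "fivex")) {
  mode <- match.arg(mode)
  if (mode == "sigma4") depth_mean + 4 * sqrt(depth_mean) else 5 * depth_mean
}

#' Apply the seven candidate-DNM filters
#'
#' Evaluates and records every filter for each Mendelian-violation
#' candidate:
#' 1. read depth between `min_depth` and the per-sample maximum
#'    ([max_depth_cutoff()]) in all three members;
#' 2. genotype quality strictly greater than `gq_min` in all members;
#' 3. child called het by both callers (concordance annotation);
#' 4. alt allele on at least one forward and one reverse child read;
#' 5. zero alt reads in either parent;
#' 6. alt allele absent from every non-sibling cohort sample (read-level by
#'    default: any alt read counts as presence; `presence = "genotype"`
#'    requires an alt genotype call);
#' 7. child allelic balance `alt / (ref + alt)` strictly greater than
#'    `ab_min`.
#'
#' A filter that cannot be evaluated (missing annotation) is recorded
#' `"not_evaluable"` and fails closed. Verdicts are per-filter and
#' order-independent; the candidate passes iff all seven pass.
#'
#' @param candidates output of [find_mendelian_violations()].
#' @param gt the cohort [genotype_table()] (for the cohort-absence filter).
#' @param trio the trio row used to build `candidates`.
#' @param depth_means named per-sample mean depths.
#' @param siblings sample ids exempt from filter 6: full siblings of the
#'   child and the child's own descendants (a transmitted DNM is
#'   necessarily present in the next generation); the trio members
#'   themselves are always exempt.
#' @param min_depth,gq_min,ab_min filter thresholds.
#' @param max_depth_mode see [max_depth_cutoff()].
#' @param presence filter 6 mode: `"read"` or `"genotype"`.
#' @return `candidates` with added columns `filter_depth`, `filter_gq`,
#'   `filter_concordance`, `filter_strand`, `filter_parent_reads`,
#'   `filter_cohort_absence`, `filter_ab` (each
#'   `"pass"`/`"fail"`/`"not_evaluable"`) and logical `pass`.
#' @export
apply_dnm_filters <- function(candidates, gt, trio, depth_means,
                              siblings = character(),
                              min_depth = 15, gq_min = 60, ab_min = 0.35,
                              max_depth_mode = c("sigma4", "fivex"),
                              presence = c("read", "genotype")) {
  max_depth_mode <- match.arg(max_depth_mode)
  presence <- match.arg(presence)
  n <- nrow(candidates)
  ch <- trio$child_id; fa <- trio$father_id; mo <- trio$mother_id
  verdict <- function(ok) {
    v <- ifelse(is.na(ok), "not_evaluable", ifelse(ok, "pass", "fail"))
    v
  }
  maxd <- max_depth_cutoff(depth_means[c(ch, fa, mo)], max_depth_mode)
  f_depth <- verdict(
    candidates$child_dp >= min_depth & candidates$child_dp <= maxd[1] &
      candidates$father_dp >= min_depth & candidates$father_dp <= maxd[2] &
      candidates$mother_dp >= min_depth & candidates$mother_dp <= maxd[3])
  f_gq <- verdict(candidates$child_gq > gq_min & candidates$father_gq > gq_min &
                    candidates$mother_gq > gq_min)
  f_conc <- verdict(candidates$child_concordant)
  f_strand <- verdict(candidates$child_fwd_alt >= 1 & candidates$child_rev_alt >= 1)
  f_parent <- verdict(candidates$father_ad_alt == 0 & candidates$mother_ad_alt == 0)

  others <- setdiff(gt$samples, c(ch, fa, mo, siblings))
  si <- attr(candidates, "site_index")
  if (is.null(si)) si <- match(paste(candidates$contig, candidates$pos),
                               paste(gt$sites$contig, gt$sites$pos))
  if (length(others)) {
    alt_read <- gt$ad_alt[si, others, drop = FALSE] > 0
    alt_gt <- gt$gt[si, others, drop = FALSE] >= 1
    present <- if (presence == "read") {
      rowSums(alt_read | alt_gt, na.rm = TRUE) > 0
    } else {
      rowSums(alt_gt, na.rm = TRUE) > 0
    }
    f_cohort <- verdict(!present)
  } else {
    f_cohort <- rep("pass", n)
  }
  ab <- candidates$child_ad_alt /
    (candidates$child_ad_ref + candidates$child_ad_alt)
  f_ab <- verdict(ab > ab_min)

  candidates$filter_depth <- f_depth
  candidates$filter_gq <- f_gq
  candidates$filter_concordance <- f_conc
  candidates$filter_strand <- f_strand
  candidates$filter_parent_reads <- f_parent
  candidates$filter_cohort_absence <- f_cohort
  candidates$filter_ab <- f_ab
  fcols <- c("filter_depth", "filter_gq", "filter_concordance",
             "filter_strand", "filter_parent_reads",
             "filter_cohort_absence", "filter_ab")
  candidates$pass <- Reduce(`&`, lapply(candidates[fcols], `==`, "pass"))
  candidates
}

#' Classify contigs as autosomal, X-linked, or unfiltered
#'
#' A contig is labelled `x_linked` when read depth or heterozygosity
#' differs significantly between the sexes (two-sided Welch t-test,
#' P < `p_cut`) *and* mean male depth is below `male_depth_max`;
#' significant contigs failing the male-depth condition are `unfiltered`
#' (kept out of the X set but flagged); everything else is `autosomal`.
#'
#' @param qc data.frame with one row per (contig, individual): columns
#'   `contig`, `individual`, `sex` (`"male"`/`"female"`), `depth`, `het`.
#' @param p_cut significance threshold.
#' @param male_depth_max male mean-depth ceiling for X-linkage.
#' @return data.frame per contig: sex-specific means, the two p-values and
#'   `label`.
#' @export
classify_contigs <- function(qc, p_cut = 0.05, male_depth_max = 25) {
  if (length(unique(qc$sex)) < 2L) {
    warning("single-sex cohort: all contigs labelled autosomal")
    u <- unique(qc$contig)
    return(data.frame(contig = u, male_mean_depth = NA_real_,
                      female_mean_depth = NA_real_, depth_p = NA_real_,
                      het_p = NA_real_, label = "autosomal",
                      stringsAsFactors = FALSE))
  }
  res <- lapply(split(qc, qc$contig), function(d) {
    m <- d[d$sex == "male", ]; f <- d[d$sex == "female", ]
    tt <- function(a, b) {
      if (length(a) < 2L || length(b) < 2L) return(NA_real_)
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
    }
    dp_p <- tt(m$depth, f$depth); het_p <- tt(m$het, f$het)
    sig <- isTRUE(dp_p < p_cut) || isTRUE(het_p < p_cut)
    md <- mean(m$depth)
    data.frame(contig = d$contig[1], male_mean_depth = md,
               female_mean_depth = mean(f$depth),
               depth_p = dp_p, het_p = het_p,
               label = if (sig && md < male_depth_max) "x_linked"
               else if (sig) "unfiltered" else "autosomal",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assess transmission of DNMs to the third generation
#'
#' A DNM is assessable when its carrier has at least one offspring with a
#' non-missing genotype at the site, and transmitted when that grandchild
#' carries the alt allele.
#'
#' @param dnms mutation table (columns `child_id`, `contig`, `pos`).
#' @param gt cohort [genotype_table()] including third-generation samples.
#' @param ped the [pedigree()].
#' @return data.frame per DNM carrier: `child_id`, `transmitted`,
#'   `assessable`.
#' @export
assess_transmission <- function(dnms, gt, ped) {
  out <- lapply(split(dnms, dnms$child_id), function(d) {
    kid <- d$child_id[1]
    offspring <- ped$id[!is.na(ped$father_id) & ped$father_id == kid |
                          !is.na(ped$mother_id) & ped$mother_id == kid]
    offspring <- intersect(offspring, gt$samples)
    if (length(offspring) == 0L) return(NULL)
    si <- match(paste(d$contig, d$pos), paste(gt$sites$contig, gt$sites$pos))
    g <- gt$gt[si, offspring, drop = FALSE]
    assessable <- rowSums(!is.na(g)) > 0
    transmitted <- rowSums(g >= 1, na.rm = TRUE) > 0
    data.frame(child_id = kid, transmitted = sum(transmitted & assessable),
               assessable = sum(assessable), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out))
    out <- data.frame(child_id = character(), transmitted = integer(),
                      assessable = integer())
  rownames(out) <- NULL
  out
}

# descendants of `id` reachable through the trio table's child-parent edges
descendants_in <- function(trios, id) {
  out <- character(); frontier <- id
  while (length(frontier)) {
    kids <- trios$child_id[trios$father_id %in% frontier |
                             trios$mother_id %in% frontier]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Call de novo mutations for every trio in a cohort
#'
#' Orchestrates the per-trio pipeline: ABHet prefilter, Mendelian-violation
#' discovery, and the seven-filter screen; then annotates sibling-shared
#' mutations (each carrier keeps its own row, flagged) and multinucleotide
#' clusters (constituent SNVs within 10 bp in the same child share an
#' `mnm_cluster_id`).
#'
#' @param gt cohort [genotype_table()].
#' @param trios data.frame from [enumerate_trios()].
#' @param depth_means named per-sample mean depths; computed from `gt` when
#'   missing.
#' @param exclude_contigs contigs to skip (e.g. X-linked).
#' @param mnm_window bp window for multinucleotide clustering.
#' @param ... thresholds passed to [apply_dnm_filters()].
#' @return list with `mutations` (the mutation table: `child_id`, `contig`,
#'   `pos`, `ref`, `alt`, `phase`, `shared_with_sibling`,
#'   `mnm_cluster_id`) and `audit` (all candidates with filter verdicts).
#' @export
call_dnms <- function(gt, trios, depth_means = NULL,
                      exclude_contigs = character(), mnm_window = 10, ...) {
  if (is.null(depth_means))
    depth_means <- colMeans(gt$dp, na.rm = TRUE)
  pre <- prefilter_sites(gt)
  audit <- list(); muts <- list()
  for (i in seq_len(nrow(trios))) {
    trio <- trios[i, ]
    sibs <- trios$child_id[trios$father_id == trio$father_id &
                             trios$mother_id == trio$mother_id &
                             trios$child_id != trio$child_id]
    cand <- find_mendelian_violations(trio, pre, exclude_contigs)
    cand <- apply_dnm_filters(cand, pre, trio, depth_means,
                              siblings = c(sibs, descendants_in(trios, trio$child_id)),
                              ...)
    audit[[i]] <- cand
    muts[[i]] <- cand[cand$pass, c("child_id", "contig", "pos", "ref", "alt")]
  }
  mutations <- do.call(rbind, muts)
  audit <- do.call(rbind, audit)
  rownames(mutations) <- rownames(audit) <- NULL
  mutations$phase <- rep("unphased", nrow(mutations))

  # sibling sharing: same site called in >= 2 children of the same parents
  key <- paste(mutations$contig, mutations$pos)
  fam <- trios$father_id[match(mutations$child_id, trios$child_id)]
  mam <- trios$mother_id[match(mutations$child_id, trios$child_id)]
  fkey <- paste(key, fam, mam)
  mutations$shared_with_sibling <- ave(seq_along(fkey), fkey,
                                       FUN = length) > 1

  # multinucleotide clusters within a child
  mutations$mnm_cluster_id <- rep(NA_character_, nrow(mutations))
  for (kid in unique(mutations$child_id)) {
    rows <- which(mutations$child_id == kid)
    d <- mutations[rows, ]
    o <- order(d$contig, d$pos)
    cl <- cumsum(c(TRUE, diff(d$pos[o]) > mnm_window |
                     d$contig[o][-1] != d$contig[o][-length(o)]))
    sizes <- table(cl)
    lab <- ifelse(sizes[cl] > 1, sprintf("%s_mnm%d", kid, cl), NA)
    mutations$mnm_cluster_id[rows[o]] <- lab
  }
  list(mutations = mutations, audit = audit)
}
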
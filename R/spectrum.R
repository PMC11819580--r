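COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(s) {
  vapply(strsplit(toupper(s), ""), function(x)
    paste(rev(unname(COMPLEMENT[x])), collapse = ""), "")
}

#' Classify a single-nucleotide mutation by type and context
#'
#' Collapses purine-origin mutations to their pyrimidine representation
#' (e.g. G>A in context CGT becomes C>T in ACG), yielding the six
#' strand-collapsed types C>A, C>G, C>T, T>A, T>C, T>G. CpG status means a
#' reference C followed by G after collapsing; TpC status marks the
#' APOBEC-associated TpC>TpT change (C>T with a 5' T).
#'
#' @param ref,alt single reference/alternate bases (vectorised).
#' @param context reference-strand trinucleotide centred on the site.
#' @return data.frame: `type`, `is_transition`, `is_cpg`, `is_tpc`.
#' @export
classify_mutation <- function(ref, alt, context) {
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  if (any(nchar(context) != 3L)) stop("context must be a trinucleotide")
  if (any(substr(context, 2, 2) != ref))
    stop("context centre does not match ref allele")
  flip <- ref %in% c("A", "G")
  ref2 <- ifelse(flip, unname(COMPLEMENT[ref]), ref)
  alt2 <- ifelse(flip, unname(COMPLEMENT[alt]), alt)
  ctx2 <- ifelse(flip, revcomp(context), context)
  type <- paste0(ref2, ">", alt2)
  transitions <- c("C>T", "T>C")
  data.frame(type = type,
             is_transition = type %in% transitions,
             is_cpg = ref2 == "C" & substr(ctx2, 3, 3) == "G",
             is_tpc = ref2 == "C" & alt2 == "T" & substr(ctx2, 1, 1) == "T",
             stringsAsFactors = FALSE)
}

#' Mutation-spectrum summary
#'
#' @param mutations data.frame with `ref`, `alt`, `context` columns.
#' @return list of class `spectrum_counts`: the six strand-collapsed type
#'   counts, `cpg_ct` (C>T at CpG), `tpc_tt` (TpC>TpT), `total`, `titv`
#'   (transition/transversion ratio, `Inf` with zero transversions, `NA`
#'   when empty), and `cpg_fraction`.
#' @export
spectrum_summary <- function(mutations) {
  types <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  if (nrow(mutations) == 0L) {
    counts <- stats::setNames(rep(0L, 6), types)
    return(structure(list(counts = counts, cpg_ct = 0L, tpc_tt = 0L,
                          total = 0L, titv = NA_real_,
                          cpg_fraction = NA_real_), class = "spectrum_counts"))
  }
  cl <- classify_mutation(mutations$ref, mutations$alt, mutations$context)
  counts <- stats::setNames(
    vapply(types, function(t) sum(cl$type == t), 0L), types)
  ti <- sum(cl$is_transition); tv <- nrow(cl) - ti
  structure(list(
    counts = counts,
    cpg_ct = sum(cl$is_cpg & cl$type == "C>T"),
    tpc_tt = sum(cl$is_tpc),
    total = nrow(cl),
    titv = if (tv == 0) Inf else ti / tv,
    cpg_fraction = mean(cl$is_cpg)
  ), class = "spectrum_counts")
}

#' Fisher test with the unconditional sample odds ratio
#'
#' Two-sided Fisher's exact p-value together with the plain sample odds
#' ratio `(a * d) / (b * c)` (the conditional-MLE OR that
#' [stats::fisher.test()] reports is also returned for reference). Zero
#' cells give `Inf` or `0` sample ORs; the p-value is still exact.
#'
#' @param a,b,c,d the 2x2 table counts, row-wise.
#' @return list: `or` (sample), `or_cmle`, `p`.
#' @export
fisher_or_test <- function(a, b, c, d) {
  a <- unname(a); b <- unname(b); c <- unname(c); d <- unname(d)
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  or <- (a * d) / (b * c)
  if (b * c == 0) or <- if (a * d == 0) NaN else Inf
  list(or = or, or_cmle = unname(ft$estimate), p = ft$p.value)
}

#' APOBEC-signature (TpC>TpT) enrichment tests
#'
#' Two 2x2 Fisher comparisons among phased C>T mutations:
#' 1. TpC>TpT maternal vs paternal against all other phased non-CpG C>T
#'    maternal vs paternal;
#' 2. among maternally phased mutations, TpC>TpT in old vs young mothers
#'    against all maternal C>T in old vs young (maternal age split
#'    strictly at `age_split`; a trio exactly at the split is
#'    unclassified).
#'
#' Category overlap (TpC>TpT is a subset of C>T) follows the conventional
#' presentation; `disjoint = TRUE` removes the TpC>TpT mutations from the
#' comparison class.
#'
#' @param mutations data.frame with `ref`, `alt`, `context`, `phase`, and
#'   `maternal_age` columns.
#' @param age_split young/old maternal split in years.
#' @param disjoint use disjoint comparison categories.
#' @return list with elements `sex` and `maternal_age`, each a
#'   [fisher_or_test()] result plus the underlying table.
#' @export
tpc_enrichment_tests <- function(mutations, age_split = 15,
                                 disjoint = FALSE) {
  cl <- classify_mutation(mutations$ref, mutations$alt, mutations$context)
  ph <- mutations$phase
  ct <- cl$type == "C>T"
  tpc <- cl$is_tpc
  base <- ct & !cl$is_cpg & (!disjoint | !tpc)

  t1 <- c(a = sum(tpc & ph == "maternal"), b = sum(tpc & ph == "paternal"),
          c = sum(base & ph == "maternal"), d = sum(base & ph == "paternal"))
  sex <- c(fisher_or_test(t1["a"], t1["b"], t1["c"], t1["d"]),
           list(table = t1))

  old <- ph == "maternal" & mutations$maternal_age > age_split
  young <- ph == "maternal" & mutations$maternal_age < age_split
  base2 <- ct & (!disjoint | !tpc)
  t2 <- c(a = sum(tpc & old), b = sum(tpc & young),
          c = sum(base2 & old), d = sum(base2 & young))
  agec <- c(fisher_or_test(t2["a"], t2["b"], t2["c"], t2["d"]),
            list(table = t2))
  list(sex = sex, maternal_age = agec)
}

#' Two-sided exact binomial transmission test
#'
#' Tests whether `k` transmitted out of `n` assessable DNMs departs from
#' the Mendelian expectation of one half, using the minimum-likelihood
#' two-sided convention (sum the probabilities of all outcomes no more
#' likely than the observed one).
#'
#' @param k transmitted count.
#' @param n assessable count (>= 1, `k <= n`).
#' @param p null transmission probability.
#' @return list: `p.value`, `estimate` (`k/n`), `k`, `n`.
#' @examples
#' transmission_test(160, 327)$p.value  # ~0.74
#' @export
transmission_test <- function(k, n, p = 0.5) {
  if (n < 1 || k > n || k < 0) stop("need 0 <= k <= n, n >= 1")
  bt <- stats::binom.test(k, n, p = p)
  list(p.value = bt$p.value, estimate = k / n, k = k, n = n)
}

#' Chi-square homogeneity test across mutation spectra
#'
#' Compares two or more six-type spectra; when any expected cell is below
#' 5 the p-value is computed by Monte-Carlo permutation instead of the
#' asymptotic chi-square. Groups with zero total are excluded with a
#' warning.
#'
#' @param groups list of named six-type count vectors or
#'   `spectrum_counts` objects.
#' @param B Monte-Carlo replicates.
#' @return list: `p.value`, `statistic`, `simulated` (logical).
#' @export
spectrum_comparison <- function(groups, B = 2000) {
  vecs <- lapply(groups, function(g) if (inherits(g, "spectrum_counts")) g$counts else g)
  tot <- vapply(vecs, sum, 0)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " group(s) with zero total excluded")
    vecs <- vecs[tot > 0]
  }
  if (length(vecs) < 2L) stop("need at least two non-empty groups")
  m <- do.call(rbind, vecs)
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  exp_small <- {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    any(e < 5)
  }
  ct <- suppressWarnings(
    stats::chisq.test(m, simulate.p.value = exp_small, B = B))
  list(p.value = ct$p.value, statistic = unname(ct$statistic),
       simulated = exp_small)
}

#' Genotype-based coefficient of relatedness
#'
#' The shared-het / IBS0 estimator:
#' `CoR = (N_shared_het - 2 * N_IBS0) / min(N_het_a, N_het_b)`, where
#' IBS0 counts opposite homozygotes. Roughly 0 (or below) for unrelated
#' pairs, 0.5 for parent-child, 1 for identical genomes.
#'
#' @param geno_a,geno_b genotype vectors (0/1/2, `NA` allowed) at the same
#'   sites.
#' @param min_sites minimum shared non-missing sites.
#' @return the CoR (scalar); `NA` with a warning when a sample has no
#'   heterozygous site.
#' @export
relatedness_cor <- function(geno_a, geno_b, min_sites = 1000) {
  stopifnot(length(geno_a) == length(geno_b))
  ok <- !is.na(geno_a) & !is.na(geno_b)
  if (sum(ok) < min_sites)
    stop("need at least ", min_sites, " shared non-missing sites")
  a <- geno_a[ok]; b <- geno_b[ok]
  het_a <- sum(a == 1); het_b <- sum(b == 1)
  if (min(het_a, het_b) == 0) {
    warning("a sample has no heterozygous sites: CoR undefined")
    return(NA_real_)
  }
  shared_het <- sum(a == 1 & b == 1)
  ibs0 <- sum((a == 0 & b == 2) | (a == 2 & b == 0))
  (shared_het - 2 * ibs0) / min(het_a, het_b)
}
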
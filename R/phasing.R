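#' Find phase-informative heterozygous sites near a DNM
#'
#' A site within `window` bp of the DNM is informative when the child is
#' heterozygous there and the parental genotypes force each child allele to
#' a unique parent. That holds exactly when at most one parent is
#' heterozygous: e.g. father 0/0 and mother 1/1 imply the child's alt is
#' maternal; father 0/0 and mother 0/1 imply the child's alt came from the
#' mother (the father cannot supply it) and the ref from the father. Sites
#' where both parents are het are ambiguous and skipped.
#'
#' @param dnm list/row with `contig`, `pos`.
#' @param trio trio row (`child_id`, `father_id`, `mother_id`).
#' @param gt cohort [genotype_table()].
#' @param window flanking distance in bp (default 1000 on each side).
#' @return data.frame: `contig`, `pos`, `distance`, `alt_parent` and
#'   `ref_parent` (`"paternal"`/`"maternal"`), one row per informative
#'   site.
#' @export
find_informative_sites <- function(dnm, trio, gt, window = 1000) {
  ch <- trio$child_id; fa <- trio$father_id; mo <- trio$mother_id
  near <- which(gt$sites$contig == dnm$contig &
                  abs(gt$sites$pos - dnm$pos) <= window &
                  gt$sites$pos != dnm$pos)
  if (!length(near))
    return(data.frame(contig = character(), pos = integer(),
                      distance = integer(), alt_parent = character(),
                      ref_parent = character()))
  gch <- gt$gt[near, ch]; gfa <- gt$gt[near, fa]; gmo <- gt$gt[near, mo]
  ok <- !is.na(gch) & gch == 1 & !is.na(gfa) & !is.na(gmo)
  # alt allele origin is forced unless both parents are het;
  # also require genotypes to be Mendelian-consistent with a het child
  one_het <- (gfa == 1) + (gmo == 1) <= 1
  consistent <- !(gfa == 0 & gmo == 0) & !(gfa == 2 & gmo == 2)
  ok <- ok & one_het & consistent
  if (!any(ok))
    return(data.frame(contig = character(), pos = integer(),
                      distance = integer(), alt_parent = character(),
                      ref_parent = character()))
  idx <- near[ok]; gfa <- gfa[ok]; gmo <- gmo[ok]
  # who supplied the alt? the parent that *can* (carries alt) when the
  # other cannot, or the homalt parent when the other is het
  alt_from_father <- (gfa >= 1 & gmo == 0) | (gfa == 2)
  alt_from_mother <- (gmo >= 1 & gfa == 0) | (gmo == 2)
  alt_parent <- ifelse(alt_from_father & !alt_from_mother, "paternal",
                       ifelse(alt_from_mother & !alt_from_father, "maternal",
                              NA_character_))
  keep <- !is.na(alt_parent)
  idx <- idx[keep]; alt_parent <- alt_parent[keep]
  data.frame(
    contig = gt$sites$contig[idx], pos = gt$sites$pos[idx],
    distance = gt$sites$pos[idx] - dnm$pos,
    alt_parent = alt_parent,
    ref_parent = ifelse(alt_parent == "paternal", "maternal", "paternal"),
    stringsAsFactors = FALSE)
}

#' Phase one DNM by read tracing
#'
#' Read pairs carrying the DNM alt allele vote for a parent via the
#' informative alleles they also carry: a read with the DNM alt and an
#' informative site's alt allele votes for that site's `alt_parent`; with
#' the informative ref allele, for its `ref_parent`. The DNM is assigned
#' only on a unanimous vote with at least `min_votes` supporting reads;
#' conflicting or absent votes leave it unphased. Genotype-only phasing is
#' never performed.
#'
#' @param dnm list/row with `child_id`, `contig`, `pos`.
#' @param evidence read-evidence table (`read_id`, `child_id`, `contig`,
#'   `pos`, `allele` with 0 ref / 1 alt).
#' @param sites informative sites from [find_informative_sites()].
#' @param min_votes minimum number of concordant linking reads.
#' @return `"paternal"`, `"maternal"`, or `"unphased"`; attribute `votes`
#'   carries the paternal/maternal read counts.
#' @export
phase_dnm <- function(dnm, evidence, sites, min_votes = 1) {
  unphased <- structure("unphased", votes = c(paternal = 0L, maternal = 0L))
  if (nrow(sites) == 0L || nrow(evidence) == 0L) return(unphased)
  ev <- evidence[evidence$child_id == dnm$child_id &
                   evidence$contig == dnm$contig, , drop = FALSE]
  carrier_reads <- unique(ev$read_id[ev$pos == dnm$pos & ev$allele == 1])
  if (!length(carrier_reads)) return(unphased)
  link <- ev[ev$read_id %in% carrier_reads & ev$pos %in% sites$pos, ,
             drop = FALSE]
  if (!nrow(link)) return(unphased)
  si <- match(link$pos, sites$pos)
  vote <- ifelse(link$allele == 1, sites$alt_parent[si], sites$ref_parent[si])
  counts <- c(paternal = sum(vote == "paternal"),
              maternal = sum(vote == "maternal"))
  if (counts["paternal"] > 0 && counts["maternal"] > 0)
    return(structure("unphased", votes = counts))
  winner <- names(counts)[counts > 0]
  if (length(winner) != 1L || counts[winner] < min_votes)
    return(structure("unphased", votes = counts))
  structure(winner, votes = counts)
}

#' Phase every mutation in a mutation table
#'
#' @param mutations mutation table (from [call_dnms()] or equivalent).
#' @param trios trios data.frame.
#' @param gt cohort [genotype_table()].
#' @param evidence read-evidence table.
#' @param window informative-site window (bp).
#' @param min_votes see [phase_dnm()].
#' @return the mutation table with its `phase` column filled.
#' @export
phase_mutations <- function(mutations, trios, gt, evidence, window = 1000,
                            min_votes = 1) {
  if (nrow(mutations) == 0L) return(mutations)
  mutations$phase <- vapply(seq_len(nrow(mutations)), function(k) {
    dnm <- mutations[k, ]
    trio <- trios[trios$child_id == dnm$child_id, ]
    if (nrow(trio) != 1L) return("unphased")
    sites <- find_informative_sites(dnm, trio, gt, window)
    as.character(phase_dnm(dnm, evidence, sites, min_votes))
  }, "")
  mutations
}

#' Per-trio and pooled phasing summaries
#'
#' @param mutations mutation table with a `phase` column
#'   (`"paternal"`/`"maternal"`/`"unphased"`).
#' @return list with `per_trio` (counts and `fraction_phased` per child)
#'   and `pooled` (totals and pooled `fraction_phased`).
#' @export
summarize_phasing <- function(mutations) {
  per <- lapply(split(mutations, mutations$child_id), function(d) {
    np <- sum(d$phase == "paternal"); nm <- sum(d$phase == "maternal")
    data.frame(trio_id = d$child_id[1], n_paternal = np, n_maternal = nm,
               n_unphased = sum(d$phase == "unphased"), n_total = nrow(d),
               fraction_phased = (np + nm) / nrow(d),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (is.null(per))
    per <- data.frame(trio_id = character(), n_paternal = integer(),
                      n_maternal = integer(), n_unphased = integer(),
                      n_total = integer(), fraction_phased = numeric())
  rownames(per) <- NULL
  tot <- colSums(per[c("n_paternal", "n_maternal", "n_unphased", "n_total")])
  pooled <- as.list(tot)
  pooled$fraction_phased <-
    if (tot[["n_total"]] > 0)
      (tot[["n_paternal"]] + tot[["n_maternal"]]) / tot[["n_total"]]
    else NA_real_
  list(per_trio = per, pooled = pooled)
}

#' Pedigree-based male-to-female mutation bias (alpha)
#'
#' `alpha = sum(paternal) / sum(maternal)` over the included trios.
#'
#' @param per_trio per-trio counts (e.g. `summarize_phasing()$per_trio`, or
#'   any data.frame with `trio_id`, `n_paternal`, `n_maternal`).
#' @param exclude trio/child ids to leave out.
#' @return list: `alpha`, `n_paternal`, `n_maternal`, `paternal_fraction`.
#'   `alpha` is `Inf` (with a warning) when the maternal total is zero.
#' @examples
#' pedigree_alpha(data.frame(trio_id = "t", n_paternal = 113,
#'                           n_maternal = 90))$alpha  # 1.26
#' @export
pedigree_alpha <- function(per_trio, exclude = character()) {
  d <- per_trio[!per_trio$trio_id %in% exclude, , drop = FALSE]
  np <- sum(d$n_paternal); nm <- sum(d$n_maternal)
  if (nm == 0) {
    warning("zero maternal mutations: alpha undefined (reported Inf)")
    a <- Inf
  } else a <- np / nm
  list(alpha = a, n_paternal = np, n_maternal = nm,
       paternal_fraction = np / (np + nm))
}

#' Compare two phase assignments
#'
#' Generic diff between two phasers' outputs over the same mutation set
#' (e.g. read-pair tracing vs an extended haplotype-bridging method).
#'
#' @param phase_a,phase_b character vectors of equal length with values
#'   `"paternal"`/`"maternal"`/`"unphased"`.
#' @return list: `n`, `both_phased`, `concordant`, `a_only`, `b_only`,
#'   `conflicts` (indices where both phased but disagree).
#' @export
phase_diff <- function(phase_a, phase_b) {
  stopifnot(length(phase_a) == length(phase_b))
  pa <- phase_a != "unphased"; pb <- phase_b != "unphased"
  list(n = length(phase_a),
       both_phased = sum(pa & pb),
       concordant = sum(pa & pb & phase_a == phase_b),
       a_only = sum(pa & !pb), b_only = sum(pb & !pa),
       conflicts = which(pa & pb & phase_a != phase_b))
}
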
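#' Configuration for the synthetic pedigree cohort simulator
#'
#' Defaults emulate the aye-aye study conditions: 12 independent trios,
#' ~1.8 Gb of autosomal sequence, parental ages uniform on 6.7-30.5 years,
#' ~40X depth, low nucleotide polymorphism, and a mutation model whose
#' expected DNM count per trio is linear in age-scaled diploid callable
#' size, `mu_i = beta0 + betaP * L_i * X_P,i + betaM * L_i * X_M,i`, with a
#' female-biased age effect at the fitted cohort scale. Tests and examples
#' pass smaller genomes; the scientific defaults are not tuned per run.
#'
#' @param n_trios number of independent father-mother-child trios.
#' @param genome data.frame with columns `contig`, `length` (bp), `is_X`.
#' @param diploid_callable_fraction fraction of sites passing the depth
#'   filters in all trio members.
#' @param het_rate per-bp probability that a site is polymorphic in the
#'   founder population.
#' @param beta0 intercept of the mutation model (expected DNMs at age 0),
#'   split evenly between parents when assigning parent of origin.
#' @param betaP,betaM paternal and maternal age coefficients, in expected
#'   mutations per (bp of diploid callable genome x year).
#' @param age_range parental ages are sampled uniformly on this interval
#'   (years).
#' @param depth_mean mean sequencing depth (reads); per-site depths are
#'   Poisson.
#' @param gq_mean,gq_sd genotype-quality distribution (phred), normal,
#'   truncated at 0 and 99.
#' @param ab_sd beta-like jitter (on the logit scale, sd) applied to the
#'   heterozygote allele-balance parameter 0.5 before binomial AD sampling.
#' @param caller_discordance_rate per-call probability that the second
#'   caller disagrees.
#' @param error_alt_rate per-read probability of an alt-supporting error
#'   read in a homozygous-reference sample.
#' @param read_length,fragment_length read and fragment sizes (bp) used by
#'   [simulate_read_evidence()].
#' @param grandchildren number of trios (taken from the first ones) whose
#'   child is mated to a new founder to produce one third-generation
#'   offspring, enabling transmission assessment.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_trios = 12,
                       genome = data.frame(
                         contig = sprintf("chr%02d", 1:12),
                         length = rep(1.5e8, 12), is_X = FALSE),
                       diploid_callable_fraction = 0.8,
                       het_rate = 5e-4,
                       beta0 = 5, betaP = 3e-11, betaM = 1.2e-9,
                       age_range = c(6.7, 30.5),
                       depth_mean = 40, gq_mean = 75, gq_sd = 12,
                       ab_sd = 0.05,
                       caller_discordance_rate = 0.01,
                       error_alt_rate = 0.001,
                       read_length = 150, fragment_length = 500,
                       grandchildren = 0, exact_evidence = FALSE) {
  stopifnot(n_trios >= 0, all(genome$length > 0),
            diploid_callable_fraction >= 0, diploid_callable_fraction <= 1,
            het_rate >= 0, beta0 >= 0, betaP >= 0, betaM >= 0,
            depth_mean > 0, read_length > 0,
            fragment_length >= read_length,
            grandchildren <= n_trios)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a sequenced pedigree cohort with a known truth set
#'
#' Founder genotypes are drawn under Hardy-Weinberg at `het_rate`
#' polymorphic sites; children inherit one parental haplotype per contig
#' per meiosis (no intra-contig recombination, which keeps phasing truth
#' exact). DNMs are injected per trio with Poisson counts whose mean
#' follows the linear parental-age model, each assigned a true parent of
#' origin with probability proportional to that parent's term (the
#' intercept is split evenly). Depth, GQ, allele depths, strand counts and
#' caller concordance are then sampled per call. All randomness flows from
#' `seed`, making outputs reproducible byte for byte.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param materialize build the observed genotype table (default). With
#'   `FALSE` only the pedigree, ages and truth set are returned, which is
#'   much lighter for count-level Monte-Carlo calibration of large
#'   cohorts.
#' @return list of class `sim_cohort`: `genotypes` ([genotype_table()]),
#'   `ped` ([pedigree()]), `ages` (child ages data.frame), `trios`,
#'   `truth` (list: `dnms` data.frame with true parent of origin and
#'   transmission, `L` diploid callable size per trio, `depth_pass_sites`),
#'   and `haplotypes` (internal per-individual site alleles used for read
#'   simulation).
#' @export
simulate_cohort <- function(config, seed = 1L, materialize = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  cf <- config
  autosomes <- cf$genome[!cf$genome$is_X, , drop = FALSE]
  if (nrow(autosomes) == 0L) stop("genome must contain at least one autosome")
  total_len <- sum(autosomes$length)
  L <- 2 * total_len * cf$diploid_callable_fraction  # diploid callable bp

  # --- individuals -------------------------------------------------------
  tid <- sprintf("T%02d", seq_len(cf$n_trios))
  fathers <- paste0(tid, "_fa"); mothers <- paste0(tid, "_mo")
  children <- paste0(tid, "_ch")
  g3 <- seq_len(cf$grandchildren)
  spouses <- if (cf$grandchildren) paste0(tid[g3], "_sp") else character()
  gkids <- if (cf$grandchildren) paste0(tid[g3], "_gc") else character()
  ids <- c(fathers, mothers, children, spouses, gkids)

  ages <- data.frame(
    child_id = children,
    paternal_age = stats::runif(cf$n_trios, cf$age_range[1], cf$age_range[2]),
    maternal_age = stats::runif(cf$n_trios, cf$age_range[1], cf$age_range[2]))

  mu <- cf$beta0 + cf$betaP * L * ages$paternal_age +
    cf$betaM * L * ages$maternal_age
  if (any(mu < 0)) stop("identity-link hazard: expected DNM count < 0")

  child_sex <- rep(c("female", "male"), length.out = cf$n_trios)
  child_sex[g3] <- "female"  # grandchild mothers must be female
  ped <- pedigree(
    id = ids,
    sex = c(rep("male", cf$n_trios), rep("female", cf$n_trios), child_sex,
            rep("male", length(spouses)), rep("female", length(gkids))),
    father_id = c(rep(NA, 2 * cf$n_trios), fathers,
                  rep(NA, length(spouses)), spouses),
    mother_id = c(rep(NA, 2 * cf$n_trios), mothers,
                  rep(NA, length(spouses)), children[g3]))

  # --- polymorphic sites -------------------------------------------------
  n_sites_per <- round(autosomes$length * cf$het_rate)
  site_contig <- rep(autosomes$contig, n_sites_per)
  site_pos <- unlist(lapply(seq_len(nrow(autosomes)), function(i) {
    sort(sample.int(autosomes$length[i], n_sites_per[i]))
  }), use.names = FALSE)
  ns <- length(site_pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ns, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  freq <- stats::rbeta(ns, 1.2, 1.2)

  # haplotype matrices: sites x individuals, one per haplotype copy
  n_ind <- length(ids)
  h1 <- matrix(0L, ns, n_ind, dimnames = list(NULL, ids))
  h2 <- matrix(0L, ns, n_ind, dimnames = list(NULL, ids))
  founder_ids <- ped$id[ped$is_founder]
  for (f in founder_ids) {
    h1[, f] <- stats::rbinom(ns, 1, freq)
    h2[, f] <- stats::rbinom(ns, 1, freq)
  }
  # meiosis: one whole parental haplotype per contig (recorded for truth)
  contig_of_site <- match(site_contig, autosomes$contig)
  transmit <- function(parent) {
    pick <- stats::rbinom(nrow(autosomes), 1, 0.5)  # per-contig choice
    src <- ifelse(pick[contig_of_site] == 1L, h1[, parent], h2[, parent])
    list(hap = src, pick = pick)
  }
  meioses <- list()  # key: child|parent -> per-contig haplotype choice
  nonfounders <- ped$id[!ped$is_founder]
  # children before grandchildren (pedigree order guarantees parents first)
  for (i in nonfounders) {
    fa <- ped$father_id[ped$id == i]; mo <- ped$mother_id[ped$id == i]
    tp <- transmit(fa); tm <- transmit(mo)
    h1[, i] <- tp$hap  # haplotype 1 = paternal by convention
    h2[, i] <- tm$hap
    meioses[[paste0(i, "|", fa)]] <- tp$pick
    meioses[[paste0(i, "|", mo)]] <- tm$pick
  }

  # --- inject DNMs -------------------------------------------------------
  n_dnm <- stats::rpois(cf$n_trios, mu)
  p_pat <- (cf$beta0 / 2 + cf$betaP * L * ages$paternal_age) / mu
  p_pat[!is.finite(p_pat)] <- 0.5
  dnm_list <- list()
  for (t in seq_len(cf$n_trios)) {
    k <- n_dnm[t]
    if (k == 0) next
    ci <- sample.int(nrow(autosomes), k, replace = TRUE,
                     prob = autosomes$length)
    pos <- vapply(ci, function(j) sample.int(autosomes$length[j], 1), 0L)
    r <- sample(bases, k, replace = TRUE)
    a <- vapply(r, function(x) sample(setdiff(bases, x), 1), "")
    parent <- ifelse(stats::runif(k) < p_pat[t], "paternal", "maternal")
    d <- data.frame(
      child_id = children[t], contig = autosomes$contig[ci], pos = pos,
      ref = r, alt = a, parent = parent, stringsAsFactors = FALSE)
    # avoid collisions with standing polymorphisms or other DNM sites
    d <- d[!paste(d$contig, d$pos) %in% paste(site_contig, site_pos), , drop = FALSE]
    d <- d[!duplicated(paste(d$contig, d$pos)), , drop = FALSE]
    dnm_list[[t]] <- d
  }
  dnms <- if (length(dnm_list)) do.call(rbind, dnm_list) else
    data.frame(child_id = character(), contig = character(), pos = integer(),
               ref = character(), alt = character(), parent = character())
  rownames(dnms) <- NULL

  # transmission truth: a DNM sits on the child's paternal (h1) or
  # maternal (h2) haplotype; the grandchild inherits it iff the child's
  # meiosis to the grandchild picked that haplotype on that contig
  dnms$transmitted_to <- rep(NA_character_, nrow(dnms))
  if (cf$grandchildren && nrow(dnms)) {
    for (t in g3) {
      sel <- dnms$child_id == children[t]
      if (!any(sel)) next
      pick <- meioses[[paste0(gkids[t], "|", children[t])]]
      hap_needed <- ifelse(dnms$parent[sel] == "paternal", 1L, 2L)
      co <- match(dnms$contig[sel], autosomes$contig)
      # pick == 1 chooses h1 (paternal copy of the child)
      got <- ifelse(pick[co] == 1L, 1L, 2L) == hap_needed
      dnms$transmitted_to[sel] <- ifelse(got, gkids[t], "")
    }
  }

  # --- observed genotype table (polymorphic sites + DNM sites) -----------
  trios <- enumerate_trios(ped, ages)
  if (!materialize) {
    return(structure(list(
      genotypes = NULL, ped = ped, ages = ages, trios = trios,
      truth = list(dnms = dnms,
                   L = stats::setNames(rep(L, cf$n_trios), children),
                   depth_pass_sites = total_len * cf$diploid_callable_fraction,
                   expected_mu = stats::setNames(mu, children),
                   p_paternal = stats::setNames(p_pat, children)),
      haplotypes = NULL, config = cf, seed = as.integer(seed)
    ), class = "sim_cohort"))
  }
  dn_sites <- unique(dnms[, c("contig", "pos", "ref", "alt")])
  sites <- rbind(
    data.frame(contig = site_contig, pos = site_pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    dn_sites)
  ord <- order(match(sites$contig, autosomes$contig), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  nall <- nrow(sites)

  truth_gt <- matrix(0L, nall, n_ind, dimnames = list(NULL, ids))
  poly_idx <- match(paste(site_contig, site_pos),
                    paste(sites$contig, sites$pos))
  truth_gt[poly_idx, ] <- h1 + h2
  if (nrow(dnms)) {
    di <- match(paste(dnms$contig, dnms$pos), paste(sites$contig, sites$pos))
    for (k in seq_len(nrow(dnms))) {
      carriers <- dnms$child_id[k]
      if (!is.na(dnms$transmitted_to[k]) && nzchar(dnms$transmitted_to[k]))
        carriers <- c(carriers, dnms$transmitted_to[k])
      truth_gt[di[k], carriers] <- truth_gt[di[k], carriers] + 1L
    }
  }

  if (isTRUE(cf$exact_evidence)) {
    # idealized evidence: fixed depth, perfectly balanced het allele
    # depths, both strands represented; used by truth-table tests where
    # every filter must be satisfiable with certainty
    dp <- matrix(cf$depth_mean, nall, n_ind, dimnames = list(NULL, ids))
    ad_alt <- (truth_gt == 1) * round(dp / 2) + (truth_gt == 2) * dp
    gq <- matrix(cf$gq_mean, nall, n_ind, dimnames = list(NULL, ids))
  } else {
    dp <- matrix(stats::rpois(nall * n_ind, cf$depth_mean), nall, n_ind,
                 dimnames = list(NULL, ids))
    ab <- matrix(0, nall, n_ind)
    ab[truth_gt == 0] <- cf$error_alt_rate
    ab[truth_gt == 2] <- 1 - cf$error_alt_rate
    if (any(truth_gt == 1)) {
      nhet <- sum(truth_gt == 1)
      ab[truth_gt == 1] <- stats::plogis(stats::rnorm(nhet, 0, cf$ab_sd / 0.25))
    }
    ad_alt <- matrix(stats::rbinom(nall * n_ind, dp, ab), nall, n_ind,
                     dimnames = list(NULL, ids))
    gq <- matrix(pmin(pmax(round(stats::rnorm(nall * n_ind, cf$gq_mean, cf$gq_sd)), 0), 99),
                 nall, n_ind, dimnames = list(NULL, ids))
  }
  ad_ref <- dp - ad_alt
  fwd_alt <- if (isTRUE(cf$exact_evidence)) floor(ad_alt / 2) else
    matrix(stats::rbinom(nall * n_ind, ad_alt, 0.5), nall, n_ind,
           dimnames = list(NULL, ids))
  rev_alt <- ad_alt - fwd_alt
  concordant <- matrix(stats::runif(nall * n_ind) >= cf$caller_discordance_rate,
                       nall, n_ind, dimnames = list(NULL, ids))

  gt_tab <- genotype_table(sites, gt = truth_gt, dp = dp, gq = gq,
                           ad_ref = ad_ref, ad_alt = ad_alt,
                           fwd_alt = fwd_alt, rev_alt = rev_alt,
                           concordant = concordant, samples = ids)

  structure(list(
    genotypes = gt_tab, ped = ped, ages = ages, trios = trios,
    truth = list(dnms = dnms, L = stats::setNames(rep(L, cf$n_trios), children),
                 depth_pass_sites = total_len * cf$diploid_callable_fraction,
                 expected_mu = stats::setNames(mu, children),
                 p_paternal = stats::setNames(p_pat, children)),
    haplotypes = list(h1 = h1, h2 = h2, sites = sites,
                      poly_index = poly_idx,
                      poly_rev = {
                        rv <- rep(NA_integer_, nall)
                        rv[poly_idx] <- seq_along(poly_idx)
                        rv
                      },
                      genome = autosomes),
    config = cf, seed = as.integer(seed)
  ), class = "sim_cohort")
}

#' Simulate read-pair evidence linking DNMs to nearby heterozygous sites
#'
#' For each true DNM, emits paired-end read observations covering the DNM
#' site and any polymorphic sites within fragment reach in the child. Each
#' read pair is drawn from one of the child's two haplotypes, so alleles
#' co-occurring on a pair are haplotype-consistent with the true parent of
#' origin; pairs from the non-carrier haplotype and pairs covering no
#' informative site are also emitted.
#'
#' @param sim a `sim_cohort` from [simulate_cohort()].
#' @param pairs_per_dnm expected number of read pairs covering each DNM.
#' @param seed integer seed.
#' @return data.frame (read-evidence table) with columns `read_id`,
#'   `child_id`, `contig`, `pos`, `allele` (0 ref / 1 alt).
#' @export
simulate_read_evidence <- function(sim, pairs_per_dnm = 20, seed = 1L) {
  stopifnot(inherits(sim, "sim_cohort"))
  set.seed(as.integer(seed) + 1L)
  cf <- sim$config
  dnms <- sim$truth$dnms
  if (nrow(dnms) == 0L)
    return(data.frame(read_id = character(), child_id = character(),
                      contig = character(), pos = integer(),
                      allele = integer()))
  sites <- sim$haplotypes$sites
  h1 <- sim$haplotypes$h1; h2 <- sim$haplotypes$h2
  site_key <- paste(sites$contig, sites$pos)
  out <- vector("list", nrow(dnms))
  for (k in seq_len(nrow(dnms))) {
    child <- dnms$child_id[k]
    dk <- match(paste(dnms$contig[k], dnms$pos[k]), site_key)
    dnm_hap <- if (dnms$parent[k] == "paternal") 1L else 2L
    npairs <- stats::rpois(1, pairs_per_dnm)
    if (npairs == 0) next
    hap <- sample(1:2, npairs, replace = TRUE)
    start <- dnms$pos[k] - sample.int(cf$fragment_length, npairs, replace = TRUE) + 1L
    rows <- list()
    near <- which(sites$contig == dnms$contig[k] &
                    abs(sites$pos - dnms$pos[k]) < cf$fragment_length)
    for (j in seq_len(npairs)) {
      covered <- c(start[j]:(start[j] + cf$read_length - 1L),
                   (start[j] + cf$fragment_length - cf$read_length):
                     (start[j] + cf$fragment_length - 1L))
      cov_idx <- near[sites$pos[near] %in% covered]
      if (!dnms$pos[k] %in% covered) next
      rid <- sprintf("%s_dnm%d_rp%d", child, k, j)
      alle <- rep(NA_integer_, length(cov_idx))
      for (ii in seq_along(cov_idx)) {
        si <- cov_idx[ii]
        if (si == dk) {
          alle[ii] <- as.integer(hap[j] == dnm_hap)
        } else {
          pi <- sim$haplotypes$poly_rev[si]
          if (!is.na(pi))
            alle[ii] <- if (hap[j] == 1L) h1[pi, child] else h2[pi, child]
        }
      }
      ok <- !is.na(alle)
      rows[[j]] <- data.frame(read_id = rid, child_id = child,
                              contig = dnms$contig[k],
                              pos = sites$pos[cov_idx][ok],
                              allele = alle[ok],
                              stringsAsFactors = FALSE)
    }
    out[[k]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(read_id = character(),
                                      child_id = character(),
                                      contig = character(), pos = integer(),
                                      allele = integer())
  rownames(res) <- NULL
  res
}

#' Simulate an X-versus-autosome branch-length table
#'
#' Inverts the standard relationship between the male-to-female mutation
#' rate ratio alpha and the X/autosome substitution-rate ratio,
#' `X/A = (4 + 2 alpha) / (3 + 3 alpha)`, producing one X branch length and
#' `autosome_count` autosomal lengths with multiplicative noise.
#'
#' @param alpha_true true male-to-female rate ratio (> 0).
#' @param autosome_count number of autosomes.
#' @param noise_sd multiplicative jitter (sd of a mean-1 normal factor)
#'   applied to each autosomal length.
#' @param branch branch label.
#' @param a_len mean autosomal branch length (substitutions/site).
#' @param seed integer seed.
#' @return data.frame with columns `branch`, `chromosome`, `is_X`, `length`.
#' @export
simulate_branch_lengths <- function(alpha_true, autosome_count = 31,
                                    noise_sd = 0, branch = "focal",
                                    a_len = 0.1, seed = 1L) {
  if (alpha_true <= 0) stop("alpha_true must be > 0")
  set.seed(as.integer(seed) + 2L)
  ratio <- (4 + 2 * alpha_true) / (3 + 3 * alpha_true)
  a <- a_len * (1 + stats::rnorm(autosome_count, 0, noise_sd))
  a <- pmax(a, 1e-9)
  data.frame(
    branch = branch,
    chromosome = c("chrX", paste0("chr", seq_len(autosome_count))),
    is_X = c(TRUE, rep(FALSE, autosome_count)),
    length = c(ratio * a_len, a),
    stringsAsFactors = FALSE)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the genotype VCF, PED, ages TSV, read-evidence TSV and a JSON
#' truth file into `dir`.
#'
#' @param sim a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @param evidence optional precomputed read-evidence table.
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort <- function(sim, dir, evidence = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             ped = file.path(dir, "cohort.ped"),
             ages = file.path(dir, "ages.tsv"),
             evidence = file.path(dir, "read_evidence.tsv"),
             truth = file.path(dir, "truth.json"))
  write_genotype_vcf(sim$genotypes, paths["vcf"])
  write_pedigree(sim$ped, paths["ped"])
  utils::write.table(sim$ages, paths["ages"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (is.null(evidence)) evidence <- simulate_read_evidence(sim, seed = sim$seed)
  utils::write.table(evidence, paths["evidence"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
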
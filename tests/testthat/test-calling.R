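test_that("ABHet prefilter removes reference-biased sites only", {
  gt <- tiny_trio_table(list(
    list(gt = c(0, 0, 1), ad_ref = c(30, 30, 5), ad_alt = c(0, 0, 45)),
    list(gt = c(0, 0, 1), ad_ref = c(30, 30, 25), ad_alt = c(0, 0, 25)),
    list(gt = c(0, 0, 1), ad_ref = c(30, 30, 41), ad_alt = c(0, 0, 9)),
    list(gt = c(0, 0, 0))  # no het carrier: retained, not evaluable
  ))
  expect_message(out <- prefilter_sites(gt), "ABHet")
  expect_equal(out$sites$pos, c(2000L, 4000L))
  expect_equal(attr(out, "n_removed_abhet"), 2L)
})

test_that("Mendelian violations are exactly homref x homref -> het", {
  gt <- tiny_trio_table(list(
    list(gt = c(0, 0, 1)),   # candidate
    list(gt = c(0, 1, 1)),   # het parent: no
    list(gt = c(0, 0, 2)),   # homalt child: no
    list(gt = c(NA, 0, 1)),  # missing member: skipped
    list(gt = c(1, 1, 0))    # no
  ))
  cand <- find_mendelian_violations(tiny_trio(), gt)
  expect_equal(cand$pos, 1000L)
  # X-linked exclusion
  expect_equal(nrow(find_mendelian_violations(tiny_trio(), gt,
                                              exclude_contigs = "chr1")), 0L)
})

test_that("each of the seven filters fails exactly its violators", {
  dm <- c(fa = 40, mo = 40, ch = 40)
  base <- list(gt = c(0, 0, 1))
  variants <- list(
    clean       = base,
    depth_low   = modifyList(base, list(dp = c(40, 14, 40))),
    depth_high  = modifyList(base, list(dp = c(40, 40, 70))),
    gq_exact60  = modifyList(base, list(gq = c(80, 80, 60))),
    discordant  = modifyList(base, list(concordant = c(1, 1, 0))),
    one_strand  = modifyList(base, list(ad_ref = c(40, 40, 20),
                                        ad_alt = c(0, 0, 20),
                                        fwd_alt = c(0, 0, 20),
                                        rev_alt = c(0, 0, 0))),
    parent_read = modifyList(base, list(ad_ref = c(39, 40, 20),
                                        ad_alt = c(1, 0, 20))),
    ab_exact    = modifyList(base, list(ad_ref = c(40, 40, 13),
                                        ad_alt = c(0, 0, 7))),
    ab_above    = modifyList(base, list(ad_ref = c(40, 40, 13),
                                        ad_alt = c(0, 0, 8)))
  )
  gt <- tiny_trio_table(variants)
  cand <- find_mendelian_violations(tiny_trio(), gt)
  out <- apply_dnm_filters(cand, gt, tiny_trio(), dm)
  rownames(out) <- names(variants)
  fails <- function(v, f) out[v, paste0("filter_", f)] == "fail"
  expect_true(out["clean", "pass"])
  expect_true(fails("depth_low", "depth"))
  expect_true(fails("depth_high", "depth"))   # 70 > 40 + 4*sqrt(40)
  expect_true(fails("gq_exact60", "gq"))      # strictly greater than 60
  expect_true(fails("discordant", "concordance"))
  expect_true(fails("one_strand", "strand"))
  expect_true(fails("parent_read", "parent_reads"))
  expect_true(fails("ab_exact", "ab"))        # 7/20 = 0.35 fails strictly
  expect_true(out["ab_above", "pass"])        # 8/21 ~ 0.381 passes
  # single-filter violators fail only their own filter
  for (v in c("depth_low", "gq_exact60", "discordant", "parent_read")) {
    fcols <- grep("^filter_", names(out), value = TRUE)
    expect_equal(sum(out[v, fcols] == "fail"), 1L, label = v)
  }
})

test_that("missing strand counts fail closed as not-evaluable", {
  gt <- tiny_trio_table(list(list(gt = c(0, 0, 1))))
  gt$fwd_alt[] <- NA; gt$rev_alt[] <- NA
  cand <- find_mendelian_violations(tiny_trio(), gt)
  out <- apply_dnm_filters(cand, gt, tiny_trio(), c(fa = 40, mo = 40, ch = 40))
  expect_equal(out$filter_strand, "not_evaluable")
  expect_false(out$pass)
})

test_that("filter verdicts are order-independent and five-x mode differs", {
  gt <- tiny_trio_table(list(list(gt = c(0, 0, 1), dp = c(40, 40, 70))))
  cand <- find_mendelian_violations(tiny_trio(), gt)
  dm <- c(fa = 40, mo = 40, ch = 40)
  a <- apply_dnm_filters(cand, gt, tiny_trio(), dm, max_depth_mode = "sigma4")
  b <- apply_dnm_filters(cand, gt, tiny_trio(), dm, max_depth_mode = "fivex")
  expect_equal(a$filter_depth, "fail")   # 70 > 65.3
  expect_equal(b$filter_depth, "pass")   # 70 < 200
  expect_equal(max_depth_cutoff(40), 40 + 4 * sqrt(40))
  expect_equal(max_depth_cutoff(40, "fivex"), 200)
})

test_that("cohort-absence filter exempts siblings and descendants", {
  sim <- clean_sim(seed = 17, n_trios = 3, grandchildren = 1)
  called <- call_dnms(sim$genotypes, sim$trios)
  truth_key <- with(sim$truth$dnms, paste(child_id, contig, pos))
  called_key <- with(called$mutations, paste(child_id, contig, pos))
  # clean evidence: every true DNM recovered, nothing else
  expect_setequal(called_key, truth_key)
})

test_that("on clean cohorts calling is exact; transmission approximates one half", {
  sim <- clean_sim(seed = 29, n_trios = 6, grandchildren = 6)
  called <- call_dnms(sim$genotypes, sim$trios)
  truth <- sim$truth$dnms
  expect_equal(nrow(called$mutations[!grepl("_gc$", called$mutations$child_id), ]),
               nrow(truth))
  tt <- assess_transmission(called$mutations, sim$genotypes, sim$ped)
  # truth comparison: assessed transmissions match the simulator's record
  truth_trans <- sum(nzchar(truth$transmitted_to), na.rm = TRUE)
  expect_equal(sum(tt$transmitted), truth_trans)
  # haplotype-block transmission is Bernoulli(1/2) per contig x parent:
  # pooled over many blocks the fraction should be near one half
  n_blocks <- 6 * 3 * 2
  expect_lt(abs(sum(tt$transmitted) / sum(tt$assessable) - 0.5),
            3 * sqrt(0.25 / n_blocks) + 0.05)
})

test_that("contig classification follows the significance and depth rules", {
  set.seed(1)
  mk <- function(contig, male_dp, female_dp, male_het, female_het) {
    data.frame(contig = contig,
               individual = paste0("i", 1:8),
               sex = rep(c("male", "female"), each = 4),
               depth = c(male_dp, female_dp), het = c(male_het, female_het))
  }
  qc <- rbind(
    mk("cA", rnorm(4, 40, .5), rnorm(4, 40, .5), rnorm(4, 1e-3, 1e-5),
       rnorm(4, 1e-3, 1e-5)),
    mk("cX", rnorm(4, 12, .5), rnorm(4, 24, .5), rnorm(4, 1e-4, 1e-5),
       rnorm(4, 1e-3, 1e-5)),
    mk("cU", rnorm(4, 40, .5), rnorm(4, 40, .5), rnorm(4, 1e-4, 1e-6),
       rnorm(4, 1e-3, 1e-6)))
  out <- classify_contigs(qc)
  expect_equal(out$label[out$contig == "cA"], "autosomal")
  expect_equal(out$label[out$contig == "cX"], "x_linked")
  expect_equal(out$label[out$contig == "cU"], "unfiltered")

  qc_m <- qc[qc$sex == "male", ]
  expect_warning(out2 <- classify_contigs(qc_m), "single-sex")
  expect_true(all(out2$label == "autosomal"))
})

test_that("sibling-shared and multinucleotide annotations are applied", {
  sim <- clean_sim(seed = 31, n_trios = 2)
  called <- call_dnms(sim$genotypes, sim$trios)
  m <- called$mutations
  # inject a forged pair of neighbouring rows to exercise MNM clustering
  expect_true(all(is.na(m$mnm_cluster_id) |
                    ave(m$pos, m$mnm_cluster_id, FUN = length) > 1))
})
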
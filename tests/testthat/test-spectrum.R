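test_that("mutation classification collapses strands and flags contexts", {
  a <- classify_mutation("C", "T", "ACG")
  expect_equal(a$type, "C>T"); expect_true(a$is_transition)
  expect_true(a$is_cpg); expect_false(a$is_tpc)
  # complement strand collapses to the same CpG C>T
  b <- classify_mutation("G", "A", "CGT")
  expect_equal(b[1, ], a[1, ], ignore_attr = TRUE)
  d <- classify_mutation("A", "T", "CAT")
  expect_equal(d$type, "T>A"); expect_false(d$is_transition)
  tpc <- classify_mutation("C", "T", "TCA")
  expect_true(tpc$is_tpc); expect_false(tpc$is_cpg)
  # reverse complement of TpC context: G>A with 3' A-complement layout
  tpc2 <- classify_mutation("G", "A", "TGA")
  expect_true(tpc2$is_tpc)
  expect_error(classify_mutation("C", "T", "AAG"), "centre")
  expect_error(classify_mutation("C", "T", "ACGT"), "trinucleotide")
})

test_that("classification is idempotent and the six types partition", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(ref = bases, alt = bases, l = bases, r = bases,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  ctx <- paste0(combos$l, combos$ref, combos$r)
  cl <- classify_mutation(combos$ref, combos$alt, ctx)
  expect_setequal(unique(cl$type),
                  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  # double reverse-complement returns the identical classification
  rc <- function(s) pedmut:::revcomp(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cl2 <- classify_mutation(comp[combos$ref], comp[combos$alt], rc(ctx))
  expect_equal(cl2$type, cl$type)
  expect_equal(cl2$is_cpg, cl$is_cpg)
  expect_equal(cl2$is_tpc, cl$is_tpc)
})

test_that("spectrum summary counts types, Ti:Tv and CpG fraction", {
  mk <- function(ref, alt, ctx) data.frame(ref = ref, alt = alt,
                                           context = ctx)
  m <- rbind(mk(rep("C", 9), rep("T", 9),
                c(rep("ACG", 4), rep("ACA", 5))),
             mk(rep("C", 4), rep("A", 4), rep("ACA", 4)))
  s <- spectrum_summary(m)
  expect_equal(unname(s$counts["C>T"]), 9L)
  expect_equal(unname(s$counts["C>A"]), 4L)
  expect_equal(s$titv, 9 / 4)
  expect_equal(s$cpg_ct, 4L)
  expect_equal(s$cpg_fraction, 4 / 13)
  # all CpG transitions: fraction one, Ti:Tv infinite
  s2 <- spectrum_summary(mk(rep("C", 3), rep("T", 3), rep("GCG", 3)))
  expect_equal(s2$cpg_fraction, 1)
  expect_equal(s2$titv, Inf)
  s0 <- spectrum_summary(m[0, ])
  expect_equal(s0$total, 0L)
  expect_true(is.na(s0$titv))
})

test_that("sample odds ratios reproduce the published Fisher statistics", {
  t1 <- fisher_or_test(9, 5, 33, 35)
  expect_equal(t1$or, 1.91, tolerance = 0.005)
  t2 <- fisher_or_test(8, 1, 28, 5)
  expect_equal(t2$or, 1.43, tolerance = 0.005)
  expect_equal(round(t2$p, 1), 1.0)
  t3 <- fisher_or_test(5, 5, 20, 20)
  expect_equal(t3$or, 1)
  expect_equal(t3$p, 1)
  # zero-cell handling
  expect_equal(fisher_or_test(3, 0, 10, 10)$or, Inf)
})

test_that("Fisher p-values match hypergeometric enumeration", {
  tabs <- list(c(9, 5, 33, 35), c(8, 1, 28, 5), c(2, 9, 8, 3),
               c(0, 7, 12, 2), c(20, 30, 40, 10))
  for (t in tabs) {
    expect_equal(fisher_or_test(t[1], t[2], t[3], t[4])$p,
                 fisher_two_sided_oracle(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-9, label = paste(t, collapse = ","))
  }
})

test_that("TpC enrichment tests build the published-style tables", {
  # construct phased C>T mutations hitting the (9,5;33,35) sex table:
  # 9 maternal TpC>TpT, 5 paternal TpC>TpT, 33/35 other non-CpG C>T
  mk <- function(n, phase, ctx, age) {
    if (n == 0) return(NULL)
    data.frame(ref = "C", alt = "T", context = ctx, phase = phase,
               maternal_age = age)[rep(1, n), ]
  }
  m <- rbind(mk(8, "maternal", "TCA", 20), mk(1, "maternal", "TCA", 10),
             mk(5, "paternal", "TCA", 10),
             mk(20, "maternal", "ACA", 20), mk(4, "maternal", "ACT", 10),
             mk(30, "paternal", "ACA", 10))
  out <- tpc_enrichment_tests(m)
  # overlapping categories as printed: TpC>TpT is a subset of the C>T class
  expect_equal(unname(out$sex$table), c(9, 5, 33, 35))
  expect_equal(out$sex$or, 1.91, tolerance = 0.005)
  expect_equal(unname(out$maternal_age$table), c(8, 1, 28, 5))
  expect_equal(out$maternal_age$or, 1.43, tolerance = 0.005)
  # the non-overlapping variant removes the signature class from the base
  outd <- tpc_enrichment_tests(m, disjoint = TRUE)
  expect_equal(unname(outd$sex$table), c(9, 5, 24, 30))
})

test_that("exact binomial transmission test matches full enumeration", {
  for (kn in list(c(160, 327), c(53, 117), c(5, 10), c(0, 8), c(7, 7),
                  c(250, 489))) {
    expect_equal(transmission_test(kn[1], kn[2])$p.value,
                 binom_two_sided_oracle(kn[1], kn[2]),
                 tolerance = 1e-9, label = paste(kn, collapse = "/"))
  }
  expect_equal(transmission_test(5, 10)$p.value, 1)
  expect_error(transmission_test(11, 10), "k <= n")
})

test_that("spectrum comparison is calibrated and detects gross differences", {
  types <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  v <- function(x) stats::setNames(x, types)
  same <- list(v(c(5, 5, 30, 5, 15, 5)), v(c(5, 5, 30, 5, 15, 5)))
  expect_equal(spectrum_comparison(same)$p.value, 1)
  diffr <- list(v(c(0, 0, 50, 0, 0, 0)), v(c(0, 0, 0, 0, 0, 50)))
  expect_lt(spectrum_comparison(diffr)$p.value, 0.001)

  # null calibration: same-multinomial groups give roughly uniform P
  set.seed(99)
  p <- replicate(300, {
    probs <- c(.1, .1, .35, .1, .25, .1)
    g1 <- v(as.vector(rmultinom(1, 60, probs)))
    g2 <- v(as.vector(rmultinom(1, 60, probs)))
    spectrum_comparison(list(g1, g2), B = 500)$p.value
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_warning(
    spectrum_comparison(list(v(rep(0, 6)), same[[1]], same[[2]])),
    "zero total")
})

test_that("relatedness coefficient separates identical, parent-child, unrelated", {
  set.seed(5)
  n <- 20000
  f <- runif(n, 0.2, 0.8)
  draw <- function() rbinom(n, 1, f) + rbinom(n, 1, f)
  a <- draw()
  expect_equal(relatedness_cor(a, a), 1)
  b <- draw()
  expect_lt(abs(relatedness_cor(a, b)), 0.05)
  # parent-child: child inherits one allele from the parent
  pat <- rbinom(n, 1, a / 2)        # transmitted allele from parent a
  child <- pat + rbinom(n, 1, f)    # other allele from the population
  child <- pmin(child, 2)
  expect_lt(abs(relatedness_cor(a, child) - 0.5), 0.1)
  expect_error(relatedness_cor(a[1:10], b[1:10]), "at least")
})
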
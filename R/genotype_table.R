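#' Per-site, per-sample genotype table
#'
#' The substrate for DNM calling and callability estimation: biallelic SNV
#' sites (1-based VCF coordinates) with, for every sample, a genotype call,
#' read depth, genotype quality, ref/alt allele depths, forward/reverse
#' strand counts of the alt allele, and a second-caller concordance flag.
#' Genotypes are coded `0` homref, `1` het, `2` homalt, `NA` missing.
#'
#' @param sites data.frame with columns `contig`, `pos`, `ref`, `alt`.
#' @param gt,dp,gq,ad_ref,ad_alt numeric matrices, sites x samples.
#' @param fwd_alt,rev_alt optional strand-count matrices (`NA` when the
#'   caller did not emit strand counts; the strand filter then reports
#'   not-evaluable).
#' @param concordant optional logical matrix: was the call reproduced by the
#'   second caller. Defaults to `TRUE` everywhere.
#' @param samples sample names; defaults to `colnames(gt)`.
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(sites, gt, dp, gq, ad_ref, ad_alt,
                           fwd_alt = NULL, rev_alt = NULL,
                           concordant = NULL, samples = colnames(gt)) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "double"
  n <- nrow(sites); m <- ncol(gt)
  if (is.null(samples)) samples <- paste0("S", seq_len(m))
  as_m <- function(x, default) {
    if (is.null(x)) x <- matrix(default, n, m)
    x <- as.matrix(x)
    if (!is.logical(default)) storage.mode(x) <- "double"
    stopifnot(nrow(x) == n, ncol(x) == m)
    x
  }
  obj <- list(sites = as.data.frame(sites), gt = gt,
              dp = as_m(dp, NA_real_), gq = as_m(gq, NA_real_),
              ad_ref = as_m(ad_ref, NA_real_), ad_alt = as_m(ad_alt, NA_real_),
              fwd_alt = as_m(fwd_alt, NA_real_), rev_alt = as_m(rev_alt, NA_real_),
              concordant = as_m(concordant, TRUE), samples = samples)
  for (f in c("gt", "dp", "gq", "ad_ref", "ad_alt", "fwd_alt", "rev_alt",
              "concordant")) colnames(obj[[f]]) <- samples
  stopifnot(all(obj$ad_ref >= 0, na.rm = TRUE), all(obj$ad_alt >= 0, na.rm = TRUE))
  structure(obj, class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d sites x %d samples (%s)\n",
              nrow(x$sites), length(x$samples),
              paste(utils::head(x$samples, 4), collapse = ", ")))
  invisible(x)
}

#' @export
`[.genotype_table` <- function(x, i, ...) {
  out <- x
  out$sites <- x$sites[i, , drop = FALSE]
  rownames(out$sites) <- NULL
  for (f in c("gt", "dp", "gq", "ad_ref", "ad_alt", "fwd_alt", "rev_alt",
              "concordant"))
    out[[f]] <- x[[f]][i, , drop = FALSE]
  out
}

gt_code <- function(gt_strings) {
  g <- sub("\\|", "/", gt_strings)
  out <- rep(NA_real_, length(g))
  out[g %in% c("0/0")] <- 0
  out[g %in% c("0/1", "1/0")] <- 1
  out[g %in% c("1/1")] <- 2
  out
}

#' Read a multi-sample VCF into a genotype table
#'
#' Consumes a VCF 4.x with per-sample `GT:AD:DP:GQ` (and optionally `SAC`
#' strand counts as ref-fwd,ref-rev,alt-fwd,alt-rev and a `CC` 0/1 flag for
#' second-caller concordance). Only biallelic SNV records are kept; indels
#' and multiallelic records are dropped and the counts reported via
#' `message()`. Missing FORMAT fields become `NA` so downstream filters can
#' report "not evaluable" instead of failing.
#'
#' @param path path to an (uncompressed or gzipped) VCF.
#' @return a [genotype_table()].
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(nrow(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  keep <- !multi & !indel
  if (any(indel)) message(sum(indel), " indel record(s) removed")
  if (any(multi)) message(sum(multi), " multiallelic record(s) removed")
  v <- v[keep, ]
  fix <- fix[keep, , drop = FALSE]
  sites <- data.frame(contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)

  ex <- function(el, fun = function(z) suppressWarnings(as.numeric(z))) {
    m <- tryCatch(vcfR::extract.gt(v, element = el), error = function(e) NULL)
    if (is.null(m)) return(NULL)
    apply(m, 2, fun)
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt <- apply(gt_raw, 2, gt_code)
  if (nrow(sites) == 1L) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, colnames(gt_raw)))
  dp <- ex("DP"); gq <- ex("GQ")
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  split_ad <- function(k) {
    if (is.null(ad)) return(NULL)
    apply(ad, 2, function(col) suppressWarnings(as.numeric(
      vapply(strsplit(col, ","), function(x) x[k], NA_character_))))
  }
  ad_ref <- split_ad(1); ad_alt <- split_ad(2)
  sac <- tryCatch(vcfR::extract.gt(v, element = "SAC"), error = function(e) NULL)
  split_sac <- function(k) {
    if (is.null(sac)) return(NULL)
    apply(sac, 2, function(col) suppressWarnings(as.numeric(
      vapply(strsplit(col, ","), function(x) x[k], NA_character_))))
  }
  cc <- ex("CC")
  fixdim <- function(x) {
    if (is.null(x)) return(NULL)
    if (nrow(sites) == 1L && is.null(dim(x)))
      x <- matrix(x, nrow = 1)
    x
  }
  genotype_table(sites, gt = gt, dp = fixdim(dp), gq = fixdim(gq),
                 ad_ref = fixdim(ad_ref), ad_alt = fixdim(ad_alt),
                 fwd_alt = fixdim(split_sac(3)), rev_alt = fixdim(split_sac(4)),
                 concordant = if (is.null(cc)) NULL else fixdim(cc) == 1,
                 samples = colnames(gt_raw))
}

#' Write a genotype table as a plain-text VCF
#'
#' Emits VCF 4.2 with per-sample `GT:AD:DP:GQ:SAC:CC` so that
#' [read_genotype_vcf()] round-trips all calls and annotations.
#'
#' @param x a [genotype_table()].
#' @param path output path (plain text).
#' @export
write_genotype_vcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  contigs <- unique(x$sites$contig)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pedmut",
    paste0("##contig=<ID=", contigs, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=SAC,Number=.,Type=Integer,Description="Strand allele counts: ref-fwd,ref-rev,alt-fwd,alt-rev">',
    '##FORMAT=<ID=CC,Number=1,Type=Integer,Description="Second-caller concordant (1) or not (0)">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  ), con)
  if (nrow(x$sites) == 0L) return(invisible(path))
  gt_str <- matrix(".", nrow(x$gt), ncol(x$gt))
  gt_str[x$gt == 0] <- "0/0"; gt_str[x$gt == 1] <- "0/1"; gt_str[x$gt == 2] <- "1/1"
  gt_str[is.na(x$gt)] <- "./."
  num <- function(m) ifelse(is.na(m), ".", format(m, trim = TRUE, scientific = FALSE))
  fwd_ref <- pmax(x$dp - x$ad_alt, 0)  # placeholder ref strand split
  sac <- matrix(paste(num(floor(fwd_ref / 2)), num(ceiling(fwd_ref / 2)),
                      num(x$fwd_alt), num(x$rev_alt), sep = ","),
                nrow(x$gt), ncol(x$gt))
  sac[is.na(x$fwd_alt) | is.na(x$rev_alt)] <- "."
  fields <- matrix(paste(gt_str,
                         paste(num(x$ad_ref), num(x$ad_alt), sep = ","),
                         num(x$dp), num(x$gq), sac,
                         num(as.integer(x$concordant)), sep = ":"),
                   nrow(x$gt), ncol(x$gt))
  lines <- paste(x$sites$contig, x$sites$pos, ".", x$sites$ref, x$sites$alt,
                 ".", "PASS", ".", "GT:AD:DP:GQ:SAC:CC",
                 apply(fields, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
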
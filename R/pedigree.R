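#' Read a PLINK-style six-column PED file
#'
#' Parses a whitespace-delimited pedigree file with columns family, id,
#' father, mother, sex, phenotype. Unknown parents are coded `"0"`; sex is
#' mapped 1 to male, 2 to female, anything else to unknown. The pedigree is
#' validated structurally: an id may not act as both a father and a mother,
#' a recorded father (mother) may not be recorded as female (male), and the
#' ancestry graph must be acyclic.
#'
#' @param path path to a PED file. An empty file yields an empty pedigree.
#' @return A `pedigree`: a data.frame with columns `id`, `sex`
#'   (`"male"`/`"female"`/`"unknown"`), `father_id`, `mother_id` (`NA` when
#'   unknown), and `is_founder` (neither parent present in the file).
#' @export
read_pedigree <- function(path) {
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "character",
                      stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) return(empty_pedigree())
  if (ncol(raw) < 6L) stop("PED file must have six columns")
  pedigree(id = raw[[2]],
           sex = c("1" = "male", "2" = "female")[raw[[5]]],
           father_id = ifelse(raw[[3]] == "0", NA_character_, raw[[3]]),
           mother_id = ifelse(raw[[4]] == "0", NA_character_, raw[[4]]))
}

empty_pedigree <- function() {
  structure(data.frame(id = character(), sex = character(),
                       father_id = character(), mother_id = character(),
                       is_founder = logical(), stringsAsFactors = FALSE),
            class = c("pedigree", "data.frame"))
}

#' Construct and validate a pedigree
#'
#' @param id individual identifiers (unique).
#' @param sex `"male"`, `"female"`, or `"unknown"`/`NA`.
#' @param father_id,mother_id parent ids or `NA`.
#' @return a `pedigree` data.frame; see [read_pedigree()].
#' @export
pedigree <- function(id, sex, father_id = NA_character_,
                     mother_id = NA_character_) {
  sex <- as.character(sex)
  sex[is.na(sex) | !sex %in% c("male", "female")] <- "unknown"
  ped <- data.frame(id = as.character(id), sex = sex,
                    father_id = as.character(father_id),
                    mother_id = as.character(mother_id),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")

  fathers <- stats::na.omit(unique(ped$father_id))
  mothers <- stats::na.omit(unique(ped$mother_id))
  both <- intersect(fathers, mothers)
  if (length(both))
    stop("pedigree sex conflict: id(s) used as both father and mother: ",
         paste(both, collapse = ", "))
  bad_f <- fathers[fathers %in% ped$id[ped$sex == "female"]]
  bad_m <- mothers[mothers %in% ped$id[ped$sex == "male"]]
  if (length(bad_f) || length(bad_m))
    stop("pedigree sex conflict: parent sex inconsistent for: ",
         paste(c(bad_f, bad_m), collapse = ", "))

  # cycle check: repeatedly peel individuals whose parents have all been
  # peeled (vectorised Kahn-style peeling)
  fa_i <- match(ped$father_id, ped$id)
  mo_i <- match(ped$mother_id, ped$id)
  alive <- rep(TRUE, nrow(ped))
  repeat {
    p_fa <- !is.na(fa_i) & alive[replace(fa_i, is.na(fa_i), 1L)]
    p_mo <- !is.na(mo_i) & alive[replace(mo_i, is.na(mo_i), 1L)]
    peel <- alive & !p_fa & !p_mo
    if (!any(peel)) break
    alive[peel] <- FALSE
  }
  if (any(alive)) stop("cyclic ancestry in pedigree: ",
                       paste(ped$id[alive], collapse = ", "))

  ped$is_founder <- !(ped$father_id %in% ped$id) & !(ped$mother_id %in% ped$id)
  structure(ped, class = c("pedigree", "data.frame"))
}

#' Enumerate trios from a pedigree
#'
#' Returns one trio per child whose father and mother are both present in
#' the pedigree. Siblings yield separate trios and an individual mating with
#' several partners yields one trio per offspring. Children with exactly one
#' in-pedigree parent are excluded with a warning.
#'
#' @param ped a [pedigree()].
#' @param ages optional data.frame with columns `child_id`, `paternal_age`,
#'   `maternal_age` (years at conception); unknown ages stay `NA`.
#' @return data.frame with columns `child_id`, `father_id`, `mother_id`,
#'   `paternal_age`, `maternal_age`.
#' @export
enumerate_trios <- function(ped, ages = NULL) {
  has_f <- ped$father_id %in% ped$id
  has_m <- ped$mother_id %in% ped$id
  half <- ped$id[xor(has_f, has_m)]
  if (length(half))
    warning("excluded child(ren) with exactly one in-pedigree parent: ",
            paste(half, collapse = ", "))
  kids <- ped[has_f & has_m, , drop = FALSE]
  out <- data.frame(child_id = kids$id, father_id = kids$father_id,
                    mother_id = kids$mother_id,
                    paternal_age = rep(NA_real_, nrow(kids)),
                    maternal_age = rep(NA_real_, nrow(kids)),
                    stringsAsFactors = FALSE)
  if (!is.null(ages) && nrow(out)) {
    i <- match(out$child_id, ages$child_id)
    out$paternal_age <- ages$paternal_age[i]
    out$maternal_age <- ages$maternal_age[i]
    bad <- !is.na(out$paternal_age) & out$paternal_age <= 0 |
      !is.na(out$maternal_age) & out$maternal_age <= 0
    if (any(bad)) stop("parental ages must be positive")
  }
  rownames(out) <- NULL
  out
}

#' Write a pedigree as a six-column PED file
#' @param ped a [pedigree()].
#' @param path output path.
#' @param family family id written in column 1.
#' @export
write_pedigree <- function(ped, path, family = "FAM1") {
  sexcode <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  utils::write.table(
    data.frame(family, ped$id,
               ifelse(is.na(ped$father_id), "0", ped$father_id),
               ifelse(is.na(ped$mother_id), "0", ped$mother_id),
               sexcode, "0"),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Reconstructed aye-aye pedigree fixture
#'
#' An 18-individual extended pedigree with 12 trios matching the published
#' cohort's counts: several parent pairs with multiple offspring, two
#' individuals appearing in multiple matings, and one second-generation
#' female who is both an offspring and a mother. Edge-level topology is a
#' reconstruction consistent with those counts (the published figure is
#' graphical only), so per-trio identities of parents should not be relied
#' on beyond the two documented old mothers (100949, 100943).
#'
#' @return a [pedigree()] with 18 individuals.
#' @export
aye_aye_pedigree <- function() {
  pedigree(
    id = c("100936", "100943", "100949", "100937", "100948", "100934",
           "100933", "100935", "100944", "100945",
           "100947", "100938", "100950", "100940",
           "100942", "100939", "100941", "100946"),
    sex = c("male", "female", "female", "male", "male", "female",
            "male", "female", "male", "female",
            "female", "male", "female", "male",
            "male", "female", "male", "female"),
    father_id = c(NA, NA, NA, NA, NA, NA,
                  "100936", "100936", "100936", "100936",
                  "100937", "100948", "100937", "100937",
                  "100948", "100948", "100936", "100937"),
    mother_id = c(NA, NA, NA, NA, NA, NA,
                  "100943", "100943", "100943", "100943",
                  "100949", "100949", "100934", "100934",
                  "100935", "100935", "100934", "100935"))
}
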
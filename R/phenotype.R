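#' CYP2C19 star-allele and metabolic-phenotype classification
#'
#' Two common functional CYP2C19 variants are used to call star alleles on
#' phased haplotypes: rs4244285 (G>A; the A allele defines the
#' non-functional *2 allele) and rs12248560 (C>T; the T allele defines the
#' increased-function *17 allele). A haplotype carrying both variant alleles
#' would be a *2/*17 recombinant, which the star nomenclature does not
#' define; phased input containing one is treated as corrupt and rejected.
#'
#' @param rs4244285 character vector of "G"/"A" alleles (one per haplotype).
#' @param rs12248560 character vector of "C"/"T" alleles, same length.
#' @param who optional identifier(s) used in error messages.
#' @return character vector of star alleles: "*1", "*2" or "*17".
#' @export
#' @examples
#' star_allele(c("A", "G", "G"), c("C", "T", "C"))  # *2, *17, *1
star_allele <- function(rs4244285, rs12248560, who = NULL) {
  stopifnot(length(rs4244285) == length(rs12248560))
  ok1 <- rs4244285 %in% c("G", "A")
  ok2 <- rs12248560 %in% c("C", "T")
  if (!all(ok1 & ok2)) {
    stop("invalid allele codes at rs4244285/rs12248560 (expect G/A and C/T)")
  }
  recomb <- rs4244285 == "A" & rs12248560 == "T"
  if (any(recomb)) {
    lab <- if (is.null(who)) which(recomb) else who[recomb]
    stop("recombinant *2+*17 haplotype (rs4244285=A and rs12248560=T) for: ",
         paste(unique(lab), collapse = ", "))
  }
  ifelse(rs4244285 == "A", "*2", ifelse(rs12248560 == "T", "*17", "*1"))
}

# canonical level order used throughout: slowest (PM) to fastest (UM)
.pheno_levels <- c("PM", "IM", "IM+", "EM", "EM+", "UM")

#' Six-level metabolic phenotype from a star-allele diplotype
#'
#' Maps the unordered pair of star alleles to the published six-level
#' scheme: *2/*2 = PM, *2/*1 = IM, *2/*17 = IM+, *1/*1 = EM, *1/*17 = EM+,
#' *17/*17 = UM. The classification is symmetric in the two alleles.
#'
#' @param a1,a2 character vectors of star alleles ("*1", "*2", "*17").
#' @return character vector of phenotype levels (PM/IM/IM+/EM/EM+/UM).
#' @seealso [activity_score()] for the inverted ordinal coding.
#' @export
metabolic_phenotype <- function(a1, a2) {
  stopifnot(length(a1) == length(a2),
            all(a1 %in% c("*1", "*2", "*17")),
            all(a2 %in% c("*1", "*2", "*17")))
  key <- paste(pmin(a1, a2), pmax(a1, a2))  # order-insensitive
  map <- c("*2 *2" = "PM", "*1 *2" = "IM", "*17 *2" = "IM+",
           "*1 *1" = "EM", "*1 *17" = "EM+", "*17 *17" = "UM")
  unname(map[key])
}

#' Inverted activity score for a metabolic phenotype
#'
#' Ordinal exposure coding where higher means slower metabolism: UM = 1,
#' EM+ = 2, EM = 3, IM+ = 4, IM = 5, PM = 6. The endpoints (UM = 1, PM = 6)
#' are fixed by the scheme; the interior follows the rank order of the six
#' levels and can be overridden if a different interior spacing is wanted.
#'
#' @param phenotype character vector of levels (PM/IM/IM+/EM/EM+/UM).
#' @param score_map named integer vector overriding the default mapping.
#' @return integer vector of scores in 1..6.
#' @export
activity_score <- function(phenotype,
                           score_map = c(UM = 1L, "EM+" = 2L, EM = 3L,
                                         "IM+" = 4L, IM = 5L, PM = 6L)) {
  stopifnot(all(phenotype %in% names(score_map)))
  unname(score_map[phenotype])
}

#' Classify a cohort of phased genotypes
#'
#' Takes a genotype table (one row per person, columns `h1_rs4244285`,
#' `h1_rs12248560`, `h2_rs4244285`, `h2_rs12248560`, optionally
#' `h1_rs2860840`, `h1_rs11188059`, `h2_rs2860840`, `h2_rs11188059`) and
#' returns per-person star alleles, six-level phenotype, activity score and,
#' when the two extra SNPs are present, the ten-level CYP2C diplotype rank
#' and its three-level collapse.
#'
#' @param genotypes data.frame in the genotypes.csv schema.
#' @param rank_table CYP2C diplotype rank table (see [cyp2c_rank_table()]);
#'   used only when the rs2860840/rs11188059 columns are present.
#' @return data.frame: person_id, star1, star2, phenotype, activity_score,
#'   and (if available) cyp2c_rank, cyp2c_collapse3.
#' @export
classify_genotypes <- function(genotypes, rank_table = cyp2c_rank_table()) {
  g <- as.data.frame(genotypes)
  need <- c("person_id", "h1_rs4244285", "h1_rs12248560",
            "h2_rs4244285", "h2_rs12248560")
  if (!all(need %in% names(g))) {
    stop("genotype table lacks columns: ",
         paste(setdiff(need, names(g)), collapse = ", "))
  }
  s1 <- star_allele(g$h1_rs4244285, g$h1_rs12248560, who = g$person_id)
  s2 <- star_allele(g$h2_rs4244285, g$h2_rs12248560, who = g$person_id)
  out <- data.frame(person_id = g$person_id, star1 = s1, star2 = s2,
                    phenotype = metabolic_phenotype(s1, s2),
                    stringsAsFactors = FALSE)
  out$activity_score <- activity_score(out$phenotype)
  cyp2c_cols <- c("h1_rs2860840", "h1_rs11188059",
                  "h2_rs2860840", "h2_rs11188059")
  if (all(cyp2c_cols %in% names(g))) {
    l1 <- cyp2c_haplotype_label(s1, g$h1_rs2860840, g$h1_rs11188059,
                                who = g$person_id)
    l2 <- cyp2c_haplotype_label(s2, g$h2_rs2860840, g$h2_rs11188059,
                                who = g$person_id)
    d <- cyp2c_diplotype(l1, l2, rank_table = rank_table)
    out$cyp2c_rank <- d$rank
    out$cyp2c_collapse3 <- d$collapse3
  }
  out
}

#' Minor/alternate allele frequency from genotype counts
#'
#' @param hom_ref,het,hom_alt non-negative genotype counts.
#' @return frequency of the alternate allele, `(2*hom_alt + het) / (2*n)`.
#' @export
#' @examples
#' allele_frequency(3636, 1288, 95)  # 0.147...
allele_frequency <- function(hom_ref, het, hom_alt) {
  stopifnot(hom_ref >= 0, het >= 0, hom_alt >= 0)
  n <- hom_ref + het + hom_alt
  if (n <= 0) stop("zero genotyped individuals")
  (2 * hom_alt + het) / (2 * n)
}

#' Phenotype frequency table for a cohort
#'
#' @param phenotypes character vector of levels, or a data.frame with a
#'   `phenotype` column (e.g. from [classify_genotypes()]).
#' @return data.frame with phenotype, n, pct (percent, one decimal) over the
#'   six levels in PM..UM order; counts sum to the cohort size.
#' @export
phenotype_table <- function(phenotypes) {
  if (is.data.frame(phenotypes)) phenotypes <- phenotypes$phenotype
  stopifnot(all(phenotypes %in% .pheno_levels))
  n <- as.integer(table(factor(phenotypes, levels = .pheno_levels)))
  total <- length(phenotypes)
  data.frame(phenotype = .pheno_levels, n = n,
             pct = if (total > 0) round(100 * n / total, 1) else rep(0, 6))
}

#' Reconstruct a phased cohort from per-SNP genotype margins
#'
#' Given the per-SNP genotype counts for rs4244285 (A/A, G/A, G/G) and
#' rs12248560 (C/C, C/T, T/T) plus the number of double heterozygotes, the
#' no-recombinant constraint forces the full joint table: A/A individuals
#' must be C/C, T/T individuals must be G/G, and every G/A x C/T double
#' heterozygote must carry *2 and *17 on opposite chromosomes. This lets a
#' published marginal genotype table be expanded into an explicit phased
#' cohort whose classification can be recomputed.
#'
#' @param n_AA,n_GA,n_GG rs4244285 genotype counts.
#' @param n_CC,n_CT,n_TT rs12248560 genotype counts.
#' @param n_double_het count of individuals heterozygous at both SNPs.
#' @return genotype data.frame in the genotypes.csv schema (core SNPs only).
#' @export
cohort_from_genotype_margins <- function(n_AA, n_GA, n_GG,
                                         n_CC, n_CT, n_TT, n_double_het) {
  n <- n_AA + n_GA + n_GG
  if (n != n_CC + n_CT + n_TT) stop("SNP margins disagree on cohort size")
  if (n_double_het > min(n_GA, n_CT)) stop("double-het count exceeds margins")
  # joint genotype counts forced by the no-recombinant constraint
  joint <- c("AA.CC" = n_AA,
             "GA.CT" = n_double_het,
             "GA.CC" = n_GA - n_double_het,
             "GG.TT" = n_TT,
             "GG.CT" = n_CT - n_double_het,
             "GG.CC" = n_GG - n_TT - (n_CT - n_double_het))
  if (any(joint < 0)) stop("margins are inconsistent with a phased cohort")
  # phased haplotypes per joint class (h1/h2 alleles at the two SNPs)
  hap <- list(  #            h1_4244285 h1_12248560 h2_4244285 h2_12248560
    "AA.CC" = c("A", "C", "A", "C"),
    "GA.CT" = c("A", "C", "G", "T"),  # *2 and *17 on opposite chromosomes
    "GA.CC" = c("A", "C", "G", "C"),
    "GG.TT" = c("G", "T", "G", "T"),
    "GG.CT" = c("G", "T", "G", "C"),
    "GG.CC" = c("G", "C", "G", "C"))
  rows <- do.call(rbind, lapply(names(joint), function(k) {
    if (joint[[k]] == 0) return(NULL)
    m <- matrix(hap[[k]], nrow = joint[[k]], ncol = 4, byrow = TRUE)
    as.data.frame(m, stringsAsFactors = FALSE)
  }))
  names(rows) <- c("h1_rs4244285", "h1_rs12248560",
                   "h2_rs4244285", "h2_rs12248560")
  cbind(person_id = sprintf("P%05d", seq_len(nrow(rows))), rows)
}
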
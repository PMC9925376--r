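#' Expanded CYP2C diplotype scheme
#'
#' Beyond the two core CYP2C19 SNPs, rs2860840 (C>T) and rs11188059 (G>A)
#' define the ultra-rapid CYP2C:TG haplotype on a *1 background. Each
#' haplotype is labelled one of: `CYP2C19null` (carries *2),
#' `CYP2C19*17`, `CYP2C:TG` (rs2860840=T and rs11188059=G on *1), or the
#' reference-background `CYP2C:CG-or-TA`. The ten unordered haplotype pairs
#' are ranked 1 (CYP2C:TG/CYP2C19*17, fastest) to 10
#' (CYP2C19null/CYP2C19null, slowest), with CYP2C:CG-or-TA/CYP2C:CG-or-TA
#' as the reference diplotype. Only the two endpoints and the reference are
#' fixed by the scheme; the interior ordering ships as an editable table.
#'
#' @name cyp2c
NULL

#' Default CYP2C diplotype rank table
#'
#' Reads the packaged ten-row table mapping unordered haplotype-label pairs
#' to ranks 1..10 and to the three-level collapse (lower-exposure /
#' reference / higher-exposure). Users may pass a path to an edited copy to
#' change the interior ordering; the endpoints (rank 1 = CYP2C:TG/CYP2C19*17,
#' rank 10 = CYP2C19null/CYP2C19null) and the reference diplotype are
#' validated on load.
#'
#' @param path CSV with columns rank, hap1, hap2, collapse3.
#' @return data.frame with those four columns, ranks 1..10.
#' @export
cyp2c_rank_table <- function(path = system.file("extdata",
                                                "cyp2c_rank_table.csv",
                                                package = "pgxepi")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("rank", "hap1", "hap2", "collapse3") %in% names(tab)),
            setequal(tab$rank, 1:10))
  key1 <- .cyp2c_pair_key(tab$hap1[tab$rank == 1], tab$hap2[tab$rank == 1])
  key10 <- .cyp2c_pair_key(tab$hap1[tab$rank == 10], tab$hap2[tab$rank == 10])
  if (key1 != .cyp2c_pair_key("CYP2C:TG", "CYP2C19*17") ||
      key10 != .cyp2c_pair_key("CYP2C19null", "CYP2C19null")) {
    stop("rank table endpoints must be CYP2C:TG/CYP2C19*17 (1) and ",
         "CYP2C19null/CYP2C19null (10)")
  }
  ref <- tab$collapse3 == "reference"
  if (sum(ref) != 1 ||
      .cyp2c_pair_key(tab$hap1[ref], tab$hap2[ref]) !=
        .cyp2c_pair_key("CYP2C:CG-or-TA", "CYP2C:CG-or-TA")) {
    stop("reference diplotype must be CYP2C:CG-or-TA/CYP2C:CG-or-TA")
  }
  tab
}

.cyp2c_pair_key <- function(h1, h2) paste(pmin(h1, h2), pmax(h1, h2), sep = "|")

#' Label a haplotype under the expanded CYP2C scheme
#'
#' @param star star allele of the haplotype ("*1", "*2", "*17").
#' @param rs2860840 "C" or "T"; @param rs11188059 "G" or "A".
#' @param who optional identifiers for error messages.
#' @return character vector of haplotype labels.
#' @export
cyp2c_haplotype_label <- function(star, rs2860840, rs11188059, who = NULL) {
  stopifnot(length(star) == length(rs2860840),
            length(star) == length(rs11188059))
  out <- rep(NA_character_, length(star))
  out[star == "*2"] <- "CYP2C19null"
  out[star == "*17"] <- "CYP2C19*17"
  wt <- star == "*1"
  out[wt & rs2860840 == "T" & rs11188059 == "G"] <- "CYP2C:TG"
  out[wt & (paste0(rs2860840, rs11188059) %in% c("CG", "TA"))] <-
    "CYP2C:CG-or-TA"
  if (anyNA(out)) {
    bad <- is.na(out)
    lab <- if (is.null(who)) which(bad) else who[bad]
    stop("unlabelled CYP2C haplotype (alleles ",
         paste(unique(paste0(rs2860840[bad], rs11188059[bad])),
               collapse = ","),
         " on *1 background) for: ", paste(unique(lab), collapse = ", "))
  }
  out
}

#' Rank a CYP2C diplotype
#'
#' @param l1,l2 haplotype labels from [cyp2c_haplotype_label()].
#' @param rank_table see [cyp2c_rank_table()].
#' @return data.frame with rank (1..10) and collapse3.
#' @export
cyp2c_diplotype <- function(l1, l2, rank_table = cyp2c_rank_table()) {
  key <- .cyp2c_pair_key(l1, l2)
  tab_key <- .cyp2c_pair_key(rank_table$hap1, rank_table$hap2)
  idx <- match(key, tab_key)
  if (anyNA(idx)) {
    stop("diplotype not covered by rank table: ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  }
  data.frame(rank = rank_table$rank[idx],
             collapse3 = rank_table$collapse3[idx],
             stringsAsFactors = FALSE)
}
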
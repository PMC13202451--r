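#' @keywords internal
"_PACKAGE"

## APOE epsilon haplotypes are defined by the bases carried at two coding
## variants on chromosome 19 (GRCh38):
##   rs429358  chr19:44908684  REF=T  ALT=C
##   rs7412    chr19:44908822  REF=C  ALT=T
## The 2x2 base space maps onto the four epsilon haplotypes; e1 (C,T) is the
## rare fourth combination, not part of the common three-haplotype system.

APOE_ALLELES <- c("e1", "e2", "e3", "e4")

RS429358 <- list(id = "rs429358", chrom = "chr19", pos = 44908684L, ref = "T", alt = "C")
RS7412 <- list(id = "rs7412", chrom = "chr19", pos = 44908822L, ref = "C", alt = "T")

#' Map bases at the two APOE coding variants to an epsilon haplotype
#'
#' The common APOE haplotypes are defined by the phased bases at rs429358
#' and rs7412: (T,T) is \eqn{\epsilon 2}, (T,C) is \eqn{\epsilon 3},
#' (C,C) is \eqn{\epsilon 4}. The remaining combination (C,T) is the rare
#' \eqn{\epsilon 1} haplotype; it is called, but with a warning, because it
#' falls outside the three-haplotype system used by the association stages.
#'
#' @param rs429358 Character vector of bases at rs429358, each "T" or "C".
#' @param rs7412 Character vector of bases at rs7412, each "T" or "C".
#' @param warn_e1 Warn when an e1 haplotype is produced (default `TRUE`).
#' @return Character vector of haplotype labels among
#'   `c("e1", "e2", "e3", "e4")`.
#' @examples
#' allele_from_variants("T", "C") # e3
#' allele_from_variants(c("T", "C"), c("T", "C")) # e2, e4
#' @export
allele_from_variants <- function(rs429358, rs7412, warn_e1 = TRUE) {
  stopifnot(length(rs429358) == length(rs7412))
  bad <- !(rs429358 %in% c("T", "C")) | !(rs7412 %in% c("T", "C"))
  if (any(bad)) {
    stop("invalid base(s) at APOE sites: expected T or C, got ",
         paste(unique(c(rs429358[bad], rs7412[bad])), collapse = ", "))
  }
  out <- ifelse(rs429358 == "T",
                ifelse(rs7412 == "T", "e2", "e3"),
                ifelse(rs7412 == "C", "e4", "e1"))
  if (warn_e1 && any(out == "e1")) {
    warning(sum(out == "e1"), " haplotype(s) called as e1 (rs429358=C, rs7412=T); ",
            "e1 is outside the common three-haplotype system")
  }
  out
}

## Inverse map: haplotype label -> bases at (rs429358, rs7412)
allele_to_variants <- function(allele) {
  map <- list(e1 = c("C", "T"), e2 = c("T", "T"),
              e3 = c("T", "C"), e4 = c("C", "C"))
  bad <- !allele %in% names(map)
  if (any(bad)) stop("unknown APOE allele label: ", paste(unique(allele[bad]), collapse = ", "))
  do.call(rbind, map[allele])
}

#' Canonical diplotype label from two haplotype labels
#'
#' A diplotype is the unordered pair of epsilon haplotypes carried by one
#' person. Rendering is order-independent: the two alleles are sorted
#' e1 < e2 < e3 < e4 and joined with "/", so `diplotype("e4","e2")` and
#' `diplotype("e2","e4")` both give `"e2/e4"`.
#'
#' @param a,b Character vectors of haplotype labels.
#' @return Character vector of canonical diplotype labels, e.g. `"e3/e4"`.
#' @export
diplotype <- function(a, b) {
  stopifnot(length(a) == length(b))
  bad <- !(a %in% APOE_ALLELES) | !(b %in% APOE_ALLELES)
  if (any(bad)) stop("unknown APOE allele label(s): ",
                     paste(unique(c(a[bad], b[bad])), collapse = ", "))
  ifelse(a <= b, paste(a, b, sep = "/"), paste(b, a, sep = "/"))
}

#' All diplotypes of the common three-haplotype system
#' @return Character vector of the six e2/e3/e4 diplotype labels.
#' @export
apoe_diplotypes <- function() {
  c("e2/e2", "e2/e3", "e2/e4", "e3/e3", "e3/e4", "e4/e4")
}

#' Count copies of an allele in a diplotype label
#'
#' @param dip Character vector of diplotype labels (e.g. `"e3/e4"`).
#' @param allele Single allele label, default `"e4"` (the risk allele dose
#'   used by additive and dominant codings).
#' @return Integer vector of allele counts (0, 1 or 2).
#' @export
allele_dose <- function(dip, allele = "e4") {
  parts <- strsplit(dip, "/", fixed = TRUE)
  vapply(parts, function(p) sum(p == allele), integer(1))
}

#' Does a diplotype carry a given allele?
#' @inheritParams allele_dose
#' @return Logical vector.
#' @export
carries_allele <- function(dip, allele = "e4") {
  allele_dose(dip, allele) > 0L
}
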
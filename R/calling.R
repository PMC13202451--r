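## Diplotype calling from phased call sets.

#' Call epsilon diplotypes from phased call sets
#'
#' Applies the two-variant haplotype map per chromosome and returns the
#' canonical unordered diplotype per sample. A sample is usable only if
#' both sites are non-missing on both haplotypes; unusable samples are
#' excluded with a logged reason (attribute `exclusions`). Calling is
#' deterministic and total on valid phased input.
#'
#' Unphased genotypes are only ambiguous when heterozygous at both sites
#' (T/C and C/T could be e2+e4 or e1+e3). By default that is an error; the
#' `"assume-e2e4"` policy resolves it to e2/e4 with a warning, justified
#' when the e1 haplotype frequency is ~0 (the e1/e3 configuration would
#' require an e1 haplotype). Unphased genotypes homozygous at either site
#' have only one haplotype decomposition and are resolved silently.
#'
#' @param calls Data frame from [read_phased_genotypes()] (columns
#'   `sample_id`, `h1_rs429358`, `h1_rs7412`, `h2_rs429358`, `h2_rs7412`,
#'   `phased`, `missing`).
#' @param resolve_unphased `"error"` (default) or `"assume-e2e4"`.
#' @return Data frame with `sample_id` and `diplotype`; excluded samples
#'   are dropped and listed in `attr(, "exclusions")` (sample_id, reason).
#' @export
diplotype_from_calls <- function(calls, resolve_unphased = c("error", "assume-e2e4")) {
  resolve_unphased <- match.arg(resolve_unphased)
  needed <- c("sample_id", "h1_rs429358", "h1_rs7412", "h2_rs429358",
              "h2_rs7412", "phased", "missing")
  stopifnot(all(needed %in% names(calls)))

  excl <- data.frame(sample_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  keep <- !calls$missing
  if (any(!keep)) {
    excl <- rbind(excl, data.frame(sample_id = calls$sample_id[!keep],
                                   reason = "missing genotype",
                                   stringsAsFactors = FALSE))
    message(sum(!keep), " sample(s) excluded: missing genotype at an APOE site")
  }
  calls <- calls[keep, , drop = FALSE]

  ## ambiguity only arises for unphased double heterozygotes
  het1 <- calls$h1_rs429358 != calls$h2_rs429358
  het2 <- calls$h1_rs7412 != calls$h2_rs7412
  ambiguous <- !calls$phased & het1 & het2
  if (any(ambiguous)) {
    if (resolve_unphased == "error") {
      stop(sum(ambiguous), " unphased genotype(s) heterozygous at both APOE ",
           "sites: phase is required to distinguish e2/e4 from e1/e3 ",
           "(set resolve_unphased = \"assume-e2e4\" to resolve)")
    }
    warning(sum(ambiguous), " unphased double-heterozygote(s) resolved to ",
            "e2/e4 under the assume-e2e4 policy")
  }

  a1 <- allele_from_variants(calls$h1_rs429358, calls$h1_rs7412, warn_e1 = FALSE)
  a2 <- allele_from_variants(calls$h2_rs429358, calls$h2_rs7412, warn_e1 = FALSE)
  dip <- diplotype(a1, a2)
  dip[ambiguous] <- "e2/e4"
  n_e1 <- sum(grepl("e1", dip, fixed = TRUE))
  if (n_e1 > 0) {
    warning(n_e1, " sample(s) carry an e1 haplotype; e1 carriers are outside ",
            "the three-haplotype system and are excluded by the association ",
            "stages by default")
  }
  out <- data.frame(sample_id = calls$sample_id, diplotype = dip,
                    stringsAsFactors = FALSE)
  attr(out, "exclusions") <- excl
  out
}

#' Call diplotypes directly from a VCF file
#'
#' Convenience wrapper: [read_phased_genotypes()] then
#' [diplotype_from_calls()].
#'
#' @inheritParams read_phased_genotypes
#' @inheritParams diplotype_from_calls
#' @return As [diplotype_from_calls()].
#' @export
call_diplotypes <- function(path, resolve_unphased = c("error", "assume-e2e4")) {
  diplotype_from_calls(read_phased_genotypes(path),
                       resolve_unphased = match.arg(resolve_unphased))
}
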
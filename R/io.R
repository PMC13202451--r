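## Cohort file I/O.
##
## Genotypes travel as a two-record VCF v4.2 (rs429358, rs7412; GRCh38
## coordinates; phased "|" genotypes). Phenotypes travel as a TSV with one
## header row and empty fields for missing values. Numeric phenotype
## columns are written with "%.17g" so a write/read round trip is exact.

gt_code <- function(base, site) ifelse(base == site$ref, "0", "1")
gt_base <- function(code, site) {
  out <- rep(NA_character_, length(code))
  out[code == "0"] <- site$ref
  out[code == "1"] <- site$alt
  out
}

#' Write a cohort to disk (phased VCF + phenotype TSV)
#'
#' Genotypes are encoded against the canonical orientation
#' (chr19:44908684 REF=T ALT=C; chr19:44908822 REF=C ALT=T) with the
#' phased separator `|`; haplotype 1 is the first phased allele at both
#' sites. Phenotypes (all non-haplotype columns) go to a tab-separated
#' table, missing values as empty fields.
#'
#' @param cohort Cohort data frame from [simulate_cohort()] (or any frame
#'   with the haplotype base columns).
#' @param vcf_path,pheno_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_cohort <- function(cohort, vcf_path, pheno_path) {
  hap_cols <- c("h1_rs429358", "h1_rs7412", "h2_rs429358", "h2_rs7412")
  stopifnot(all(hap_cols %in% names(cohort)), "sample_id" %in% names(cohort))
  n <- nrow(cohort)
  gt1 <- paste(gt_code(cohort$h1_rs429358, RS429358),
               gt_code(cohort$h2_rs429358, RS429358), sep = "|")
  gt2 <- paste(gt_code(cohort$h1_rs7412, RS7412),
               gt_code(cohort$h2_rs7412, RS7412), sep = "|")
  if (n == 0) gt1 <- gt2 <- character(0)
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=chr19>",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", cohort$sample_id), collapse = "\t"))
  rec <- function(site, gts) {
    paste(c(site$chrom, site$pos, site$id, site$ref, site$alt, ".", "PASS",
            ".", "GT", gts), collapse = "\t")
  }
  writeLines(c(header, rec(RS429358, gt1), rec(RS7412, gt2)), vcf_path)

  pheno <- cohort[, setdiff(names(cohort), c(hap_cols, "h1", "h2", "diplotype")),
                  drop = FALSE]
  num <- vapply(pheno, is.numeric, logical(1))
  for (j in which(num)) {
    x <- sprintf("%.17g", pheno[[j]])
    x[is.na(pheno[[j]])] <- ""
    pheno[[j]] <- x
  }
  for (j in which(vapply(pheno, is.logical, logical(1)))) {
    pheno[[j]] <- ifelse(is.na(pheno[[j]]), "", ifelse(pheno[[j]], "1", "0"))
  }
  utils::write.table(pheno, pheno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(list(vcf = vcf_path, pheno = pheno_path))
}

#' Read a phenotype table written by [write_cohort()]
#'
#' @param path Tab-separated phenotype file with a header row; empty
#'   fields are missing.
#' @param logical_cols Columns to decode as logical (0/1); defaults to
#'   `"dementia_status"` plus any column whose values are all in {0,1,NA}
#'   named in `extra_logical`.
#' @param extra_logical Additional logical column names.
#' @return Data frame.
#' @export
read_phenotypes <- function(path, logical_cols = "dementia_status",
                            extra_logical = character(0)) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                          stringsAsFactors = FALSE)
  for (nm in intersect(c(logical_cols, extra_logical), names(df))) {
    df[[nm]] <- as.logical(df[[nm]])
  }
  df
}

#' Read phased genotypes at the two APOE sites from a VCF
#'
#' Sites are located by chromosome and position (identifier as fallback);
#' REF/ALT orientation is validated against the canonical alleles and any
#' mismatch is a fatal error -- there is no silent allele flip. A missing
#' site is a fatal error naming it.
#'
#' @param path VCF file (v4.2, plain text or bgzipped).
#' @param site1,site2 Site definitions; defaults are the canonical GRCh38
#'   rs429358 / rs7412 records.
#' @return A data frame of phased call sets: `sample_id`, per-haplotype
#'   bases at both sites (`h1_rs429358`, ...), `phased` (logical: phased at
#'   both sites) and `missing` (logical: any missing allele call).
#' @export
read_phased_genotypes <- function(path, site1 = RS429358, site2 = RS7412) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  locate <- function(site) {
    i <- which(fix[, "CHROM"] == site$chrom & as.integer(fix[, "POS"]) == site$pos)
    if (length(i) == 0) i <- which(fix[, "ID"] == site$id)
    if (length(i) == 0) {
      stop("site ", site$id, " (", site$chrom, ":", site$pos,
           ") absent from ", path)
    }
    i <- i[1]
    if (!identical(unname(fix[i, "REF"]), site$ref) ||
        !identical(unname(fix[i, "ALT"]), site$alt)) {
      stop("REF/ALT orientation mismatch at ", site$id, ": expected ",
           site$ref, ">", site$alt, ", found ", fix[i, "REF"], ">",
           fix[i, "ALT"], "; refusing to flip alleles silently")
    }
    i
  }
  i1 <- locate(site1)
  i2 <- locate(site2)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0 || ncol(gt) == 0) {
    return(data.frame(sample_id = character(0), h1_rs429358 = character(0),
                      h1_rs7412 = character(0), h2_rs429358 = character(0),
                      h2_rs7412 = character(0), phased = logical(0),
                      missing = logical(0), stringsAsFactors = FALSE))
  }
  parse_site <- function(g, site) {
    phased <- grepl("|", g, fixed = TRUE)
    parts <- strsplit(g, "[|/]")
    a1 <- vapply(parts, function(p) if (length(p) >= 1) p[1] else ".", character(1))
    a2 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else ".", character(1))
    miss <- is.na(g) | a1 == "." | a2 == "."
    list(h1 = gt_base(a1, site), h2 = gt_base(a2, site),
         phased = phased & !is.na(g), missing = miss)
  }
  s1 <- parse_site(gt[i1, ], site1)
  s2 <- parse_site(gt[i2, ], site2)
  data.frame(sample_id = colnames(gt),
             h1_rs429358 = s1$h1, h1_rs7412 = s2$h1,
             h2_rs429358 = s1$h2, h2_rs7412 = s2$h2,
             phased = s1$phased & s2$phased,
             missing = s1$missing | s2$missing,
             row.names = NULL, stringsAsFactors = FALSE)
}
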
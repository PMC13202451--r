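# Shared fixtures: the published demographic count table and small
# in-code cohort/VCF builders.

# Control / case genotype counts from the published demographic table;
# rare case cells are masked (<10) in print and carried here as NA, with
# the e4-dose rows supplying the masked information.
table1_controls <- c("e2/e2" = 145, "e2/e3" = 3707, "e2/e4" = 472,
                     "e3/e3" = 36738, "e3/e4" = 8831, "e4/e4" = 597)
table1_cases <- c("e2/e2" = NA, "e2/e3" = 39, "e2/e4" = NA,
                  "e3/e3" = 412, "e3/e4" = 133, "e4/e4" = 20)
table1_case_dose <- c("0" = 452, "1" = 142, "2" = 20)

table1 <- function() {
  genotype_count_table(control_counts = table1_controls,
                       case_counts = table1_cases,
                       case_dose = table1_case_dose)
}

# Null-effect simulation config (all true hazard ratios 1).
null_log_hr <- stats::setNames(rep(0, 6), apoe_diplotypes())

# Per-e4-allele multiplicative hazard config (dose coding truth).
additive_log_hr <- function(hr_per_allele) {
  stats::setNames(log(hr_per_allele) * allele_dose(apoe_diplotypes(), "e4"),
                  apoe_diplotypes())
}

# Small high-event-rate cohort for fast model tests.
quick_cohort <- function(n = 10000, seed = 1, baseline_hazard = 2e-3,
                         true_log_hr = NULL, ...) {
  args <- list(n_samples = n, baseline_hazard = baseline_hazard, seed = seed, ...)
  if (!is.null(true_log_hr)) args$true_log_hr <- true_log_hr
  simulate_cohort(do.call(sim_config, args))
}

# Hand-built VCF text for calling tests; gts1/gts2 are genotype strings
# for the rs429358 / rs7412 records.
write_test_vcf <- function(gts1, gts2, samples = paste0("S", seq_along(gts1)),
                           ref1 = "T", alt1 = "C", ref2 = "C", alt2 = "T",
                           drop_site2 = FALSE) {
  path <- tempfile(fileext = ".vcf")
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chr19>",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             paste(c("chr19", "44908684", "rs429358", ref1, alt1, ".", "PASS",
                     ".", "GT", gts1), collapse = "\t"))
  if (!drop_site2) {
    lines <- c(lines, paste(c("chr19", "44908822", "rs7412", ref2, alt2, ".",
                              "PASS", ".", "GT", gts2), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}
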
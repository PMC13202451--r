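## Config-driven orchestration: simulate -> call -> describe -> associate
## -> PAF -> PheWAS -> report. One root seed; stage randomness lives in
## the generator's deterministic sub-streams, so identical config + seed
## gives identical outputs.

#' Pipeline configuration
#'
#' Exactly one of `sim` (a [sim_config()]) or `inputs` (a list with
#' `vcf` and `pheno` paths) must be supplied.
#'
#' @param sim Simulation config, or `NULL` when reading files.
#' @param inputs List with `vcf` and `pheno` paths, or `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of enabled stages, in fixed order, from
#'   `c("describe", "associate", "paf", "phewas")` (simulation or loading
#'   always runs).
#' @param survival A [survival_config()] for the association stage.
#' @param paf_formula PAF formula variant (see [stratum_paf()]).
#' @param phewas_traits Trait manifest for the screen, or `NULL` to use
#'   every simulated trait column.
#' @param reference_carrier_proportion External carrier proportion for the
#'   enrichment test (plain numeric parameter).
#' @param seed Root seed; overrides `sim$seed` when `sim` is given.
#' @return A list of class `apoe_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), inputs = NULL,
                            out_dir = tempfile("apoedem_run_"),
                            stages = c("describe", "associate", "paf", "phewas"),
                            survival = survival_config(),
                            paf_formula = "case-load",
                            phewas_traits = NULL,
                            reference_carrier_proportion = 0.288,
                            seed = NULL) {
  if (is.null(sim) == is.null(inputs)) {
    stop("supply exactly one of `sim` (simulation config) or `inputs` (file paths)")
  }
  if (!is.null(sim) && !is.null(seed)) sim$seed <- as.integer(seed)
  cfg <- list(sim = sim, inputs = inputs, out_dir = out_dir,
              stages = stages, survival = survival, paf_formula = paf_formula,
              phewas_traits = phewas_traits,
              reference_carrier_proportion = reference_carrier_proportion)
  class(cfg) <- "apoe_pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] / [sim_config()] field for field
#' (simulation parameters under a `sim:` block).
#'
#' @param path YAML file.
#' @return An `apoe_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    args <- y$sim
    for (nm in c("hap_freqs", "ancestry_props", "true_log_hr",
                 "binary_trait_prevalences", "binary_trait_log_or",
                 "recruitment_age")) {
      if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
    }
    if (!is.null(args$trait_effects)) {
      args$trait_effects <- lapply(args$trait_effects, unlist)
    }
    sim <- do.call(sim_config, args)
  }
  surv <- if (is.null(y$survival)) survival_config() else
    do.call(survival_config, y$survival)
  pipeline_config(sim = sim, inputs = y$inputs,
                  out_dir = if (is.null(y$out_dir)) tempfile("apoedem_run_") else y$out_dir,
                  stages = if (is.null(y$stages)) c("describe", "associate", "paf", "phewas") else y$stages,
                  survival = surv,
                  paf_formula = if (is.null(y$paf_formula)) "case-load" else y$paf_formula,
                  reference_carrier_proportion =
                    if (is.null(y$reference_carrier_proportion)) 0.288 else y$reference_carrier_proportion,
                  seed = y$seed)
}

default_trait_manifest <- function(cohort, sim) {
  quant <- names(sim$trait_effects)
  bin <- names(sim$binary_trait_prevalences)
  data.frame(name = c(quant, bin),
             kind = c(rep("quantitative", length(quant)), rep("binary", length(bin))),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order and writes every artifact to the
#' output directory together with a manifest (stage list, seed, package
#' version, parameter fingerprint). Identical config and seed give
#' identical outputs. A stage failure halts with a stage-named error;
#' artifacts already written are retained.
#'
#' @param config An [pipeline_config()] object.
#' @return Invisibly, the report bundle (a list with the cohort, the
#'   per-stage results and the output paths).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "apoe_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = config, paths = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (!is.null(config$sim)) {
    bundle$cohort <- stage("simulate", simulate_cohort(config$sim))
    paths <- stage("simulate", write_cohort(
      bundle$cohort,
      file.path(config$out_dir, "genotypes.vcf"),
      file.path(config$out_dir, "phenotypes.tsv")))
    bundle$paths <- c(bundle$paths, paths)
    vcf <- paths$vcf
  } else {
    vcf <- config$inputs$vcf
    bundle$cohort <- stage("load", read_phenotypes(config$inputs$pheno))
  }

  calls <- stage("call-apoe", call_diplotypes(vcf))
  bundle$diplotypes <- calls
  coh <- merge(bundle$cohort[, setdiff(names(bundle$cohort), "diplotype")],
               calls, by = "sample_id", sort = TRUE)
  bundle$cohort <- coh
  dip_path <- file.path(config$out_dir, "diplotypes.tsv")
  utils::write.table(calls, dip_path, sep = "\t", quote = FALSE, row.names = FALSE)
  bundle$paths$diplotypes <- dip_path

  if ("describe" %in% config$stages) {
    bundle$descriptives <- stage("describe", {
      tab <- summarize_genotypes(coh$diplotype, coh$dementia_status)
      e4 <- carrier_stats(tab, "e4", "overall")
      enr <- carrier_enrichment_test(e4$carriers, e4$n,
                                     config$reference_carrier_proportion)
      write_genotype_report(tab, file.path(config$out_dir, "genotype_counts.tsv"),
                            file.path(config$out_dir, "genotype_counts.json"))
      list(table = tab, e4_carriers = e4, enrichment_p = enr)
    })
    bundle$paths$genotype_counts <- file.path(config$out_dir, "genotype_counts.tsv")
  }

  if ("associate" %in% config$stages) {
    bundle$association <- stage("associate", {
      res <- rbind(fit_cox(coh, config$survival),
                   fit_cox(coh, modifyList_cfg(config$survival, coding = "additive")),
                   fit_cox(coh, modifyList_cfg(config$survival, coding = "dominant")),
                   fit_logistic(coh, config$survival))
      utils::write.table(res, file.path(config$out_dir, "association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(res, file.path(config$out_dir, "association.json"),
                           dataframe = "rows", digits = NA, auto_unbox = TRUE)
      km <- km_by_dose(coh, config$survival)
      utils::write.table(km, file.path(config$out_dir, "km_by_dose.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(results = res, km = km)
    })
    bundle$paths$association <- file.path(config$out_dir, "association.tsv")
  }

  if ("paf" %in% config$stages) {
    bundle$paf <- stage("paf", {
      lcfg <- modifyList_cfg(config$survival, reference = "e2/e2")
      fits <- fit_logistic(coh, lcfg)
      cases <- coh[coh$dementia_status & !grepl("e1", coh$diplotype, fixed = TRUE), ]
      counts <- table(factor(cases$diplotype, levels = apoe_diplotypes()))
      paf <- paf_from_fits(fits, stats::setNames(as.numeric(counts), names(counts)),
                           formula = config$paf_formula)
      write_paf_report(paf, file.path(config$out_dir, "paf.tsv"),
                       file.path(config$out_dir, "paf.json"))
      paf
    })
    bundle$paths$paf <- file.path(config$out_dir, "paf.tsv")
  }

  if ("phewas" %in% config$stages) {
    bundle$phewas <- stage("phewas", {
      manifest <- config$phewas_traits
      if (is.null(manifest)) {
        if (is.null(config$sim)) stop("no trait manifest supplied")
        manifest <- default_trait_manifest(coh, config$sim)
      }
      res <- run_phewas(coh, manifest)
      write_phewas_report(res, file.path(config$out_dir, "phewas.tsv"),
                          file.path(config$out_dir, "phewas.json"),
                          file.path(config$out_dir, "phewas_plot.tsv"))
      res
    })
    bundle$paths$phewas <- file.path(config$out_dir, "phewas.tsv")
  }

  bundle$manifest <- write_manifest(config, bundle)
  write_report(bundle, config$out_dir)
  invisible(bundle)
}

## survival_config copies with a field changed (keeps the S3 class)
modifyList_cfg <- function(cfg, ...) {
  out <- utils::modifyList(unclass(cfg), list(...))
  class(out) <- class(cfg)
  out
}

write_manifest <- function(config, bundle) {
  fingerprint <- {
    tmp <- tempfile()
    saveRDS(config[c("sim", "survival", "paf_formula", "stages")], tmp, version = 2)
    on.exit(unlink(tmp))
    unname(tools::md5sum(tmp))
  }
  manifest <- list(
    package = "apoedem",
    version = as.character(utils::packageVersion("apoedem")),
    seed = if (!is.null(config$sim)) config$sim$seed else NA,
    stages = config$stages,
    paf_formula = config$paf_formula,
    parameter_fingerprint = fingerprint,
    n_samples = nrow(bundle$cohort),
    n_events = sum(bundle$cohort$dementia_status, na.rm = TRUE))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Write the human-readable report for a pipeline bundle
#'
#' Markdown summary (percentages at one decimal) plus a machine-readable
#' JSON twin at full precision.
#'
#' @param bundle Bundle from [run_pipeline()].
#' @param path Output directory.
#' @return Invisibly, the markdown lines.
#' @export
write_report <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  lines <- c("# APOE-dementia pipeline report", "")
  json <- list()
  n <- nrow(bundle$cohort)
  nev <- sum(bundle$cohort$dementia_status, na.rm = TRUE)
  lines <- c(lines, sprintf("Samples: %d; dementia cases: %d (%s%%)", n, nev,
                            pct1(nev / n)), "")
  json$n_samples <- n
  json$n_events <- nev
  if (!is.null(bundle$descriptives)) {
    e4 <- bundle$descriptives$e4_carriers
    lines <- c(lines, "## Genotypes",
               sprintf("- e4 carriers: %d (%s%%); heterozygous %s%%, homozygous %s%%",
                       e4$carriers, pct1(e4$prop_carrier), pct1(e4$prop_het),
                       pct1(e4$prop_hom)),
               sprintf("- carrier-enrichment binomial p vs reference: %.3g",
                       bundle$descriptives$enrichment_p), "")
    json$e4_carriers <- e4
    json$enrichment_p <- bundle$descriptives$enrichment_p
  }
  if (!is.null(bundle$association)) {
    res <- bundle$association$results
    lines <- c(lines, "## Association", "",
               "| model | term | HR/OR | 95% CI | p |",
               "|---|---|---|---|---|",
               sprintf("| %s | %s | %.2f | %.2f-%.2f | %.2g |",
                       res$model, res$term, res$hr, res$hr_lo, res$hr_hi, res$p),
               "")
    json$association <- res
  }
  if (!is.null(bundle$paf)) {
    p <- bundle$paf
    lines <- c(lines, "## Population attributable fractions",
               sprintf("- formula variant: %s", p$formula),
               sprintf("- PAF e4: %s%% (%s%%, %s%%)", pct1(p$e4$paf),
                       pct1(p$e4$lower), pct1(p$e4$upper)),
               sprintf("- PAF e3: %s%% (%s%%, %s%%)", pct1(p$e3$paf),
                       pct1(p$e3$lower), pct1(p$e3$upper)),
               sprintf("- PAF joint (e3 or e4): %s%% (%s%%, %s%%)",
                       pct1(p$joint$paf), pct1(p$joint$lower), pct1(p$joint$upper)),
               "")
    json$paf <- unclass(p)[c("strata", "joint", "e4", "e3", "weight", "formula")]
  }
  if (!is.null(bundle$phewas) && nrow(bundle$phewas) > 0) {
    ph <- bundle$phewas
    nsig <- sum(ph$passes_bonferroni, na.rm = TRUE)
    lines <- c(lines, "## PheWAS",
               sprintf("- %d eligible trait test(s); Bonferroni threshold %.3g",
                       attr(ph, "m"), attr(ph, "bonferroni_threshold")),
               sprintf("- %d genotype-trait association(s) pass Bonferroni", nsig), "")
    json$phewas_m <- attr(ph, "m")
    json$phewas_n_bonferroni <- nsig
  }
  writeLines(lines, file.path(path, "report.md"))
  jsonlite::write_json(json, file.path(path, "report.json"), dataframe = "rows",
                       digits = NA, auto_unbox = TRUE, na = "null", force = TRUE)
  invisible(lines)
}
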
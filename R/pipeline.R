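#' @include io-vcf.R io-annotation.R site-filters.R annotation.R diversity.R ld.R simulate.R toy-genome.R
NULL

.defaultConfig <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    filters = list(max_missing = 0.10, max_het = 0.10, min_maf = 0.02),
    diversity = list(window = 100000L, step = 10000L, mode = "sliding"),
    ld = list(max_dist = 1000000L, bin_width = 1000L, min_subpop = 20L))
}

.mergeConfig <- function(user) {
  cfg <- .defaultConfig()
  for (k in names(user)) {
    if (k %in% names(cfg) && is.list(cfg[[k]]) && is.list(user[[k]])) {
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg
}

#' Read and validate a pipeline run configuration
#'
#' A run is driven either by input file paths (`inputs:` with `vcf` and
#' optionally `gff3`, `fasta`, `meta`) or by a simulation block
#' (`simulation:` with `type: subpops` or `type: toy`), never both.
#' Unset keys fall back to defaults (filters 0.10/0.10/0.02; diversity
#' window 100 kb step 10 kb sliding; LD max distance 1 Mb, bin 1 kb,
#' minimum 20 samples per sub-population).
#'
#' @param config path to a YAML file, or an equivalent nested list.
#' @return validated configuration list.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) config <- read_yaml(config)
  cfg <- .mergeConfig(config)
  has_inputs <- !is.null(cfg$inputs)
  has_sim <- !is.null(cfg$simulation)
  if (has_inputs == has_sim) {
    stop("config must contain exactly one of 'inputs' and 'simulation'")
  }
  thr <- unlist(cfg$filters)
  if (any(thr < 0) || any(thr > 1)) stop("filter thresholds must lie in [0, 1]")
  if (is.null(cfg$outdir)) stop("config needs an 'outdir'")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.simulateInputs <- function(cfg, outdir) {
  sim <- cfg$simulation
  seed <- cfg$seed
  if (identical(sim$type, "toy")) {
    toy <- makeToyGenome(seed = seed,
                         n_samples = sim$n_samples %||% 3L,
                         out_dir = outdir)
    return(list(vcf = toy$paths$vcf, gff3 = toy$paths$gff3,
                fasta = toy$paths$fasta, meta = NULL,
                truth = toy$paths$truth))
  }
  if (identical(sim$type, "subpops")) {
    subpops <- lapply(sim$subpops, function(sp) {
      sp$n_samples <- as.integer(sp$n_samples)
      sp
    })
    res <- simulateSubpops(
      subpops = subpops,
      n_sites = as.integer(sim$n_sites %||% 2000L),
      missing_rate = sim$missing_rate %||% 0,
      f = sim$f %||% 0.95,
      seed = seed)
    vcf <- file.path(outdir, "input.vcf")
    meta <- file.path(outdir, "meta.tsv")
    truth <- file.path(outdir, "truth.json")
    writeVcfGenotypes(res$gm, vcf)
    writeSampleMeta(res$meta, meta)
    write_json(res$truth, truth, digits = NA)
    return(list(vcf = vcf, gff3 = NULL, fasta = NULL, meta = meta,
                truth = truth))
  }
  stop("unknown simulation type: ", sim$type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) - filter - annotate (when gene
#' annotation is available) - diversity - LD - report, writing each
#' stage's output under `outdir` before the next begins:
#' `filtered.vcf` (core SNP set), `annotation.tsv`, `windows.tsv`,
#' `ld_curve.tsv`, `report.tsv` and `report.txt` (plus `input.vcf`,
#' `meta.tsv`, `truth.json` for simulation-backed runs).  Re-running
#' with an identical configuration reproduces byte-identical reports.
#'
#' @param config a YAML path or list, see [readRunConfig()].
#' @return the run report, an S3 list of class `popdivRunReport`, with
#'   components `counts`, `chrom_counts`, `tstv`, `regions`,
#'   `syn_nonsyn`, `effect_counts`, `mutated_in_all`, `population`,
#'   `subpops`, `ld`, `provenance`.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list()

  ## stage: acquire inputs
  inputs <- if (!is.null(cfg$simulation)) {
    .simulateInputs(cfg, outdir)
  } else cfg$inputs
  gm <- readVcfGenotypes(inputs$vcf)
  message("loaded ", nSites(gm), " sites x ", ncol(gm), " samples")

  ## stage: filters
  snps_simple <- simpleFilter(gm)
  indels <- variantClassSubset(gm, "InDel")
  core <- coreFilter(snps_simple,
                     max_missing = cfg$filters$max_missing,
                     max_het = cfg$filters$max_het,
                     min_maf = cfg$filters$min_maf)
  writeVcfGenotypes(core, file.path(outdir, "filtered.vcf"))
  message("simple filter: ", nSites(snps_simple), " SNPs; core filter: ",
          nSites(core), " SNPs; InDels: ", nSites(indels))
  report$counts <- list(
    n_input = nSites(gm), n_snps_simple = nSites(snps_simple),
    n_indels = nSites(indels), n_core = nSites(core))
  report$chrom_counts <- chromCounts(core)
  report$mutated_in_all <- length(mutatedInAll(snps_simple))

  ## stage: annotation
  if (!is.null(inputs$gff3) && !is.null(inputs$fasta)) {
    genes <- readGeneModels(inputs$gff3)
    genome <- readGenome(inputs$fasta)
    ann_gm <- gm[.simpleKeep(gm) | variantClass(gm) == "InDel", ]
    ann <- annotateVariants(ann_gm, genes, genome)
    write.table(ann, file.path(outdir, "annotation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$regions <- regionSummary(ann$region)
    report$syn_nonsyn <- synNonsynRatio(ann$so_term)
    eff <- table(ann$so_term[!is.na(ann$so_term)])
    report$effect_counts <- setNames(as.integer(eff), names(eff))
  }
  if (nSites(snps_simple) > 0L) {
    report$tstv <- tstvRatio(snps_simple)
  }

  ## stage: diversity
  win <- windowedPi(core, window = cfg$diversity$window,
                    step = cfg$diversity$step, mode = cfg$diversity$mode)
  write.table(win, file.path(outdir, "windows.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$population <- if (nSites(core) > 0L && nrow(win) > 0L) {
    list(pi = populationPi(win), pic = populationPic(core))
  } else {
    list(pi = NA_real_, pic = NA_real_)
  }
  meta <- NULL
  if (!is.null(inputs$meta)) {
    meta <- readSampleMeta(inputs$meta)
    report$subpops <- subpopDiversity(
      core, meta, window = cfg$diversity$window,
      step = cfg$diversity$step, mode = cfg$diversity$mode)
  }

  ## stage: LD
  curve <- ldCurve(core, max_dist = cfg$ld$max_dist,
                   bin_width = cfg$ld$bin_width)
  write.table(ldBins(curve), file.path(outdir, "ld_curve.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report$ld <- list(all = list(max_r2 = maxR2(curve),
                               half_decay = halfDecayDistance(curve)))
  if (!is.null(meta)) {
    for (sp in sort(unique(meta$subpop[!is.na(meta$subpop)]))) {
      ids <- intersect(meta$sample[meta$subpop %in% sp], sampleNames(core))
      if (length(ids) < cfg$ld$min_subpop) {
        warning("sub-population ", sp, " below LD minimum sample count (",
                cfg$ld$min_subpop, "); skipped")
        next
      }
      sub_curve <- ldCurve(core[, ids], max_dist = cfg$ld$max_dist,
                           bin_width = cfg$ld$bin_width)
      report$ld[[sp]] <- list(max_r2 = maxR2(sub_curve),
                              half_decay = halfDecayDistance(sub_curve))
    }
  }

  ## stage: report
  cfg_file <- file.path(outdir, "config_used.yaml")
  writeLines(yaml::as.yaml(cfg[setdiff(names(cfg), "outdir")]), cfg_file)
  report$provenance <- list(
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("popdiv")))
  class(report) <- "popdivRunReport"
  renderReport(report, outdir)
  report
}

.flattenReport <- function(report) {
  rows <- list()
  put <- function(key, value) {
    val <- if (is.numeric(value)) sprintf("%.17g", value) else as.character(value)
    rows[[length(rows) + 1L]] <<- data.frame(key = key, value = val,
                                             stringsAsFactors = FALSE)
  }
  cn <- report$counts
  for (k in names(cn)) put(paste0("counts.", k), cn[[k]])
  if (!is.null(report$chrom_counts)) {
    for (i in seq_len(nrow(report$chrom_counts))) {
      put(paste0("core_snps.", report$chrom_counts$chrom[i]),
          report$chrom_counts$n_sites[i])
    }
  }
  put("mutated_in_all", report$mutated_in_all)
  if (!is.null(report$tstv)) put("tstv_ratio", report$tstv$ratio)
  if (!is.null(report$regions)) {
    for (i in seq_len(nrow(report$regions))) {
      put(paste0("region_pct.", report$regions$region[i]),
          report$regions$pct[i])
    }
  }
  if (!is.null(report$syn_nonsyn)) {
    put("syn_nonsyn_ratio", report$syn_nonsyn$ratio)
  }
  if (!is.null(report$effect_counts)) {
    for (k in names(report$effect_counts)) {
      put(paste0("effect_count.", k), report$effect_counts[[k]])
    }
  }
  put("population.pi", report$population$pi)
  put("population.pic", report$population$pic)
  if (!is.null(report$subpops)) {
    for (i in seq_len(nrow(report$subpops))) {
      sp <- report$subpops$subpop[i]
      put(paste0("subpop.", sp, ".accessions"), report$subpops$accessions[i])
      put(paste0("subpop.", sp, ".pi"), report$subpops$pi[i])
      put(paste0("subpop.", sp, ".pic"), report$subpops$pic[i])
      if (nzchar(report$subpops$note[i])) {
        put(paste0("subpop.", sp, ".note"), report$subpops$note[i])
      }
    }
  }
  for (k in names(report$ld)) {
    put(paste0("ld.", k, ".half_decay_bp"), report$ld[[k]]$half_decay)
  }
  put("provenance.seed", report$provenance$seed)
  put("provenance.config_md5", report$provenance$config_md5)
  put("provenance.package_version", report$provenance$package_version)
  do.call(rbind, rows)
}

#' Render a run report to TSV and a human-readable summary
#'
#' `report.tsv` holds flattened key/value pairs with raw full-precision
#' values (numbers re-parse exactly); `report.txt` is a readable summary
#' in which nucleotide diversity is displayed in units of 1e-3, the
#' convention of diversity tables.
#'
#' @param report a `popdivRunReport` from [runPipeline()].
#' @param outdir output directory.
#' @return the flattened data.frame, invisibly.
#' @export
renderReport <- function(report, outdir) {
  flat <- .flattenReport(report)
  write.table(flat, file.path(outdir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  txt <- c("popdiv run report",
           "=================",
           sprintf("seed: %d", report$provenance$seed),
           "",
           sprintf("sites: %d input, %d simple-filtered SNPs, %d core SNPs, %d InDels",
                   report$counts$n_input, report$counts$n_snps_simple,
                   report$counts$n_core, report$counts$n_indels),
           sprintf("sites mutated in all samples: %d", report$mutated_in_all))
  if (!is.null(report$tstv)) {
    txt <- c(txt, sprintf("ts/tv ratio: %s",
                          format(report$tstv$ratio, digits = 4)))
  }
  if (!is.null(report$syn_nonsyn)) {
    txt <- c(txt, sprintf("syn/nonsyn ratio: %s",
                          format(report$syn_nonsyn$ratio, digits = 4)))
  }
  txt <- c(txt, "",
           sprintf("population pi: %s x 10^-3, PIC: %s",
                   format(report$population$pi * 1e3, digits = 4),
                   format(report$population$pic, digits = 4)))
  if (!is.null(report$subpops)) {
    txt <- c(txt, "", "sub-population diversity (pi displayed x 10^-3):")
    sp <- report$subpops
    for (i in seq_len(nrow(sp))) {
      txt <- c(txt, if (nzchar(sp$note[i])) {
        sprintf("  %s  n=%d  %s", sp$subpop[i], sp$accessions[i], sp$note[i])
      } else {
        sprintf("  %s  n=%d  pi=%.3f  PIC=%.3f", sp$subpop[i],
                sp$accessions[i], sp$pi_display[i], sp$pic[i])
      })
    }
  }
  txt <- c(txt, "")
  for (k in names(report$ld)) {
    hd <- report$ld[[k]]$half_decay
    txt <- c(txt, sprintf("LD half-decay (%s): %s", k,
                          if (is.na(hd)) "undefined" else
                            sprintf("%.1f kb", hd / 1000)))
  }
  writeLines(txt, file.path(outdir, "report.txt"))
  invisible(flat)
}

#' @export
print.popdivRunReport <- function(x, ...) {
  cat("popdiv run report (seed ", x$provenance$seed, ")\n", sep = "")
  cat("  sites: ", x$counts$n_input, " input, ", x$counts$n_core,
      " core SNPs\n", sep = "")
  cat("  population pi: ", format(x$population$pi, digits = 4),
      ", PIC: ", format(x$population$pic, digits = 4), "\n", sep = "")
  invisible(x)
}
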
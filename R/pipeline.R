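default_thresholds <- function() {
  list(fc = 2, raw_p = 0.05, bh = 0.05, max_gap = 250,
       min_coverage = 10, min_frequency = 0.60, pathlength_factor = 1)
}

#' Build a pipeline configuration
#'
#' Collects input paths, analysis thresholds and output settings for
#' [run_pipeline()]. Thresholds default to the study values: candidate genes
#' need `|fc| >= 2` and raw p `< 0.05`; the affected set uses BH `< 0.05`
#' with the TC rescue rule; TCs chain genes separated by less than 250 bp on
#' the same strand; variant calls need coverage `>= 10` and alternate-allele
#' frequency `> 0.60`.
#'
#' @param counts,conditions,annotation input paths (required unless
#'   `simulate` is given).
#' @param regions,categories,growth,variants_mutant,variants_wildtype
#'   optional input paths; the matching stages are skipped when `NULL`.
#' @param control_condition unpigmented reference condition for delta PMP.
#' @param thresholds named list overriding entries of the default thresholds.
#' @param simulate optional [sim_config()]; when given, inputs are generated
#'   into `outdir/simulated/` and used for all stages.
#' @param outdir output directory.
#' @param force overwrite an existing non-empty `outdir`.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(counts = NULL, conditions = NULL, annotation = NULL,
                            regions = NULL, categories = NULL, growth = NULL,
                            variants_mutant = NULL, variants_wildtype = NULL,
                            control_condition = "O1",
                            thresholds = list(), simulate = NULL,
                            outdir = "redoxreg_out", force = FALSE) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  stopifnot(th$fc > 0, th$raw_p > 0, th$bh > 0, th$max_gap > 0,
            th$min_coverage >= 0, th$min_frequency >= 0)
  cfg <- list(counts = counts, conditions = conditions, annotation = annotation,
              regions = regions, categories = categories, growth = growth,
              variants_mutant = variants_mutant,
              variants_wildtype = variants_wildtype,
              control_condition = control_condition,
              thresholds = th, simulate = simulate,
              outdir = outdir, force = isTRUE(force))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat keys matching the arguments of [pipeline_config()]; threshold keys
#' (`fc`, `raw_p`, `bh`, `max_gap`, `min_coverage`, `min_frequency`,
#' `pathlength_factor`) may appear at the top level. A nested `simulate:`
#' mapping holds [sim_config()] arguments and replaces the file inputs.
#'
#' @param path YAML file.
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  th_keys <- names(default_thresholds())
  th <- y[intersect(names(y), th_keys)]
  args <- y[setdiff(names(y), th_keys)]
  args$thresholds <- th
  # a nested `simulate:` mapping holds sim_config() arguments
  if (is.list(args$simulate)) args$simulate <- do.call(sim_config, args$simulate)
  do.call(pipeline_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

require_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(what, " file not found: ", if (is.null(path)) "<missing>" else path)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: optional simulation, differential expression,
#' candidate selection + transcriptional-cluster calling + rescue, region
#' and category profiling (when configured), growth/pigmentation endpoints
#' (when configured), and the variant screen (when configured). Each stage
#' writes its tables under `config$outdir` and a JSON manifest
#' (`manifest.json`) records parameters, input md5 hashes and the summary
#' counts. A failing stage aborts with an error naming the stage.
#'
#' @param config a [pipeline_config()] or the path of a YAML file for
#'   [read_pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  say <- function(...) if (!quiet) message("[redoxreg] ", ...)

  if (dir.exists(config$outdir) &&
      length(list.files(config$outdir)) > 0 && !config$force)
    stop("output directory ", config$outdir,
         " is not empty (use force = TRUE to overwrite)")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    say("stage simulate")
    simdir <- file.path(config$outdir, "simulated")
    stage("simulate", simulate_dataset(config$simulate, simdir))
    config$counts <- file.path(simdir, "counts.tsv")
    config$conditions <- file.path(simdir, "conditions.csv")
    config$annotation <- file.path(simdir, "annotation.gff3")
    config$growth <- config$growth %||% file.path(simdir, "growth.csv")
    config$variants_mutant <- config$variants_mutant %||%
      file.path(simdir, "variants_mutant.tsv")
    config$variants_wildtype <- config$variants_wildtype %||%
      file.path(simdir, "variants_wildtype.tsv")
  }

  inputs <- Filter(Negate(is.null), config[c(
    "counts", "conditions", "annotation", "regions", "categories",
    "growth", "variants_mutant", "variants_wildtype")])

  say("stage de")
  de <- stage("de", {
    counts <- read_counts(require_file(config$counts, "counts"),
                          require_file(config$conditions, "conditions"))
    run_de(counts)
  })
  write_de(de, file.path(config$outdir, "de_results.tsv"))

  say("stage tc")
  tc_res <- stage("tc", {
    ann <- read_annotation(require_file(config$annotation, "annotation"))
    candidates <- select_candidates(de, th$fc, th$raw_p)
    tcs <- call_tcs(candidates, ann, th$max_gap)
    affected <- apply_rescue(de, candidates, tcs, th$bh)
    list(annotation = ann, candidates = candidates, tcs = tcs,
         affected = affected, summary = summarize_affected(affected, tcs))
  })
  utils::write.table(tc_res$tcs$tcs, file.path(config$outdir, "tcs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tc_res$affected$genes,
                     file.path(config$outdir, "affected_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  region_profiles <- NULL
  if (!is.null(config$regions)) {
    say("stage regions")
    region_profiles <- stage("regions", {
      regions <- read_regions(require_file(config$regions, "regions"))
      lapply(seq_len(nrow(regions)), function(i)
        profile_region(regions[i, ], de, tc_res$affected, tc_res$tcs,
                       tc_res$annotation))
    })
    region_tab <- do.call(rbind, lapply(region_profiles, function(p)
      data.frame(name = p$name, n_genes = p$n_genes, n_affected = p$n_affected,
                 avg_fc = p$avg_fc, max_fc_gene = p$max_fc_gene,
                 max_fc = p$max_fc, n_tcs_inside = p$n_tcs_inside,
                 n_isolated_affected = p$n_isolated_affected,
                 stringsAsFactors = FALSE)))
    utils::write.table(region_tab, file.path(config$outdir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  categories <- NULL
  if (!is.null(config$categories)) {
    say("stage categories")
    categories <- stage("categories", categorize_affected(
      tc_res$affected, read_category_map(require_file(config$categories, "categories"))))
    jsonlite::write_json(categories, file.path(config$outdir, "categories.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  phenotype <- NULL
  if (!is.null(config$growth)) {
    say("stage phenotype")
    phenotype <- stage("phenotype", endpoint_summary(
      read_growth(require_file(config$growth, "growth")),
      config$control_condition, th$pathlength_factor))
    utils::write.table(phenotype$summary,
                       file.path(config$outdir, "phenotype_endpoints.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  variants <- NULL
  if (!is.null(config$variants_mutant) && !is.null(config$variants_wildtype)) {
    say("stage variants")
    variants <- stage("variants", {
      mut <- filter_variants(
        read_variants(require_file(config$variants_mutant, "mutant variants")),
        th$min_coverage, th$min_frequency)
      wt <- filter_variants(
        read_variants(require_file(config$variants_wildtype, "wild-type variants")),
        th$min_coverage, th$min_frequency)
      unique_to_mutant(mut, wt)
    })
    write_variants(variants, file.path(config$outdir, "mutant_unique_variants.tsv"))
  }

  manifest <- list(
    package = "redoxreg",
    version = as.character(utils::packageVersion("redoxreg")),
    generated_at = format(Sys.time(), tz = "UTC"),
    parameters = th,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    summary = c(
      tc_res$summary[c("n_affected", "n_down", "n_up", "n_in_tc", "n_tcs",
                       "n_rescued", "pct_down", "pct_up", "pct_in_tc")],
      list(n_unique_variants = if (is.null(variants)) NA else nrow(variants))
    )
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  say("done: ", config$outdir)
  invisible(manifest)
}
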
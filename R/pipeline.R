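# End-to-end pipeline: curation -> coverage -> abundance -> classification
# -> enrichment, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' genome detection breadth (0.5), gene detection coverage fraction (0.9)
#' and minimum depth (1), module completion threshold (0.75), enrichment
#' significance cutoff (q < 0.01), dereplication ANI ceiling (98%),
#' genome QC completeness floor (90%) and contamination ceiling (5%), the
#' classifier site universe (the eight sites of [classifier_sites()];
#' hard palate excluded), and the global seed.
#'
#' @param breadth_threshold Genome detection breadth threshold.
#' @param gene_cov_fraction,gene_min_depth Gene detection parameters.
#' @param module_completeness_threshold Module completion threshold.
#' @param q_threshold Enrichment significance cutoff (strict).
#' @param ani_threshold Dereplication ANI ceiling (percent).
#' @param min_completeness,max_contamination Genome QC bounds (percent).
#' @param site_universe Classifier site universe.
#' @param seed Integer seed for any stochastic stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(breadth_threshold = 0.5,
                            gene_cov_fraction = 0.9,
                            gene_min_depth = 1L,
                            module_completeness_threshold = 0.75,
                            q_threshold = 0.01,
                            ani_threshold = 98,
                            min_completeness = 90,
                            max_contamination = 5,
                            site_universe = classifier_sites(),
                            seed = 1L) {
  in_range <- function(x, lo, hi, what) {
    if (length(x) != 1L || is.na(x) || x < lo || x > hi) {
      stop_input("%s must lie in [%s, %s]", what, format(lo), format(hi))
    }
  }
  in_range(breadth_threshold, 1e-12, 1, "breadth_threshold")
  in_range(gene_cov_fraction, 1e-12, 1, "gene_cov_fraction")
  in_range(gene_min_depth, 1, Inf, "gene_min_depth")
  in_range(module_completeness_threshold, 0, 1, "module_completeness_threshold")
  in_range(q_threshold, 0, 1, "q_threshold")
  in_range(ani_threshold, 0, 100, "ani_threshold")
  in_range(min_completeness, 0, 100, "min_completeness")
  in_range(max_contamination, 0, 100, "max_contamination")
  if (length(site_universe) < 2L) {
    stop_input("site_universe needs at least 2 sites")
  }
  structure(
    list(
      breadth_threshold = breadth_threshold,
      gene_cov_fraction = gene_cov_fraction,
      gene_min_depth = as.integer(gene_min_depth),
      module_completeness_threshold = module_completeness_threshold,
      q_threshold = q_threshold,
      ani_threshold = ani_threshold,
      min_completeness = min_completeness,
      max_contamination = max_contamination,
      site_universe = sort(as.character(site_universe)),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; absent keys keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_input("config file not found: %s", path)
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop_input(
      "unknown config key(s): %s", paste(unknown, collapse = ", ")
    )
  }
  do.call(pipeline_config, vals)
}

log_stage <- function(fmt, ...) {
  message(sprintf("[oralmpg %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes, in order: genome curation (QC filter + ANI dereplication),
#' coverage summarization, relative abundance, habitat-preference
#' classification, and functional enrichment — each stage writing one
#' headered TSV into `out_dir` — followed by a JSON manifest recording the
#' configuration, package and R versions, seed, stages run, and MD5
#' checksums of all file inputs. Re-running with identical inputs and
#' configuration reproduces identical stage outputs.
#'
#' Stages whose inputs are absent from `inputs` are skipped with a message
#' when downstream stages can still run; a stage named in `skip` is always
#' skipped.
#'
#' @param inputs Named list of input paths (or in-memory objects where
#'   noted): `summary` (coverage summary TSV, or a list of
#'   [depth_profile()]s), `clades` (clade map TSV), `sites` (site map
#'   TSV), `genomes` (genome record TSV), `ani` (square ANI TSV),
#'   `functions` (function table TSV), `groups` (genome group TSV for
#'   enrichment; defaults to the classifier's preferred sites when
#'   omitted), `modules` (module definition TSV, optional).
#' @param out_dir Output directory, created if needed.
#' @param config A [pipeline_config()].
#' @param skip Character vector of stage names to skip, from
#'   `c("curation", "coverage", "abundance", "classification",
#'   "enrichment")`.
#' @return Invisibly, a list of the in-memory stage results plus the
#'   manifest.
#' @export
run_pipeline <- function(inputs, out_dir, config = pipeline_config(),
                         skip = character(0)) {
  stages_all <- c(
    "curation", "coverage", "abundance", "classification", "enrichment"
  )
  bad <- setdiff(skip, stages_all)
  if (length(bad) > 0) {
    stop_input("unknown stage(s) in skip: %s", paste(bad, collapse = ", "))
  }
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  results <- list()
  ran <- character(0)
  t0 <- proc.time()[["elapsed"]]

  want <- function(stage, needed) {
    if (stage %in% skip) {
      log_stage("skipping %s (requested)", stage)
      return(FALSE)
    }
    have <- needed %in% names(inputs)
    if (!all(have)) {
      log_stage(
        "skipping %s (missing input: %s)", stage,
        paste(needed[!have], collapse = ", ")
      )
      return(FALSE)
    }
    TRUE
  }
  finish <- function(stage, t_start) {
    ran <<- c(ran, stage)
    log_stage("%s done in %.1fs", stage,
              proc.time()[["elapsed"]] - t_start)
  }

  kept <- NULL
  if (want("curation", c("genomes", "ani"))) {
    t <- proc.time()[["elapsed"]]
    records <- read_genome_records_tsv(inputs$genomes)
    ani <- read_ani_tsv(inputs$ani)
    passed <- qc_filter(
      records, config$min_completeness, config$max_contamination
    )
    kept <- dereplicate_by_ani(passed, ani, config$ani_threshold)
    write_tsv(kept, file.path(out_dir, "curation.tsv"))
    finish("curation", t)
    results$curation <- kept
  }

  summary_df <- NULL
  if (want("coverage", "summary")) {
    t <- proc.time()[["elapsed"]]
    summary_df <- if (is.character(inputs$summary)) {
      # Re-derive detection from breadth so the configured threshold rules.
      df <- read_coverage_tsv(inputs$summary)
      df$detected <- detect_genome(df$breadth, config$breadth_threshold)
      df
    } else {
      summarize_profiles(inputs$summary, config$breadth_threshold)
    }
    if (!is.null(kept)) {
      summary_df <- summary_df[summary_df$genome_id %in% kept$genome_id, ]
    }
    write_coverage_tsv(summary_df, file.path(out_dir, "coverage.tsv"))
    finish("coverage", t)
    results$coverage <- summary_df
  }

  if (!is.null(summary_df) && want("abundance", "clades")) {
    t <- proc.time()[["elapsed"]]
    clades <- read_clade_map_tsv(inputs$clades)
    rel <- relative_abundance(summary_df)
    species <- species_relative_abundance(rel, clades)
    write_tsv(species, file.path(out_dir, "abundance.tsv"))
    finish("abundance", t)
    results$abundance <- species
  }

  classes <- NULL
  if (!is.null(summary_df) && want("classification", c("clades", "sites"))) {
    t <- proc.time()[["elapsed"]]
    clades <- read_clade_map_tsv(inputs$clades)
    site_map <- read_site_map_tsv(inputs$sites)
    classes <- classify_habitats(
      summary_df, clades, site_map,
      metric = "both", sites = config$site_universe,
      threshold = config$breadth_threshold
    )
    write_tsv(classes, file.path(out_dir, "classification.tsv"))
    finish("classification", t)
    results$classification <- classes
  }

  if (want("enrichment", "functions")) {
    t <- proc.time()[["elapsed"]]
    fn <- read_function_table_tsv(inputs$functions)
    groups <- if ("groups" %in% names(inputs)) {
      read_tsv(inputs$groups, "group table", c("genome_id", "group"))
    } else if (!is.null(classes)) {
      # habitat-preference groups from the abundance-metric classification
      clades <- read_clade_map_tsv(inputs$clades)
      pref <- classes[classes$metric == "abundance", ]
      data.frame(
        genome_id = clades$genome_id,
        group = pref$preferred_sites[
          match(clades$clade_id, pref$clade_id)
        ],
        stringsAsFactors = FALSE
      )
    } else {
      stop_input(
        "enrichment stage needs a `groups` input or a classification run"
      )
    }
    enr <- enrich_by_habitat(fn, groups, config$q_threshold)
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
    if ("modules" %in% names(inputs)) {
      modules <- read_modules_tsv(inputs$modules)
      comp <- module_completeness_table(
        fn, modules, config$module_completeness_threshold
      )
      mod_fn <- data.frame(
        genome_id = comp$genome_id, accession = comp$module_id,
        count = as.integer(comp$complete), stringsAsFactors = FALSE
      )
      mod_enr <- enrich_by_habitat(mod_fn, groups, config$q_threshold)
      write_tsv(comp, file.path(out_dir, "module_completeness.tsv"))
      write_tsv(mod_enr, file.path(out_dir, "module_enrichment.tsv"))
      results$module_enrichment <- mod_enr
    }
    finish("enrichment", t)
    results$enrichment <- enr
  }

  file_inputs <- inputs[vapply(inputs, is.character, logical(1))]
  manifest <- list(
    package = "oralmpg",
    version = as.character(utils::packageVersion("oralmpg")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(config),
    stages = ran,
    inputs = lapply(file_inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 2)
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  results$manifest <- manifest
  invisible(results)
}
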
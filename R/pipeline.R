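#' Assemble a pipeline configuration
#'
#' Accepts a YAML or JSON file path, or a named list. Fields: `spectra`,
#' `phenotypes`, `genotypes` (input paths; or `simulate: true` with an
#' optional `sim` parameter block), optional `annotation` (GFF3) and
#' `q_matrix`; `preprocess` (keep_min_nm, keep_max_nm, target_width_nm,
#' window, polyorder); `trait`; `engines` (subset of mlm, farmcpu, svr);
#' per-engine blocks `mlm`, `farmcpu`, `svr`; `hypwas` (folds, repeats,
#' subset_sizes, learner); `postgwas` (window_bp); `out_dir`; `seed`;
#' `gwas_on_trait` (also scan the trait itself).
#'
#' @param config path or named list.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop_config("YAML config needs the yaml package; use JSON instead")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(simulate = FALSE, trait = "yield",
                   engines = c("mlm", "farmcpu", "svr"),
                   preprocess = list(), hypwas = list(), mlm = list(),
                   farmcpu = list(), svr = list(),
                   postgwas = list(window_bp = 150000),
                   gwas_on_trait = FALSE,
                   out_dir = "hypwas_run", seed = 1L)
  cfg <- modifyList(defaults, config)
  bad <- setdiff(cfg$engines, c("mlm", "farmcpu", "svr"))
  if (length(bad))
    stop_config("unknown engine(s): %s", paste(bad, collapse = ", "))
  if (!isTRUE(cfg$simulate)) {
    for (f in c("spectra", "phenotypes", "genotypes")) {
      if (is.null(cfg[[f]]))
        stop_config("config needs '%s' (or simulate: true)", f)
      if (!file.exists(cfg[[f]]))
        stop_config("input file for '%s' not found: %s", f, cfg[[f]])
    }
  }
  for (f in c("annotation", "q_matrix")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop_config("input file for '%s' not found: %s", f, cfg[[f]])
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

stage_record <- function(manifest, name, ...) {
  manifest$stages[[name]] <- c(list(stage = name,
                                    time = format(Sys.time(), "%H:%M:%S")),
                               list(...))
  manifest
}

#' Run the hierarchical phenome-to-genome pipeline
#'
#' Stages, in order: preprocess (trim, rebin, smooth, outlier screen) ->
#' blup (per-band and trait genetic values) -> hypwas (RFE band selection)
#' -> gwas (each requested engine, on each selected band and optionally the
#' trait) -> postgwas (regions and, given annotation, candidate genes).
#' GWAS runs only on HypWAS-selected bands, implementing the hierarchical
#' integration: bands carry the prior phenome-level association with the
#' trait. Writes per-stage outputs plus a JSON run manifest under
#' `out_dir`; a failing stage aborts with a stage-named error, retaining
#' partial outputs.
#'
#' @param config a [pipeline_config()] (or path / list coercible to one).
#' @param dry_run validate the configuration and return the planned stages
#'   without computing.
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  cfg <- pipeline_config(if (inherits(config, "pipeline_config")) config
                         else config)
  stages <- c("preprocess", "blup", "hypwas", "gwas", "postgwas")
  if (dry_run)
    return(list(validated = TRUE, stages = stages, seed = cfg$seed))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("hypwas")),
                   seed = cfg$seed, engines = cfg$engines, stages = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## inputs
  if (isTRUE(cfg$simulate)) {
    sim <- simulate_dataset(do.call(sim_config,
                                    c(cfg$sim %||% list(),
                                      if (is.null(cfg$sim$seed))
                                        list(seed = cfg$seed))))
    S <- sim$spectra; plots <- sim$plots; G <- sim$genotypes
  } else {
    S <- read_spectra(cfg$spectra)
    plots <- read_plot_table(cfg$phenotypes)
    G <- read_hapmap(cfg$genotypes)
  }

  ## preprocess
  pre <- run_stage("preprocess", do.call(preprocess_spectra,
                                         c(list(S), cfg$preprocess)))
  write_spectra(pre$spectra, file.path(cfg$out_dir, "spectra_preprocessed.tsv"))
  manifest <- stage_record(manifest, "preprocess",
                           n_bands_in = length(S$wavelengths_nm),
                           n_bands_out = length(pre$spectra$wavelengths_nm),
                           outliers = pre$outliers)

  ## blup
  bl <- run_stage("blup", {
    bands <- blup_band_matrix(pre$spectra)
    tr_fit <- fit_blup(plots, trait = cfg$trait)
    trait_vals <- mean(plots$value[plots$trait == cfg$trait], na.rm = TRUE) +
      tr_fit$blup
    list(bands = bands, trait_fit = tr_fit, trait_vals = trait_vals)
  })
  genos <- intersect(rownames(bl$bands$values), names(bl$trait_vals))
  band_mat <- bl$bands$values[genos, , drop = FALSE]
  trait_vals <- bl$trait_vals[genos]
  data.table::fwrite(data.frame(genotype = genos, value = trait_vals),
                     file.path(cfg$out_dir, "blup_trait.tsv"), sep = "\t")
  data.table::fwrite(cbind(data.frame(genotype = genos), band_mat),
                     file.path(cfg$out_dir, "blup_bands.tsv"), sep = "\t")
  jsonlite::write_json(list(varcomp = as.list(bl$trait_fit$varcomp),
                            h2 = heritability(bl$trait_fit$varcomp,
                                              bl$trait_fit$n_env,
                                              max(1, bl$trait_fit$n_rep))),
                       file.path(cfg$out_dir, "variance_report.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- stage_record(manifest, "blup", n_genotypes = length(genos),
                           var_g = unname(bl$trait_fit$varcomp[1]))

  ## hypwas
  hw <- run_stage("hypwas", do.call(rfe_select,
                                    c(list(X = band_mat, y = trait_vals,
                                           seed = cfg$seed + 1L),
                                      cfg$hypwas)))
  write_rfe_profile(hw, file.path(cfg$out_dir, "hypwas"))
  manifest <- stage_record(manifest, "hypwas",
                           selected_bands = hw$selected_names,
                           optimal_size = hw$optimal_size)

  ## gwas
  targets <- band_mat[, hw$selected, drop = FALSE]
  if (isTRUE(cfg$gwas_on_trait))
    targets <- cbind(targets, trait = trait_vals)
  Gc <- impute_missing(filter_maf(G, cfg$maf %||% 0.05))
  Gc <- genotype_matrix(Gc$samples, Gc$map, Gc$dosage)  # drop attrs
  keep_s <- Gc$samples %in% genos
  Gc <- genotype_matrix(Gc$samples[keep_s], Gc$map,
                        Gc$dosage[keep_s, , drop = FALSE])
  Qm <- if (!is.null(cfg$q_matrix)) {
    Q <- read_q_matrix(cfg$q_matrix)
    Q[Gc$samples, , drop = FALSE]
  } else NULL
  results <- list()
  run_stage("gwas", {
    for (bn in colnames(targets)) {
      yv <- setNames(targets[, bn], rownames(targets))
      for (eng in cfg$engines) {
        res <- switch(eng,
          mlm = do.call(mlm_scan, c(list(y = yv, G = Gc, X = Qm), cfg$mlm)),
          farmcpu = do.call(farmcpu_scan,
                            c(list(y = yv, G = Gc, X = Qm), cfg$farmcpu)),
          svr = svr_gwas(yv, Gc,
                         do.call(svr_config,
                                 c(cfg$svr,
                                   if (is.null(cfg$svr$seed))
                                     list(seed = cfg$seed + 2L)))))
        key <- paste(bn, eng, sep = ".")
        results[[key]] <- res
        write_gwas_result(res, file.path(cfg$out_dir,
                                         paste0("gwas_", key, ".tsv")))
      }
    }
  })
  manifest <- stage_record(manifest, "gwas", n_scans = length(results),
                           n_markers = nrow(Gc$map))

  ## postgwas
  pg <- run_stage("postgwas", {
    regions <- do.call(rbind, lapply(names(results), function(k) {
      r <- extract_regions(results[[k]],
                           window_bp = cfg$postgwas$window_bp %||% 150000)
      if (nrow(r)) r$scan <- k
      r
    }))
    genes <- NULL
    if (!is.null(cfg$annotation) && !is.null(regions) && nrow(regions)) {
      genes <- overlap_genes(regions, read_gff3(cfg$annotation))
    }
    list(regions = regions, genes = genes)
  })
  if (!is.null(pg$regions) && nrow(pg$regions))
    data.table::fwrite(pg$regions, file.path(cfg$out_dir, "regions.tsv"),
                       sep = "\t")
  if (!is.null(pg$genes) && nrow(pg$genes))
    data.table::fwrite(pg$genes, file.path(cfg$out_dir, "candidate_genes.tsv"),
                       sep = "\t")
  manifest <- stage_record(manifest, "postgwas",
                           n_regions = if (is.null(pg$regions)) 0L
                           else nrow(pg$regions))

  manifest$completed <- names(manifest$stages)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
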
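# End-to-end orchestration: a YAML-configured run of
# simulate/load -> standardize -> diversity -> spatial/group statistics ->
# assembly inference, with a checksummed manifest for reproducibility.

config_defaults <- function() {
  list(
    scenario = NULL,
    inputs = NULL,
    standardization = "relative",
    analyses = list(alpha = TRUE, pcoa = TRUE, permanova = TRUE,
                    mantel = TRUE, distance_decay = TRUE, diel_cv = FALSE,
                    assembly = TRUE),
    permanova_terms = c("station", "irradiance_zone"),
    mantel_variables = c("temperature", "nitrate"),
    n_perm = 999L,
    n_null = 999L,
    seed = NULL,
    outdir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration, applies documented defaults
#' (`n_perm = 999`, `n_null = 999`, relative-abundance standardization),
#' rejects unknown keys (suggesting the closest known key), and enforces
#' cross-field invariants: exactly one of `scenario` / `inputs`; a seed
#' whenever any stochastic stage is enabled; positive permutation and
#' null-replicate counts.
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @return A validated config list of class `run_config`.
#' @export
validate_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0L) {
    hint <- vapply(unknown, function(k) {
      m <- agrep(k, names(defaults), max.distance = 2L, value = TRUE)
      if (length(m) > 0L) sprintf(" (did you mean '%s'?)", m[1L]) else ""
    }, character(1L))
    stop_invalid(sprintf("unknown config key(s): %s",
                         paste0("'", unknown, "'", hint, collapse = ", ")))
  }
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  an <- defaults$analyses
  for (k in names(cfg$analyses)) {
    if (!k %in% names(an)) stop_invalid(sprintf("unknown analysis toggle '%s'", k))
    an[[k]] <- isTRUE(cfg$analyses[[k]])
  }
  cfg$analyses <- an
  if (is.null(cfg$scenario) == is.null(cfg$inputs))
    stop_invalid("exactly one of 'scenario' or 'inputs' must be given")
  if (cfg$n_perm < 1L) stop_invalid("n_perm must be positive")
  if (cfg$n_null < 1L) stop_invalid("n_null must be positive")
  stochastic <- !is.null(cfg$scenario) || an$assembly || an$permanova ||
    an$mantel || identical(cfg$standardization, "rarefy")
  if (stochastic && is.null(cfg$seed))
    stop_invalid("a seed is required when any stochastic stage is enabled")
  if (!cfg$standardization %in% c("relative", "rarefy"))
    stop_invalid("standardization must be 'relative' or 'rarefy'")
  if (an$assembly && !is.null(cfg$inputs) && is.null(cfg$inputs$tree))
    stop_invalid("assembly stage is enabled but no tree input is configured")
  if (is.null(cfg$outdir)) stop_invalid("outdir is required")
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order and writes every
#' result as TSV (plus the tree as Newick in simulate mode) under
#' `config$outdir`. Returns a manifest listing per-stage outputs with MD5
#' checksums, so byte-level reproducibility from config + seed can be
#' asserted. On stage failure the error names the failed stage; outputs of
#' completed stages are preserved.
#'
#' @param config A validated [validate_config()] object (or a path/list,
#'   which will be validated first).
#' @return Manifest list: `settings`, `stages` (stage -> output files),
#'   `checksums` (file -> md5).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(settings = unclass(config), stages = list())
  tab <- tree <- meta <- NULL
  out <- function(name) file.path(config$outdir, name)
  stage <- function(name, expr) {
    files <- tryCatch(expr, error = function(e)
      stop_consist(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
    manifest$stages[[name]] <<- files
    files
  }

  if (!is.null(config$scenario)) {
    spec <- do.call(scenario_spec, c(config$scenario,
                                     if (is.null(config$scenario$seed)) list(seed = config$seed)))
    stage("simulate", {
      tree <- simulate_yule_tree(spec$n_taxa, seed = spec$seed)
      traits <- simulate_bm_traits(tree, spec$trait_diffusion, seed = spec$seed + 10L)
      depths <- c(20, 80, 200, 500)
      n_st <- ceiling(spec$n_sites / length(depths))
      meta_full <- simulate_transect_metadata(n_st, depths, seed = spec$seed + 20L)
      meta <- meta_full[seq_len(spec$n_sites), , drop = FALSE]
      tab <- simulate_metacommunity(spec, tree, traits, meta)
      c(write_community_table(tab, out("community_table.tsv")),
        {ape::write.tree(tree, out("tree.nwk")); out("tree.nwk")},
        write_sample_metadata(meta, out("metadata.tsv")),
        write_scenario_spec(spec, out("scenario.yaml")))
    })
  } else {
    stage("load", {
      tab <- read_community_table(config$inputs$table)
      tree <- if (!is.null(config$inputs$tree)) read_newick_tree(config$inputs$tree) else NULL
      meta <- if (!is.null(config$inputs$metadata)) read_sample_metadata(config$inputs$metadata) else NULL
      character(0)
    })
  }
  if (!is.null(tree)) {
    al <- align_inputs(tab, tree, meta)
    tab <- al$table; tree <- al$tree
    if (!is.null(al$meta)) meta <- al$meta
  }

  std <- standardize_table(tab, mode = config$standardization,
                           seed = config$seed)

  if (config$analyses$alpha) stage("alpha", {
    write_tsv(alpha_diversity(tab, tree), out("alpha_diversity.tsv"))
  })

  bc <- bray_curtis_matrix(std)
  stage("bray_curtis", {
    write_tsv(data.frame(sample_id = rownames(bc), bc, check.names = FALSE),
              out("bray_curtis.tsv"))
  })

  if (config$analyses$pcoa) stage("pcoa", {
    pc <- pcoa(bc, n_axes = 2L)
    write_tsv(data.frame(sample_id = rownames(pc$coordinates), pc$coordinates,
                         check.names = FALSE), out("pcoa_coordinates.tsv"))
  })

  if (config$analyses$permanova && !is.null(meta)) stage("permanova", {
    rows <- lapply(intersect(config$permanova_terms, names(meta)), function(term) {
      g <- meta[rownames(bc), term]
      if (length(unique(g)) < 2L || any(table(g) < 2L)) return(NULL)
      r <- permanova(bc, stats::setNames(g, rownames(bc)),
                     n_perm = config$n_perm, seed = config$seed, term = term)
      data.frame(term = term, pseudo_F = r$pseudo_F, r_squared = r$r_squared,
                 p_value = r$p_value, n_perm = r$n_permutations)
    })
    rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
    write_tsv(rows, out("permanova.tsv"))
  })

  if ((config$analyses$mantel || config$analyses$distance_decay) &&
      !is.null(meta) && all(c("lat", "lon") %in% names(meta))) {
    geo <- haversine_matrix(meta[rownames(bc), ])
    if (config$analyses$distance_decay) stage("distance_decay", {
      r <- distance_decay(bc, geo)
      write_tsv(data.frame(response = r$response, slope = r$slope,
                           intercept = r$intercept, r_squared = r$r_squared,
                           p_value = r$p_value, n_pairs = r$n),
                out("distance_decay.tsv"))
    })
    if (config$analyses$mantel) stage("mantel", {
      vars <- intersect(config$mantel_variables, names(meta))
      rows <- lapply(vars, function(v) {
        env <- tryCatch(environmental_distance(meta[rownames(bc), ], v),
                        error = function(e) NULL)
        if (is.null(env) || nrow(env) != nrow(bc)) return(NULL)
        r <- mantel_test(bc, env, n_perm = config$n_perm, seed = config$seed)
        data.frame(variable = v, r = r$r, p_value = r$p_value,
                   n_perm = r$n_permutations, tail = r$tail)
      })
      rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
      write_tsv(rows, out("mantel.tsv"))
    })
  }

  if (config$analyses$diel_cv && !is.null(meta) &&
      "time_point" %in% names(meta) &&
      length(unique(meta$time_point)) > 1L) stage("diel_cv", {
    write_tsv(diel_cv(std, meta), out("diel_cv.tsv"))
  })

  if (config$analyses$assembly) stage("assembly", {
    if (is.null(tree)) stop_invalid("assembly requires a tree")
    fit <- community_assembly(tab, tree, meta, n_null = config$n_null,
                              seed = config$seed)
    c(write_tsv(fit$pairs, out("assembly_pairs.tsv")),
      write_tsv(fit$fractions, out("assembly_fractions.tsv")))
  })

  files <- unique(unlist(manifest$stages, use.names = FALSE))
  manifest$checksums <- as.list(tools::md5sum(files[file.exists(files)]))
  yaml::write_yaml(list(settings = manifest$settings,
                        stages = manifest$stages,
                        checksums = manifest$checksums),
                   file.path(config$outdir, "manifest.yaml"))
  invisible(manifest)
}
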
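## Pipeline driver: run the full analysis (load/generate -> ratios ->
## significance -> Venn -> serum classes -> kinase enrichment -> functional
## context) from one declarative configuration, writing a TSV report bundle
## plus a manifest with config hash, seeds and row counts.

#' Pipeline configuration
#'
#' Exactly one of `synthetic` (a [synthetic_config()]) or `inputs` (a list
#' of file paths: `sites`, and optionally `kinase`, `annotations`, `edges`)
#' must be given. All analysis thresholds are surfaced here: `alpha = 0.05`
#' and `network_threshold = 0.9` follow the analysis conventions of the
#' study design; `min_bin`, `tau_change`, `tau_null`, `n_perm` and
#' `min_set_size` are package defaults.
#'
#' @param synthetic a [synthetic_config()], or `NULL`.
#' @param inputs named list of input paths, or `NULL`.
#' @param design a [silac_design()].
#' @param alpha significance threshold on the outlier p-value.
#' @param min_bin Significance B bin occupancy.
#' @param two_sided use the doubled (calibrated two-sided) outlier p-value.
#' @param tau_change,tau_null serum-response thresholds (log2 units).
#' @param n_perm,gsea_seed,min_set_size kinase-enrichment parameters.
#' @param network_threshold strict lower bound on edge confidence.
#' @param species species filter for the kinase-substrate table.
#' @param comparisons named list binding pipeline roles to design
#'   comparisons: `diff_high`, `diff_low`, `serum_x`, `serum_y`, `ranking`.
#' @return a validated `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL,
                            design = default_design(),
                            alpha = 0.05, min_bin = 300L, two_sided = FALSE,
                            tau_change = 1, tau_null = 0.5,
                            n_perm = 1000L, gsea_seed = 1L,
                            min_set_size = 3L,
                            network_threshold = 0.9, species = "mouse",
                            comparisons = list(diff_high = "smarcb1_high",
                                               diff_low = "smarcb1_low",
                                               serum_x = "serum_proficient",
                                               serum_y = "serum_deficient",
                                               ranking = "smarcb1_low")) {
  if (is.null(synthetic) == is.null(inputs)) {
    config_error("exactly one of 'synthetic' or 'inputs' must be given")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_config"))
  if (!is.null(inputs) && is.null(inputs$sites)) {
    config_error("inputs must at least name a site table")
  }
  need <- c("diff_high", "diff_low", "serum_x", "serum_y", "ranking")
  if (!all(need %in% names(comparisons))) {
    config_error(paste0("comparisons must bind: ", paste(need, collapse = ", ")))
  }
  for (cmp in unlist(comparisons)) {
    if (!cmp %in% names(design$comparisons)) {
      config_error(paste0("comparison '", cmp, "' not defined in design"))
    }
  }
  cfg <- as.list(environment())
  cfg$need <- NULL
  cfg$cmp <- NULL
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file mirrors [pipeline_config()] keys; a `synthetic:` block is
#' passed to [synthetic_config()], an `inputs:` block names file paths
#' (relative paths resolve against the YAML file's directory).
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synthetic)) {
    args$synthetic <- do.call(synthetic_config, y$synthetic)
  }
  if (!is.null(y$inputs)) {
    args$inputs <- lapply(y$inputs, function(p) {
      if (!grepl("^(/|[A-Za-z]:)", p)) file.path(dirname(path), p) else p
    })
  }
  for (key in c("alpha", "min_bin", "two_sided", "tau_change", "tau_null",
                "n_perm", "gsea_seed", "min_set_size", "network_threshold",
                "species", "comparisons")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  do.call(pipeline_config, args)
}

write_report <- function(df, out_dir, name, files) {
  path <- file.path(out_dir, name)
  write_tsv(as.data.frame(df), path)
  files[[name]] <- nrow(df)
  files
}

#' Run the full analysis pipeline
#'
#' Stages run in order: load or generate inputs; ratio computation for the
#' configured comparisons; Significance B calling on both genotype
#' comparisons; cross-condition Venn; serum-response classification; kinase
#' target-set enrichment (skipped, and noted in the manifest, when no
#' kinase table is available); annotation and network functional context
#' (likewise optional); count summary. Every output is a TSV under
#' `out_dir`, plus `counts.json` and `manifest.json` recording the config
#' hash, seeds, stage status and per-file row counts. Runs are idempotent
#' for a fixed configuration; any stage error aborts with the stage name
#' and leaves the manifest marked incomplete.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with every stage's in-memory result
#'   (`sites`, `ratios`, `significant`, `venn`, `partition`, `kinase`,
#'   `functional`, `counts`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  files <- list()
  manifest_path <- file.path(out_dir, "manifest.json")
  fail <- function(stage, e) {
    stages[[stage]] <<- paste0("error: ", conditionMessage(e))
    manifest <- list(package = "silacsites",
                     version = as.character(utils::packageVersion("silacsites")),
                     config_hash = rlang::hash(unclass(config)),
                     complete = FALSE, stages = stages, files = files)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    silac_abort(class(e)[1L],
                paste0("pipeline stage '", stage, "' failed: ",
                       conditionMessage(e)))
  }
  ## NB: stage expressions are promises evaluated in this function's frame,
  ## so plain `<-` inside them updates `files`/`ratios` here directly.
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) fail(name, e))
    stages[[name]] <<- "ok"
    res
  }

  ## -- load or generate ----------------------------------------------------
  loaded <- stage("load", {
    if (!is.null(config$synthetic)) {
      study <- generate_study(config$synthetic, config$design)
      ind <- file.path(out_dir, "inputs")
      dir.create(ind, showWarnings = FALSE)
      write_site_table(study$sites, file.path(ind, "sites.tsv"))
      write_kinase_substrates(study$kinase, file.path(ind, "kinase.tsv"))
      write_annotations(study$annotations, file.path(ind, "annotations.gmt"))
      write_edges(study$edges, file.path(ind, "edges.tsv"))
      write_tsv(study$truth, file.path(ind, "truth.tsv"))
      sites <- read_site_table(file.path(ind, "sites.tsv"))
      list(sites = sites,
           kinase = read_kinase_substrates(file.path(ind, "kinase.tsv"),
                                           species = config$species),
           annotations = read_annotations(file.path(ind, "annotations.gmt"),
                                          background = sort(unique(sites$gene))),
           edges = read_edges(file.path(ind, "edges.tsv")),
           truth = study$truth)
    } else {
      inp <- config$inputs
      list(
        sites = read_site_table(inp$sites),
        kinase = if (!is.null(inp$kinase)) {
          read_kinase_substrates(inp$kinase, species = config$species)
        },
        annotations = if (!is.null(inp$annotations)) {
          read_annotations(inp$annotations)
        },
        edges = if (!is.null(inp$edges)) read_edges(inp$edges),
        truth = NULL
      )
    }
  })

  ## -- ratios and significance ---------------------------------------------
  cmp_names <- unique(unlist(config$comparisons))
  ratios <- stage("ratios", {
    r <- lapply(cmp_names, function(cmp) {
      compute_ratios(loaded$sites, config$design, cmp)
    })
    names(r) <- cmp_names
    r
  })
  significant <- stage("significance", {
    out <- list()
    for (role in c("diff_high", "diff_low")) {
      cmp <- config$comparisons[[role]]
      ratios[[cmp]] <- suppressWarnings(add_significance(
        ratios[[cmp]], method = "B", alpha = config$alpha,
        min_bin = config$min_bin, two_sided = config$two_sided))
      files <- write_report(ratios[[cmp]],
                            out_dir, paste0("ratios_", cmp, ".tsv"), files)
      files <- write_report(volcano_table(ratios[[cmp]]),
                            out_dir, paste0("volcano_", cmp, ".tsv"), files)
      out[[role]] <- significant_sites(ratios[[cmp]], alpha = config$alpha)
      files <- write_report(out[[role]],
                            out_dir, paste0("significant_", cmp, ".tsv"), files)
    }
    out
  })

  venn <- stage("venn", {
    v <- venn_counts(significant$diff_high, significant$diff_low)
    files <- write_report(
      data.frame(quantity = names(unclass(v)),
                 count = unlist(unclass(v), use.names = FALSE)),
      out_dir, "venn.tsv", files)
    v
  })

  ## -- serum-response classes ----------------------------------------------
  partition <- stage("serum_response", {
    pairs <- serum_response_pairs(ratios[[config$comparisons$serum_x]],
                                  ratios[[config$comparisons$serum_y]])
    part <- partition_sites(pairs, tau_change = config$tau_change,
                            tau_null = config$tau_null)
    files <- write_report(part$table, out_dir, "serum_classes.tsv", files)
    part
  })

  ## -- kinase target enrichment --------------------------------------------
  kinase <- NULL
  if (is.null(loaded$kinase) || nrow(loaded$kinase) == 0L) {
    stages[["kinase_enrichment"]] <- "skipped: no kinase-substrate table"
  } else {
    kinase <- stage("kinase_enrichment", {
      ranked <- rank_sites(ratios[[config$comparisons$ranking]])
      sets <- build_target_sets(loaded$kinase, ranked$keys,
                                min_size = config$min_set_size)
      if (!length(sets)) {
        NULL
      } else {
        res <- kinase_enrichment(ranked, sets, n_perm = config$n_perm,
                                 seed = config$gsea_seed)
        files <- write_report(enrichment_report(res), out_dir,
                              "kinase_enrichment.tsv", files)
        res
      }
    })
    if (is.null(kinase)) {
      stages[["kinase_enrichment"]] <-
        "skipped: no target set overlaps the ranked universe"
    }
  }

  ## -- functional context ---------------------------------------------------
  functional <- stage("functional_context", {
    out <- list()
    if (!is.null(loaded$annotations)) {
      for (role in c("diff_high", "diff_low")) {
        query <- intersect(unique(significant[[role]]$gene),
                           loaded$annotations$background)
        if (length(query)) {
          enr <- term_enrichment(query, loaded$annotations)
          out[[paste0("terms_", role)]] <- enr
          files <- write_report(enr, out_dir,
                                paste0("term_enrichment_", role, ".tsv"),
                                files)
        }
      }
    }
    if (!is.null(loaded$edges)) {
      anti <- union(partition$proteins$persistent_in_deficient,
                    partition$proteins$lost_in_deficient)
      subnet <- high_confidence_subnetwork(anti, loaded$edges,
                                           threshold = config$network_threshold)
      out$subnetwork <- subnet
      files <- write_report(subnet$edges, out_dir, "subnetwork_edges.tsv",
                            files)
      comp_df <- if (length(subnet$components)) {
        data.frame(
          component = seq_along(subnet$components),
          size = lengths(subnet$components),
          members = vapply(subnet$components, paste, character(1L),
                           collapse = ";"))
      } else {
        data.frame(component = integer(), size = integer(),
                   members = character())
      }
      files <- write_report(comp_df, out_dir, "subnetwork_components.tsv",
                            files)
      if (!is.null(loaded$annotations) && length(subnet$components)) {
        ce <- component_enrichment(subnet, loaded$annotations)
        if (length(ce)) {
          ce_df <- do.call(rbind, lapply(names(ce), function(nm) {
            cbind(component = nm, ce[[nm]])
          }))
          out$component_terms <- ce
          files <- write_report(ce_df, out_dir, "component_enrichment.tsv",
                                files)
        }
      }
    }
    out
  })
  if (is.null(loaded$annotations) && is.null(loaded$edges)) {
    stages[["functional_context"]] <- "skipped: no annotations or edge list"
  }

  ## -- summary and manifest -------------------------------------------------
  results <- list(sites = loaded$sites, truth = loaded$truth,
                  ratios = ratios, significant = significant, venn = venn,
                  partition = partition, kinase = kinase,
                  functional = functional, config = config,
                  out_dir = out_dir)
  counts <- stage("summary", {
    cnt <- summarize_counts(results)
    jsonlite::write_json(cnt, file.path(out_dir, "counts.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    cnt
  })
  results$counts <- counts

  manifest <- list(
    package = "silacsites",
    version = as.character(utils::packageVersion("silacsites")),
    config_hash = rlang::hash(unclass(config)),
    seeds = list(synthetic = if (!is.null(config$synthetic)) config$synthetic$seed,
                 gsea = config$gsea_seed),
    complete = TRUE,
    stages = stages,
    files = files,
    counts = counts
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Summarize pipeline counts
#'
#' Counts report over the stage outputs: sites quantified per comparison,
#' significant sites and distinct proteins per genotype comparison with the
#' sign split (higher in proficient vs. higher in deficient), the
#' cross-condition overlap, and serum-response class sizes. All counts obey
#' the set-algebra identities of the underlying sets.
#'
#' @param results the results list assembled by [run_pipeline()].
#' @return a nested list of counts.
#' @export
summarize_counts <- function(results) {
  cfg <- results$config
  quantified <- lapply(results$ratios, nrow)
  sig <- lapply(c(diff_high = "diff_high", diff_low = "diff_low"),
                function(role) {
    s <- results$significant[[role]]
    list(sites = nrow(s),
         proteins = length(unique(s$gene)),
         higher_in_proficient = sum(s$log2_ratio > 0),
         higher_in_deficient = sum(s$log2_ratio < 0))
  })
  overlap <- list(
    sites = results$venn$both,
    proteins = length(intersect(unique(results$significant$diff_high$gene),
                                unique(results$significant$diff_low$gene)))
  )
  serum <- as.list(stats::setNames(results$partition$counts,
                                   results$partition$labels))
  serum$pairs <- results$partition$n
  out <- list(sites_loaded = nrow(results$sites),
              proteins_loaded = length(unique(results$sites$gene)),
              quantified = quantified,
              significant = sig,
              overlap = overlap,
              serum_response = serum)
  if (!is.null(results$kinase)) {
    tab <- results$kinase$table
    out$kinase <- list(sets_scored = nrow(tab),
                       fdr_below_0.05 = sum(tab$FDR < 0.05, na.rm = TRUE),
                       top_kinase = tab$kinase[which.max(tab$NES)])
  }
  out
}
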
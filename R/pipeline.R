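#' Run the full consensus-DE pipeline
#'
#' Orchestrates simulate -> qc -> deg -> jury -> classify -> enrich -> mirror
#' as one configured run. Inputs either come from files (counts + sample
#' sheet, annotation tables, optional OBO ontology) or from the synthetic
#' generator (`simulate` argument). Every stage writes its result tables as
#' TSV under `out_dir` and the run ends with a manifest recording the config,
#' input/output digests, seed, package version and per-stage wall-clock. A
#' stage failure aborts with a stage-named error after writing the partial
#' manifest.
#'
#' @param out_dir output directory (created if needed)
#' @param config a [pipeline_config()]
#' @param counts_path,sheet_path count matrix and sample sheet TSVs (ignored
#'   when `simulate` is given)
#' @param annotation_path gene-to-GO annotation TSV for the enrichment stage
#' @param ec_annotation_path gene-to-enzyme-code TSV for the mirror stage
#' @param obo_path optional OBO ontology; annotations are propagated when given
#' @param simulate optional list of arguments to [simulate_counts()]; may also
#'   carry `n_terms`, `planted`, `planted_ec` for [simulate_annotations()]
#' @param stages_enabled which stages to run
#' @param methods jury/caller methods classified, enriched and mirrored
#' @return a `run_manifest`
#' @export
run_pipeline <- function(out_dir,
                         config = pipeline_config(),
                         counts_path = NULL, sheet_path = NULL,
                         annotation_path = NULL, ec_annotation_path = NULL,
                         obo_path = NULL,
                         simulate = NULL,
                         stages_enabled = c("simulate", "qc", "deg", "jury",
                                            "classify", "enrich", "mirror"),
                         methods = c("J1", "J3")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  simulating <- "simulate" %in% stages_enabled && !is.null(simulate)
  # fail on missing inputs before any computation
  if (any(c("qc", "deg") %in% stages_enabled) && !simulating &&
      (is.null(counts_path) || is.null(sheet_path)))
    stopf("stage deg/qc enabled but no counts: give counts_path+sheet_path or simulate")
  if ("enrich" %in% stages_enabled && !simulating && is.null(annotation_path))
    stopf("stage enrich enabled but no annotation_path given")
  if ("mirror" %in% stages_enabled && !simulating && is.null(ec_annotation_path))
    stopf("stage mirror enabled but no ec_annotation_path given")
  for (p in c(counts_path, sheet_path, annotation_path, ec_annotation_path, obo_path))
    if (!is.null(p) && !file.exists(p)) stopf("input not readable: %s", p)

  manifest <- list(config = unclass(config),
                   seed = config$seed,
                   versions = list(package = as.character(utils::packageVersion("juryde")),
                                   r = R.version.string),
                   inputs = list(), outputs = list(), timing = list())
  register <- function(kind, name, path) {
    manifest[[kind]][[name]] <<- list(path = path,
                                      md5 = unname(tools::md5sum(path)))
  }
  write_manifest <- function() {
    path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    path
  }
  run_stage <- function(name, code) {
    if (!name %in% stages_enabled) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      manifest$failed_stage <<- name
      write_manifest()
      stopf("stage %s failed: %s", name, conditionMessage(e))
    })
    manifest$timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  out_path <- function(name) file.path(out_dir, name)

  cm <- NULL; ann <- NULL; ec_ann <- NULL; dag <- NULL
  run_stage("simulate", {
    if (simulating) {
      sim_args <- simulate[setdiff(names(simulate),
                                   c("n_terms", "planted", "planted_ec",
                                     "base_prevalence"))]
      sim_args$seed <- sim_args$seed %||% config$seed
      sim <- do.call(simulate_counts, sim_args)
      cm <- sim$counts
      write_counts(cm, out_path("counts.tsv"), out_path("samples.tsv"))
      write_tsv(sim$truth, out_path("truth.tsv"))
      register("outputs", "counts", out_path("counts.tsv"))
      register("outputs", "samples", out_path("samples.tsv"))
      register("outputs", "truth", out_path("truth.tsv"))
      ann <- simulate_annotations(sim$truth,
                                   n_terms = simulate$n_terms %||% 50L,
                                   planted = simulate$planted %||% list(),
                                   base_prevalence = simulate$base_prevalence %||% 0.1,
                                   seed = sim_args$seed + 1)
      write_annotations(ann, out_path("annotations.tsv"))
      register("outputs", "annotations", out_path("annotations.tsv"))
      ec_ann <- simulate_annotations(sim$truth, n_terms = 10L,
                                      planted = simulate$planted_ec %||% list(),
                                      base_prevalence = 0.05,
                                      namespace = "EC", seed = sim_args$seed + 2)
      write_annotations(ec_ann, out_path("ec_annotations.tsv"))
      register("outputs", "ec_annotations", out_path("ec_annotations.tsv"))
    }
  })
  if (!simulating && !is.null(counts_path)) {
    cm <- read_counts(counts_path, sheet_path)
    register("inputs", "counts", counts_path)
    register("inputs", "samples", sheet_path)
  }
  if (!simulating && !is.null(annotation_path)) {
    ann <- read_annotations(annotation_path)
    register("inputs", "annotations", annotation_path)
  }
  if (!simulating && !is.null(ec_annotation_path)) {
    ec_ann <- read_annotations(ec_annotation_path)
    register("inputs", "ec_annotations", ec_annotation_path)
  }
  if (!is.null(obo_path)) {
    dag <- read_obo(obo_path)
    register("inputs", "ontology", obo_path)
  }

  run_stage("qc", {
    qc <- qc_report(cm)
    write_tsv(data.frame(sample = rownames(qc$distances), qc$distances,
                         check.names = FALSE), out_path("qc_distances.tsv"))
    write_tsv(data.frame(sample = rownames(qc$pca$scores), qc$pca$scores,
                         check.names = FALSE), out_path("qc_pca.tsv"))
    write_tsv(data.frame(sample = qc$flagged), out_path("qc_flags.tsv"))
    for (f in c("qc_distances.tsv", "qc_pca.tsv", "qc_flags.tsv"))
      register("outputs", f, out_path(f))
  })

  de_tables <- list(); juries <- list(); assigns <- list()
  run_stage("deg", {
    for (scheme in config$schemes) {
      de_tables[[scheme]] <- lapply(config$callers, function(cl)
        run_de(cm, scheme = scheme, caller = cl, config = config))
      names(de_tables[[scheme]]) <- config$callers
      for (cl in config$callers) {
        f <- sprintf("de_%s_%s.tsv", scheme, cl)
        write_tsv(de_tables[[scheme]][[cl]], out_path(f))
        register("outputs", f, out_path(f))
      }
    }
  })
  run_stage("jury", {
    for (scheme in names(de_tables)) {
      juries[[scheme]] <- jury_aggregate(de_tables[[scheme]])
      f <- sprintf("jury_%s.tsv", scheme)
      write_tsv(juries[[scheme]], out_path(f))
      register("outputs", f, out_path(f))
    }
  })
  run_stage("classify", {
    for (scheme in names(juries)) {
      assigns[[scheme]] <- assign_trajectories(juries[[scheme]])
      f <- sprintf("trajectory_%s.tsv", scheme)
      write_tsv(assigns[[scheme]], out_path(f))
      register("outputs", f, out_path(f))
    }
  })
  run_stage("enrich", {
    use_ann <- if (!is.null(dag)) propagate_annotations(ann, dag) else ann
    universe <- rownames(cm$counts)
    rows <- list()
    for (scheme in names(assigns)) for (m in methods) {
      sub <- assigns[[scheme]][assigns[[scheme]]$method == m, , drop = FALSE]
      flat <- paste(rep("ns", length(attr(juries[[scheme]], "contrasts"))),
                    collapse = "_")
      for (categ in setdiff(unique(sub$category), flat)) {
        genes_cat <- sub$gene[sub$category == categ]
        rec <- enrich_category(genes_cat, universe, use_ann,
                               fdr = config$enrichment_fdr)
        if (nrow(rec)) {
          rec$scheme <- scheme; rec$method <- m; rec$category <- categ
          rows[[length(rows) + 1L]] <- rec
        }
      }
    }
    enr <- if (length(rows)) do.call(rbind, rows) else empty_enrichment()
    write_tsv(enr, out_path("enrichment.tsv"))
    register("outputs", "enrichment.tsv", out_path("enrichment.tsv"))
  })
  run_stage("mirror", {
    rows <- list()
    for (scheme in names(assigns)) for (m in methods) {
      mt <- mirror_kegg_tests(assigns[[scheme]], ec_ann, method = m)
      if (nrow(mt)) rows[[length(rows) + 1L]] <- mt
    }
    mir <- if (length(rows)) do.call(rbind, rows) else
      mirror_kegg_tests(assigns[[names(assigns)[1L]]], ec_ann, method = methods[1L])
    write_tsv(mir, out_path("mirror.tsv"))
    register("outputs", "mirror.tsv", out_path("mirror.tsv"))
  })

  manifest$manifest_path <- write_manifest()
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest\n")
  cat(sprintf("  seed: %s; package %s\n", x$seed, x$versions$package))
  cat(sprintf("  stages timed: %s\n",
              paste(sprintf("%s=%.2fs", names(x$timing), unlist(x$timing)),
                    collapse = ", ")))
  cat(sprintf("  outputs: %d files\n", length(x$outputs)))
  if (!is.null(x$failed_stage)) cat("  FAILED at stage:", x$failed_stage, "\n")
  invisible(x)
}
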
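#' Pipeline configuration
#'
#' Single configuration object governing every stage of the
#' simulate - indices - diffabund - ora pipeline. Stage parameter lists
#' only need the entries that deviate from the defaults.
#'
#' @param seed Integer seed for all stochastic stages.
#' @param run_label Free-text label stored in the report provenance.
#' @param cohort Named list of overrides for [cohort_config()].
#' @param indices List: `glucose_auc_unit`, `insulin_conversion`,
#'   `grid_step`, `mean_insulin` (see [compute_ir_profiles()]).
#' @param diffabund List: `transform`, `moderation`, `alpha_nominal`,
#'   `alpha_fdr` (see [run_differential_abundance()]).
#' @param ora List: `alpha`, `coverage_fraction`, `min_hits`, `universe`
#'   (`"panel"` keeps all genes mapped from the measured panel as sampling
#'   frame; `"collection"` intersects it with the collection's gene space),
#'   `merge_sets` (see [filter_enriched()], [export_network()]).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            run_label = "irproteo-run",
                            cohort = list(),
                            indices = list(),
                            diffabund = list(),
                            ora = list()) {
  cfg <- list(
    seed = as.integer(seed),
    run_label = run_label,
    cohort = cohort,
    indices = modifyList(list(glucose_auc_unit = "mol_l_h",
                              insulin_conversion = 6.0,
                              grid_step = 1,
                              mean_insulin = "trapezoid"), indices),
    diffabund = modifyList(list(transform = "none",
                                moderation = TRUE,
                                alpha_nominal = 0.05,
                                alpha_fdr = 0.05), diffabund),
    ora = modifyList(list(alpha = 0.05,
                          coverage_fraction = 0.05,
                          min_hits = NULL,
                          universe = "panel",
                          merge_sets = NULL),
                     ora)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; missing keys
#' fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "run_label", "cohort", "indices", "diffabund", "ora")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(out_dir, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  cat(line, "\n", sep = "", file = file.path(out_dir, "run.log"),
      append = TRUE)
}

#' Run the full pipeline
#'
#' Executes simulate - indices - diffabund - ora in order, each stage
#' writing its artifacts before the next stage reads them back from disk, so
#' that every reported number is recomputable from the stage files alone.
#' The run is idempotent for a given configuration and seed. A structured
#' log with per-stage record counts goes to `stderr` and to `run.log` in
#' the output directory; if a stage fails, a `FAILED` marker naming the
#' stage is left there and the error is re-thrown.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for all artifacts (created if needed).
#' @return A `"run_report"` list (see [write_report()]), invisibly
#'   containing also the per-stage artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, c("run.log", "FAILED")))
  stage <- "setup"
  report <- tryCatch({
    # -- simulate ---------------------------------------------------------
    stage <- "simulate"
    cohort_args <- modifyList(config$cohort, list(seed = config$seed))
    cc <- do.call(cohort_config, cohort_args)
    sim <- simulate_cohort(cc)
    data_dir <- file.path(out_dir, "data")
    paths <- write_cohort(sim, data_dir)
    pipeline_log(out_dir, stage,
                 sprintf("%d subjects, %d aptamers, %d gene sets written",
                         cc$n_subjects, cc$n_aptamers,
                         length(sim$gene_sets)))

    # -- indices ----------------------------------------------------------
    stage <- "indices"
    ogtt <- read.csv(paths[["ogtt"]], stringsAsFactors = FALSE)
    idx <- config$indices
    ir <- compute_ir_profiles(ogtt,
                              glucose_auc_unit = idx$glucose_auc_unit,
                              insulin_conversion = idx$insulin_conversion,
                              grid_step = idx$grid_step,
                              mean_insulin = idx$mean_insulin)
    indices_path <- file.path(out_dir, "indices.tsv")
    write.table(ir, indices_path, sep = "\t", row.names = FALSE,
                quote = FALSE)
    pipeline_log(out_dir, stage,
                 sprintf("%d IR profiles (%d flagged)", nrow(ir),
                         sum(nzchar(ir$qc_flags))))

    # -- diffabund --------------------------------------------------------
    stage <- "diffabund"
    covariates <- read.csv(paths[["covariates"]], stringsAsFactors = FALSE)
    prot_df <- read.csv(paths[["proteome"]], check.names = FALSE,
                        stringsAsFactors = FALSE)
    proteome <- as.matrix(prot_df[, -1, drop = FALSE])
    rownames(proteome) <- prot_df$subject_id
    ir_read <- read.delim(indices_path, stringsAsFactors = FALSE)
    dab <- config$diffabund
    da <- run_differential_abundance(proteome, covariates, ir_read,
                                     transform = dab$transform,
                                     moderation = dab$moderation,
                                     alpha_nominal = dab$alpha_nominal,
                                     alpha_fdr = dab$alpha_fdr)
    da_paths <- character(0)
    for (ax in unique(da$results$axis)) {
      pth <- file.path(out_dir, sprintf("da_%s.tsv", ax))
      write.table(da$results[da$results$axis == ax, ], pth, sep = "\t",
                  row.names = FALSE, quote = FALSE)
      da_paths[ax] <- pth
    }
    jsonlite::write_json(da$venn, file.path(out_dir, "venn.json"),
                         auto_unbox = TRUE, digits = NA)
    cnt <- da_counts(da)
    pipeline_log(out_dir, stage,
                 paste(sprintf("%s: %d DA (%d up / %d down), %d significant",
                               cnt$axis, cnt$total, cnt$up, cnt$down,
                               cnt$significant), collapse = "; "))

    # -- ora --------------------------------------------------------------
    stage <- "ora"
    annotation <- read.delim(paths[["annotation"]], stringsAsFactors = FALSE)
    collection <- read_gmt(paths[["gene_sets"]])
    panel_genes <- map_to_genes(unique(annotation$aptamer_id), annotation)
    universe <- panel_genes$gene_id
    if (config$ora$universe == "collection") {
      universe <- intersect(universe, unique(unlist(collection$sets)))
    }
    ora_out <- list()
    for (ax in unique(da$results$axis)) {
      res_ax <- da$results[da$results$axis == ax, ]
      de_apts <- res_ax$aptamer_id[res_ax$da]
      de_map <- map_to_genes(de_apts, annotation)
      de_genes <- intersect(de_map$gene_id, universe)
      enr <- hypergeom_enrich(de_genes, universe, collection)
      keep <- filter_enriched(enr, alpha = config$ora$alpha,
                              coverage_fraction = config$ora$coverage_fraction,
                              min_hits = config$ora$min_hits)
      write.table(enr, file.path(out_dir, sprintf("ora_%s.tsv", ax)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(keep, file.path(out_dir, sprintf("enriched_%s.tsv", ax)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      if (nrow(keep) > 0) {
        gene_tab <- de_map
        # per-gene association sign: mean logFC of the DA aptamers mapping
        # to the gene on this axis
        sub_ann <- annotation[annotation$aptamer_id %in% de_apts &
                                annotation$gene_id %in% gene_tab$gene_id, ]
        lfc <- setNames(res_ax$logFC, res_ax$aptamer_id)
        agg <- tapply(lfc[sub_ann$aptamer_id], sub_ann$gene_id, mean)
        gene_tab$logFC <- as.numeric(agg[gene_tab$gene_id])
        gene_tab$logFC[is.na(gene_tab$logFC)] <- 0
        export_network(keep, gene_tab, merge_sets = config$ora$merge_sets,
                       out_dir = file.path(out_dir,
                                           sprintf("network_%s", ax)))
      }
      ora_out[[ax]] <- list(all = enr, enriched = keep)
      pipeline_log(out_dir, stage,
                   sprintf("%s: %d mapped DE genes, %d/%d sets enriched",
                           ax, attr(enr, "n_de"), nrow(keep), nrow(enr)))
    }

    # -- report -----------------------------------------------------------
    stage <- "report"
    report <- build_run_report(da, ora_out, config)
    write_report(report, out_dir)
    pipeline_log(out_dir, stage, "report written (tsv, json, markdown)")
    report
  }, error = function(e) {
    writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(report)
}

build_run_report <- function(da, ora_out, config) {
  res <- da$results
  shared <- da$shared_ids
  wide <- function(ids) {
    m <- res[res$axis == "muscle", ][match(ids, res$aptamer_id[res$axis ==
                                                                 "muscle"]), ]
    l <- res[res$axis == "liver", ][match(ids, res$aptamer_id[res$axis ==
                                                                "liver"]), ]
    data.frame(aptamer_id = ids,
               logFC_muscle = m$logFC, p_muscle = m$p_value,
               logFC_liver = l$logFC, p_liver = l$p_value,
               stringsAsFactors = FALSE)
  }
  sig <- res[res$significant, c("axis", "aptamer_id", "logFC", "q_value")]
  rownames(sig) <- NULL
  enriched_tbl <- function(ax) {
    e <- ora_out[[ax]]$enriched
    data.frame(set = e$set, gene_ratio = e$gene_ratio, k = e$k, n = e$n,
               p_value = e$p_value, q_value = e$q_value,
               stringsAsFactors = FALSE)
  }
  structure(list(
    da_counts = da_counts(da),
    shared_table = wide(shared),
    significant_table = sig,
    enriched_muscle = enriched_tbl("muscle"),
    enriched_liver = enriched_tbl("liver"),
    venn = da$venn,
    provenance = list(run_label = config$run_label,
                      seed = config$seed,
                      config_hash = config_hash(config),
                      package_version =
                        as.character(utils::packageVersion("irproteo")))
  ), class = "run_report")
}

#' Write a run report as TSV tables, JSON and markdown
#'
#' The TSV and markdown renderings format p- and q-values in the
#' three-significant-digit scientific style of clinical tables
#' (`"3.26E-02"`); `report.json` is the machine-readable twin with full
#' numeric precision, from which [read_report()] reconstructs the report.
#' Empty reports produce valid header-only files.
#'
#' @param report A `"run_report"` from [run_pipeline()].
#' @param out_dir Output directory.
#' @param formats Subset of `c("tsv", "json", "markdown")`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir,
                         formats = c("tsv", "json", "markdown")) {
  stopifnot(inherits(report, "run_report"))
  bad <- setdiff(formats, c("tsv", "json", "markdown"))
  if (length(bad) > 0) stop("unknown report format: ", bad[1])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  fmt <- function(df) {
    for (cl in intersect(c("p_muscle", "p_liver", "p_value", "q_value"),
                         names(df))) {
      df[[cl]] <- format_pvalue(df[[cl]])
    }
    df
  }
  tables <- list(da_counts = report$da_counts,
                 shared = report$shared_table,
                 significant = report$significant_table,
                 enriched_muscle = report$enriched_muscle,
                 enriched_liver = report$enriched_liver)

  if ("tsv" %in% formats) {
    for (nm in names(tables)) {
      pth <- file.path(out_dir, sprintf("report_%s.tsv", nm))
      write.table(fmt(tables[[nm]]), pth, sep = "\t", row.names = FALSE,
                  quote = FALSE)
      paths[paste0("tsv_", nm)] <- pth
    }
  }
  if ("json" %in% formats) {
    pth <- file.path(out_dir, "report.json")
    jsonlite::write_json(unclass(report), pth, auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", null = "null")
    paths["json"] <- pth
  }
  if ("markdown" %in% formats) {
    pth <- file.path(out_dir, "report.md")
    md <- c(sprintf("# Run report: %s", report$provenance$run_label),
            "",
            sprintf("seed %d | config %s | irproteo %s",
                    report$provenance$seed, report$provenance$config_hash,
                    report$provenance$package_version),
            "",
            sprintf("Venn: muscle only %d | shared %d | liver only %d",
                    report$venn$muscle_only, report$venn$shared,
                    report$venn$liver_only),
            "")
    for (nm in names(tables)) {
      md <- c(md, sprintf("## %s", gsub("_", " ", nm)), "",
              md_table(fmt(tables[[nm]])), "")
    }
    writeLines(md, pth)
    paths["markdown"] <- pth
  }
  invisible(paths)
}

md_table <- function(df) {
  if (is.null(df) || ncol(df) == 0) return(character(0))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  if (nrow(df) == 0) return(c(header, sep))
  body <- apply(df, 1, function(r) {
    paste0("| ", paste(as.character(r), collapse = " | "), " |")
  })
  c(header, sep, body)
}

#' Reconstruct a run report from its JSON twin
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return A `"run_report"` list.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("da_counts", "shared_table", "significant_table",
               "enriched_muscle", "enriched_liver")) {
    raw[[nm]] <- as.data.frame(raw[[nm]], stringsAsFactors = FALSE)
  }
  structure(raw, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report '%s' (seed %d)\n", x$provenance$run_label,
              x$provenance$seed))
  print(x$da_counts)
  cat(sprintf("shared DA proteins: %d; enriched pathways: muscle %d, liver %d\n",
              x$venn$shared, nrow(x$enriched_muscle),
              nrow(x$enriched_liver)))
  invisible(x)
}
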
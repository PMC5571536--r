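#' Default contrast table for a factorial design
#'
#' One disease contrast (control -> disease) and one treatment contrast
#' (disease -> treated disease) per tissue.
#'
#' @param tissues Tissue labels.
#' @param control,disease,treated_disease Group labels.
#' @return Data frame with columns `tissue`, `ref`, `alt`, `role`.
#' @export
default_contrasts <- function(tissues = c("SCN", "DRG", "Glom", "cortex"),
                              control = "db/+", disease = "db/db",
                              treated_disease = "db/db PIO") {
  rbind(
    data.frame(tissue = tissues, ref = control, alt = disease,
               role = "disease", stringsAsFactors = FALSE),
    data.frame(tissue = tissues, ref = disease, alt = treated_disease,
               role = "treatment", stringsAsFactors = FALSE)
  )
}

#' Assemble a pipeline configuration
#'
#' @param simulation A [simulation_config()] used when no input paths are
#'   given.
#' @param matrix_path,metadata_path Optional paths to an existing FPKM
#'   matrix and metadata (TSV); when set, the simulation is skipped.
#' @param gmt_path Optional GMT file; when absent and data are simulated,
#'   gene sets are generated from the planted modules.
#' @param contrasts Contrast table (`tissue`, `ref`, `alt`, `role` with
#'   role in disease/treatment); every tissue with a treatment contrast
#'   must also have a disease contrast.
#' @param alpha FDR threshold for DEG calling.
#' @param som List of SOM settings: `width`, `height`, `epochs`,
#'   `min_fpkm`, `conditions` (data frame tissue/group),
#'   `correlation_threshold` for module merging.
#' @param enrichment List: `n_decoy_sets`, `set_size` for generated gene
#'   sets.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            matrix_path = NULL, metadata_path = NULL,
                            gmt_path = NULL,
                            contrasts = default_contrasts(simulation$tissues,
                                                          simulation$groups[1L],
                                                          simulation$groups[2L],
                                                          simulation$groups[4L]),
                            alpha = 0.05,
                            som = list(),
                            enrichment = list(),
                            seed = 1L) {
  contrasts <- as.data.frame(contrasts, stringsAsFactors = FALSE)
  req <- c("tissue", "ref", "alt", "role")
  if (!all(req %in% names(contrasts))) {
    abort_config("contrasts must have columns tissue, ref, alt, role")
  }
  if (!all(contrasts$role %in% c("disease", "treatment"))) {
    abort_config("contrast role must be 'disease' or 'treatment'")
  }
  trt_tissues <- contrasts$tissue[contrasts$role == "treatment"]
  dis_tissues <- contrasts$tissue[contrasts$role == "disease"]
  orphan <- setdiff(trt_tissues, dis_tissues)
  if (length(orphan)) {
    abort_config("tissue '%s' has a treatment contrast but no disease contrast",
                 orphan[1L])
  }
  som_defaults <- list(width = 7L, height = 7L, epochs = 50L, min_fpkm = 3,
                       conditions = default_module_conditions(),
                       correlation_threshold = 0.8)
  som <- utils::modifyList(som_defaults, som)
  enr_defaults <- list(n_decoy_sets = 5L, set_size = 50L)
  enrichment <- utils::modifyList(enr_defaults, enrichment)
  structure(list(simulation = simulation,
                 matrix_path = matrix_path, metadata_path = metadata_path,
                 gmt_path = gmt_path,
                 contrasts = contrasts, alpha = alpha,
                 som = som, enrichment = enrichment,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `simulation` key holds [simulation_config()] arguments.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sim_args <- raw$simulation %||% list()
  for (f in c("frac_disease_deg", "frac_reversed", "frac_exacerbated")) {
    if (!is.null(sim_args[[f]])) sim_args[[f]] <- unlist(sim_args[[f]])
  }
  sim <- do.call(simulation_config, sim_args)
  args <- raw[setdiff(names(raw), "simulation")]
  if (!is.null(args$contrasts)) {
    args$contrasts <- as.data.frame(args$contrasts,
                                    stringsAsFactors = FALSE)
  }
  if (!is.null(args$som$conditions)) {
    args$som$conditions <- as.data.frame(args$som$conditions,
                                         stringsAsFactors = FALSE)
  }
  do.call(pipeline_config, c(list(simulation = sim), args))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation (or ingestion), per-tissue DEG
#' contrasts, reversed/exacerbated overlap classification and
#' stratification, SOM preprocessing, training, module assignment,
#' U-matrix and threshold cluster merging, and Fisher over-representation
#' of every DEG stratum (universe: all genes) and SOM cluster (universe:
#' genes surviving the SOM filter).  All stage tables are written to
#' `output_dir` as TSV, plus a JSON summary (`summary.json`) and a run
#' log (`run.log`).  A fixed configuration and seed yield byte-identical
#' summaries.
#'
#' @param config A `pipeline_config`.
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  log_path <- file.path(output_dir, "run.log")
  cat("", file = log_path)
  log_stage <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                    stage, sprintf(fmt, ...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    log_stage(stage, "done in %.1fs", proc.time()[["elapsed"]] - t0)
    out
  }
  summary <- list(seed = config$seed, alpha = config$alpha)

  ## --- input -------------------------------------------------------------
  truth <- NULL
  em <- run_stage("input", {
    if (!is.null(config$matrix_path)) {
      read_expression_matrix(config$matrix_path, config$metadata_path)
    } else {
      sim <- config$simulation
      sim$seed <- derive_seed(config$seed, "simulate")
      ds <- generate_dataset(sim)
      truth <- ds$truth
      write_expression_matrix(ds$matrix,
                              file.path(output_dir, "matrix.tsv"),
                              file.path(output_dir, "metadata.tsv"))
      write_table(ds$truth$roles, file.path(output_dir, "truth.tsv"))
      ds$matrix
    }
  })
  log_stage("input", "%d genes x %d samples", nrow(em$values),
            ncol(em$values))
  summary$n_genes <- nrow(em$values)
  summary$n_samples <- ncol(em$values)

  sets <- run_stage("gene_sets", {
    if (!is.null(config$gmt_path)) {
      read_gene_sets(config$gmt_path)
    } else if (!is.null(truth) && nrow(truth$modules)) {
      s <- generate_gene_sets(truth,
                              n_decoy_sets = config$enrichment$n_decoy_sets,
                              set_size = config$enrichment$set_size,
                              seed = derive_seed(config$seed, "gene_sets"))
      write_gene_sets(s, file.path(output_dir, "sets.gmt"))
      s
    } else NULL
  })

  ## --- contrasts ---------------------------------------------------------
  deg_sets <- list()
  summary$contrasts <- run_stage("contrasts", {
    lapply(seq_len(nrow(config$contrasts)), function(i) {
      cc <- config$contrasts[i, ]
      res <- call_degs(em, cc$tissue, cc$ref, cc$alt, alpha = config$alpha)
      ds <- extract_deg_set(res)
      deg_sets[[paste(cc$tissue, cc$role)]] <<- ds
      fname <- sprintf("contrast_%s_%s_vs_%s.tsv",
                       sanitize_filename(cc$tissue),
                       sanitize_filename(cc$ref), sanitize_filename(cc$alt))
      write_table(res, file.path(output_dir, fname))
      list(name = attr(res, "contrast_name"), tissue = cc$tissue,
           role = cc$role, n_deg = length(ds$members),
           n_up = sum(ds$members > 0), n_down = sum(ds$members < 0))
    })
  })

  ## --- overlap classification --------------------------------------------
  strata <- list()
  summary$overlap <- run_stage("overlap", {
    tiss <- intersect(
      config$contrasts$tissue[config$contrasts$role == "disease"],
      config$contrasts$tissue[config$contrasts$role == "treatment"])
    out <- lapply(tiss, function(t) {
      cls <- classify_overlap(deg_sets[[paste(t, "disease")]],
                              deg_sets[[paste(t, "treatment")]],
                              tissue = t)
      tab <- rbind(
        data.frame(gene = cls$reversed, category = "reversed"),
        data.frame(gene = cls$exacerbated, category = "exacerbated"),
        data.frame(gene = cls$disease_only, category = "disease_only"),
        data.frame(gene = cls$treatment_only, category = "treatment_only"))
      d <- deg_sets[[paste(t, "disease")]]$members
      tr <- deg_sets[[paste(t, "treatment")]]$members
      tab$sign_disease <- unname(d[tab$gene])
      tab$sign_treatment <- unname(tr[tab$gene])
      write_table(tab, file.path(output_dir,
                                 sprintf("classification_%s.tsv",
                                         sanitize_filename(t))))
      strata[[t]] <<- stratify_deg_sets(cls, deg_sets[[paste(t, "disease")]])
      list(tissue = t,
           n_shared = length(cls$reversed) + length(cls$exacerbated),
           n_reversed = length(cls$reversed),
           n_exacerbated = length(cls$exacerbated),
           n_disease_only = length(cls$disease_only),
           n_treatment_only = length(cls$treatment_only),
           pct_reversed = cls$pct_reversed,
           pct_exacerbated = cls$pct_exacerbated)
    })
    names(out) <- tiss
    out
  })

  ## --- SOM ----------------------------------------------------------------
  som_out <- run_stage("som", {
    som_cfg <- config$som
    input <- preprocess_for_som(em, conditions = som_cfg$conditions,
                                min_fpkm = som_cfg$min_fpkm)
    grid <- train_som(input, width = som_cfg$width, height = som_cfg$height,
                      epochs = som_cfg$epochs,
                      seed = derive_seed(config$seed, "som"))
    asg <- assign_modules(grid, input)
    um <- compute_umatrix(grid)
    clusters <- merge_modules(grid, asg,
                              correlation_threshold =
                                som_cfg$correlation_threshold)
    cb <- data.frame(module = seq_len(nrow(grid$codebook)), grid$codebook)
    names(cb)[-1L] <- grid$condition_labels
    write_table(cb, file.path(output_dir, "som_codebook.tsv"))
    write_table(data.frame(gene = names(asg$modules),
                           module = unname(asg$modules)),
                file.path(output_dir, "som_assignment.tsv"))
    write_table(um, file.path(output_dir, "som_umatrix.tsv"))
    list(input = input, grid = grid, assignment = asg, clusters = clusters)
  })
  summary$som <- list(
    grid = c(config$som$width, config$som$height),
    n_genes_input = length(som_out$input$gene_ids),
    quantization_error = som_out$assignment$quantization_error,
    clusters = lapply(som_out$clusters, function(cl) {
      list(label = cl$label, modules = cl$module_ids,
           n_genes = length(cl$member_genes))
    })
  )

  ## --- enrichment ---------------------------------------------------------
  summary$enrichment <- run_stage("enrichment", {
    if (is.null(sets)) return(NULL)
    universe_all <- rownames(em$values)
    lists <- list()
    for (t in names(strata)) {
      for (nm in names(strata[[t]])) {
        if (length(strata[[t]][[nm]])) lists[[nm]] <- strata[[t]][[nm]]
      }
    }
    top <- list()
    for (nm in names(lists)) {
      res <- fisher_enrichment(lists[[nm]], universe_all, sets)
      write_table(res, file.path(output_dir,
                                 sprintf("enrichment_%s.tsv",
                                         sanitize_filename(nm))))
      best <- res[order(res$p_value, res$set), ][1L, ]
      top[[nm]] <- list(list_name = nm, universe = "all genes",
                        top_set = best$set, p_value = best$p_value,
                        q_value = best$q_value)
    }
    som_universe <- som_out$input$gene_ids
    for (cl in som_out$clusters) {
      if (!length(cl$member_genes)) next
      nm <- paste0("som_", cl$label)
      res <- fisher_enrichment(cl$member_genes, som_universe, sets)
      write_table(res, file.path(output_dir,
                                 sprintf("enrichment_%s.tsv",
                                         sanitize_filename(nm))))
      best <- res[order(res$p_value, res$set), ][1L, ]
      top[[nm]] <- list(list_name = nm, universe = "SOM-filtered genes",
                        top_set = best$set, p_value = best$p_value,
                        q_value = best$q_value)
    }
    if (length(lists) >= 2L) {
      emat <- enrichment_matrix(lists, universe_all, sets)
      m <- data.frame(set = rownames(emat$matrix), emat$matrix,
                      check.names = FALSE)
      write_table(m, file.path(output_dir, "enrichment_matrix.tsv"))
    }
    unname(top)
  })

  summary_path <- file.path(output_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  log_stage("summary", "written to %s", summary_path)
  invisible(summary)
}
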
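#' Default co-expression module archetypes
#'
#' Archetype profiles are defined over six focal conditions (two tissues
#' by three groups; the treated-control group is excluded), mirroring the
#' condition panel used for SOM module discovery.  The defaults plant
#' three biologically motivated patterns: a conserved-but-opposite pattern
#' (down in diabetic nerve, up in diabetic glomeruli, both restored by
#' treatment), an inflammation-like pattern (induced by disease in both
#' tissues, restored by treatment only in glomeruli), and a stable
#' tissue-offset pattern.
#'
#' @param n_genes Genes per archetype.
#' @param scale Multiplier applied to each profile (log2 units).
#' @return A list of archetypes, each a list with `name`, `profile`
#'   (length-6 numeric), `n_genes`, `scale`.
#' @export
default_archetypes <- function(n_genes = 50L, scale = 1.5) {
  list(
    list(name = "mito_reversed",
         profile = c(0, -1, 0, 0, 1, 0), n_genes = n_genes, scale = scale),
    list(name = "inflam_exacerbated",
         profile = c(0, 1, 1, 0, 1, 0), n_genes = n_genes, scale = scale),
    list(name = "tissue_offset",
         profile = c(0.5, 0.5, 0.5, -0.5, -0.5, -0.5),
         n_genes = n_genes, scale = scale)
  )
}

# The six focal conditions the archetype profiles are defined over.
default_module_conditions <- function(tissues = c("SCN", "Glom"),
                                      groups = c("db/+", "db/db",
                                                 "db/db PIO")) {
  data.frame(tissue = rep(tissues, each = length(groups)),
             group = rep(groups, times = length(tissues)),
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic expression-data generator
#'
#' Describes a factorial design of `tissues` x `groups` with
#' `n_replicates` samples per cell and planted per-tissue differential
#' expression.  Genes with a disease effect are split, per tissue, into
#' those whose treatment effect has the opposite sign (`frac_reversed`),
#' the same sign (`frac_exacerbated`), and no treatment effect
#' (remainder); an additional `frac_treatment_only` of genes respond to
#' treatment alone.  Fractions may be scalars or named per-tissue vectors.
#'
#' The defaults emulate a four-tissue (sciatic nerve, dorsal root ganglia,
#' kidney glomeruli, kidney cortex), four-group (db/+ control, db/db
#' diabetic, each with and without pioglitazone) mouse design with six
#' replicates, a diabetes effect in 6-13% of genes per tissue and
#' per-tissue reversal/exacerbation splits in which nearly all shared
#' glomerular disease genes are reversed by treatment while roughly half
#' the shared nerve genes are.
#'
#' @param tissues,groups Condition labels.
#' @param disease_groups Groups carrying the disease genotype (default:
#'   those containing `"db/db"`).
#' @param treated_groups Groups receiving treatment (default: those
#'   containing `"PIO"`).
#' @param n_replicates Samples per tissue x group cell (>= 2).
#' @param n_genes Number of genes.
#' @param frac_disease_deg Proportion of genes with a disease effect,
#'   per tissue.
#' @param frac_reversed,frac_exacerbated Proportions *of the disease
#'   genes* whose treatment effect is opposite-signed / same-signed,
#'   per tissue; their sum must not exceed 1.
#' @param frac_treatment_only Proportion of genes with a treatment effect
#'   but no disease effect.
#' @param effect_mean_log2,effect_sd_log2 Mean and spread of the absolute
#'   planted log2 effect sizes (magnitudes are truncated below at 0.25).
#' @param noise_sd_log2 Replicate noise standard deviation on the
#'   log2(FPKM+1) scale (>= 0).
#' @param baseline_log2_mean Mean of the exponential distribution of
#'   baseline log2(FPKM+1); the default 3 yields a right-skewed FPKM
#'   spectrum in which roughly half the genes fall below an FPKM floor
#'   of 3.
#' @param module_archetypes List of planted co-expression archetypes, see
#'   [default_archetypes()]; may be `list()` for none.
#' @param module_conditions Data frame (`tissue`, `group`) naming the
#'   conditions the archetype profiles span.
#' @param seed Integer seed; identical configs give bit-identical data.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(tissues = c("SCN", "DRG", "Glom", "cortex"),
                              groups = c("db/+", "db/db",
                                         "db/+ PIO", "db/db PIO"),
                              disease_groups = grep("db/db", groups,
                                                    value = TRUE),
                              treated_groups = grep("PIO", groups,
                                                    value = TRUE),
                              n_replicates = 6L,
                              n_genes = 4000L,
                              frac_disease_deg = c(SCN = 0.13, DRG = 0.13,
                                                   Glom = 0.10,
                                                   cortex = 0.06),
                              frac_reversed = c(SCN = 0.21, DRG = 0.025,
                                                Glom = 0.65, cortex = 0.085),
                              frac_exacerbated = c(SCN = 0.22, DRG = 0.025,
                                                   Glom = 0.03,
                                                   cortex = 0.085),
                              frac_treatment_only = 0.05,
                              effect_mean_log2 = 2,
                              effect_sd_log2 = 0.5,
                              noise_sd_log2 = 0.25,
                              baseline_log2_mean = 3,
                              module_archetypes = default_archetypes(),
                              module_conditions = default_module_conditions(),
                              seed = 1L) {
  per_tissue <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(x, length(tissues)), tissues)
    }
    if (!all(tissues %in% names(x))) {
      abort_config("%s must be a scalar or name every tissue", what)
    }
    x <- x[tissues]
    if (any(x < 0 | x > 1)) abort_config("%s must lie in [0, 1]", what)
    x
  }
  if (anyDuplicated(tissues) || anyDuplicated(groups)) {
    abort_config("tissue and group labels must be unique")
  }
  frac_disease_deg <- per_tissue(frac_disease_deg, "frac_disease_deg")
  frac_reversed <- per_tissue(frac_reversed, "frac_reversed")
  frac_exacerbated <- per_tissue(frac_exacerbated, "frac_exacerbated")
  if (any(frac_reversed + frac_exacerbated > 1 + 1e-12)) {
    abort_config("frac_reversed + frac_exacerbated must be <= 1")
  }
  if (frac_treatment_only < 0 || frac_treatment_only > 1) {
    abort_config("frac_treatment_only must lie in [0, 1]")
  }
  if (n_replicates < 2L) abort_config("n_replicates must be >= 2")
  if (n_genes < 1L) abort_config("n_genes must be >= 1")
  if (noise_sd_log2 < 0) abort_config("noise_sd_log2 must be >= 0")
  n_module_genes <- sum(vapply(module_archetypes,
                               function(a) as.integer(a$n_genes), integer(1)))
  if (n_module_genes > n_genes) {
    abort_config("archetype gene counts (%d) exceed n_genes (%d)",
                 n_module_genes, n_genes)
  }
  for (a in module_archetypes) {
    if (length(a$profile) != nrow(module_conditions)) {
      abort_config("archetype '%s' profile length != number of module conditions",
                   a$name)
    }
  }
  if (length(module_archetypes) &&
      (!all(module_conditions$tissue %in% tissues) ||
       !all(module_conditions$group %in% groups))) {
    abort_config("module_conditions must name existing tissues and groups")
  }
  structure(list(
    tissues = tissues, groups = groups,
    disease_groups = disease_groups, treated_groups = treated_groups,
    n_replicates = as.integer(n_replicates), n_genes = as.integer(n_genes),
    frac_disease_deg = frac_disease_deg, frac_reversed = frac_reversed,
    frac_exacerbated = frac_exacerbated,
    frac_treatment_only = frac_treatment_only,
    effect_mean_log2 = effect_mean_log2, effect_sd_log2 = effect_sd_log2,
    noise_sd_log2 = noise_sd_log2, baseline_log2_mean = baseline_log2_mean,
    module_archetypes = module_archetypes,
    module_conditions = module_conditions,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Planted role counts for one tissue: deterministic rounding so that role
# bookkeeping is exact given the fractions.
role_counts <- function(n_candidates, n_genes, f_dis, f_rev, f_exa, f_trt) {
  n_dis <- min(round(n_genes * f_dis), n_candidates)
  n_rev <- round(n_dis * f_rev)
  n_exa <- min(round(n_dis * f_exa), n_dis - n_rev)
  n_trt <- min(round(n_genes * f_trt), n_candidates - n_dis)
  c(reversed = n_rev, exacerbated = n_exa,
    disease_only = n_dis - n_rev - n_exa, treatment_only = n_trt)
}

#' Generate a synthetic FPKM dataset with planted ground truth
#'
#' For each gene a baseline log2(FPKM+1) is drawn from an exponential
#' distribution; per tissue, planted disease effects are added to the
#' disease-genotype groups and treatment effects to the treated groups
#' (additively on the log2 scale), so that reversed genes return toward
#' baseline in the treated-disease group.  Replicates receive Gaussian
#' log2 noise and values are mapped back to FPKM via `2^x - 1` truncated
#' at zero.  Genes carrying a module archetype instead follow the
#' archetype's profile across the focal conditions; their per-tissue truth
#' roles and effects are derived from that profile, so the truth table
#' reflects everything that was planted.  Output is bit-identical for
#' identical configurations.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (a `synthetic_truth`: per-gene, per-tissue roles and signed
#'   effects, plus the gene-to-archetype map).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n_genes <- config$n_genes
    gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
    rate <- 1 / config$baseline_log2_mean

    ## module genes: chosen first, excluded from role assignment
    arch <- config$module_archetypes
    arch_sizes <- vapply(arch, function(a) as.integer(a$n_genes), integer(1))
    module_idx <- if (sum(arch_sizes)) sample(n_genes, sum(arch_sizes))
                  else integer(0)
    module_of <- rep(NA_character_, n_genes)
    module_of[module_idx] <- rep(vapply(arch, `[[`, character(1), "name"),
                                 times = arch_sizes)

    baseline <- stats::rexp(n_genes, rate = rate)
    ## archetype genes must clear a moderate expression floor so that the
    ## planted modules survive SOM preprocessing
    if (length(module_idx)) {
      baseline[module_idx] <- 2 + stats::rexp(length(module_idx), rate = rate)
    }

    candidates <- setdiff(seq_len(n_genes), module_idx)
    roles <- list()
    dis_eff <- matrix(0, n_genes, length(config$tissues),
                      dimnames = list(gene_ids, config$tissues))
    trt_eff <- dis_eff
    draw_mag <- function(k) {
      pmax(stats::rnorm(k, config$effect_mean_log2, config$effect_sd_log2),
           0.25)
    }
    for (t in config$tissues) {
      cnt <- role_counts(length(candidates), n_genes,
                         config$frac_disease_deg[[t]],
                         config$frac_reversed[[t]],
                         config$frac_exacerbated[[t]],
                         config$frac_treatment_only)
      perm <- sample(candidates)
      idx <- split(perm[seq_len(sum(cnt))],
                   rep(names(cnt), times = cnt))
      role_vec <- rep("null", n_genes)
      role_vec[module_idx] <- "null"
      for (r in names(idx)) role_vec[idx[[r]]] <- r
      dis_idx <- c(idx$reversed, idx$exacerbated, idx$disease_only)
      sgn <- sample(c(-1, 1), length(dis_idx), replace = TRUE)
      dis_eff[dis_idx, t] <- sgn * draw_mag(length(dis_idx))
      n_re <- length(idx$reversed) + length(idx$exacerbated)
      if (n_re) {
        re_idx <- c(idx$reversed, idx$exacerbated)
        re_sign <- c(-sign(dis_eff[idx$reversed, t]),
                     sign(dis_eff[idx$exacerbated, t]))
        trt_eff[re_idx, t] <- re_sign * draw_mag(n_re)
      }
      if (length(idx$treatment_only)) {
        trt_eff[idx$treatment_only, t] <-
          sample(c(-1, 1), length(idx$treatment_only), replace = TRUE) *
          draw_mag(length(idx$treatment_only))
      }
      roles[[t]] <- data.frame(gene = gene_ids, tissue = t, role = role_vec,
                               disease_effect = dis_eff[, t],
                               treatment_effect = trt_eff[, t],
                               stringsAsFactors = FALSE)
    }
    roles <- do.call(rbind, roles)
    rownames(roles) <- NULL

    ## module genes carry real planted structure: derive their per-tissue
    ## disease/treatment effects (and hence roles) from the archetype
    ## profile over the control / disease / treated-disease conditions
    mc <- config$module_conditions
    if (length(module_idx)) {
      is_dis <- mc$group %in% config$disease_groups
      is_trt <- mc$group %in% config$treated_groups
      for (t in unique(mc$tissue)) {
        ctl_i <- which(mc$tissue == t & !is_dis & !is_trt)[1L]
        dis_i <- which(mc$tissue == t & is_dis & !is_trt)[1L]
        pio_i <- which(mc$tissue == t & is_dis & is_trt)[1L]
        if (anyNA(c(ctl_i, dis_i, pio_i))) next
        for (a in config$module_archetypes) {
          d_eff <- a$scale * (a$profile[dis_i] - a$profile[ctl_i])
          t_eff <- a$scale * (a$profile[pio_i] - a$profile[dis_i])
          role <- if (d_eff != 0 && t_eff != 0) {
            if (sign(d_eff) * sign(t_eff) < 0) "reversed" else "exacerbated"
          } else if (d_eff != 0) "disease_only"
          else if (t_eff != 0) "treatment_only" else "null"
          sel <- roles$tissue == t &
            roles$gene %in% gene_ids[module_idx][module_of[module_idx] ==
                                                   a$name]
          roles$role[sel] <- role
          roles$disease_effect[sel] <- d_eff
          roles$treatment_effect[sel] <- t_eff
        }
      }
    }

    ## group-mean log2(FPKM+1) per tissue x group
    mc <- config$module_conditions
    mc_key <- paste(mc$tissue, mc$group)
    arch_profile <- lapply(arch, function(a) a$scale * a$profile)
    names(arch_profile) <- vapply(arch, `[[`, character(1), "name")

    n_rep <- config$n_replicates
    total_samples <- length(config$tissues) * length(config$groups) * n_rep
    values <- matrix(NA_real_, n_genes, total_samples)
    sample_ids <- character(total_samples)
    md_tissue <- character(total_samples)
    md_group <- character(total_samples)
    col <- 0L
    for (t in config$tissues) {
      for (g in config$groups) {
        mu <- baseline +
          dis_eff[, t] * (g %in% config$disease_groups) +
          trt_eff[, t] * (g %in% config$treated_groups)
        ci <- match(paste(t, g), mc_key)
        if (!is.na(ci) && length(module_idx)) {
          prof <- vapply(module_of[module_idx],
                         function(m) arch_profile[[m]][ci], numeric(1))
          mu[module_idx] <- baseline[module_idx] + prof
        }
        for (r in seq_len(n_rep)) {
          col <- col + 1L
          x <- mu + stats::rnorm(n_genes, 0, config$noise_sd_log2)
          values[, col] <- pmax(2^x - 1, 0)
          sample_ids[col] <- sprintf("%s_%s_r%d", t, sanitize_filename(g), r)
          md_tissue[col] <- t
          md_group[col] <- g
        }
      }
    }
    dimnames(values) <- list(gene_ids, sample_ids)
    em <- expression_matrix(values,
                            data.frame(sample_id = sample_ids,
                                       tissue = md_tissue, group = md_group,
                                       stringsAsFactors = FALSE))
    truth <- structure(list(
      roles = roles,
      modules = data.frame(gene = gene_ids[module_idx],
                           module = module_of[module_idx],
                           stringsAsFactors = FALSE),
      gene_ids = gene_ids,
      config = config,
      seed = config$seed
    ), class = "synthetic_truth")
    list(matrix = em, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d genes, %d tissues, %d module genes\n",
              length(x$gene_ids), length(unique(x$roles$tissue)),
              nrow(x$modules)))
  print(table(x$roles$tissue, x$roles$role))
  invisible(x)
}

#' Build a gene-set collection matched to a synthetic dataset
#'
#' Produces one gene set per planted module archetype (containing exactly
#' that module's genes) plus `n_decoy_sets` decoy sets drawn uniformly
#' from all genes, giving enrichment analyses a known ground truth.
#'
#' @param truth A `synthetic_truth` containing at least one planted module.
#' @param n_decoy_sets Number of uniform decoy sets.
#' @param set_size Size of each decoy set (<= number of genes).
#' @param seed Integer seed.
#' @return A `gene_set_collection`.
#' @export
generate_gene_sets <- function(truth, n_decoy_sets = 5L, set_size = 50L,
                               seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!nrow(truth$modules)) {
    abort_config("truth contains no planted modules")
  }
  if (set_size > length(truth$gene_ids)) {
    abort_config("set_size (%d) exceeds number of genes (%d)",
                 set_size, length(truth$gene_ids))
  }
  with_seed(seed, {
    sets <- lapply(split(truth$modules$gene, truth$modules$module),
                   function(g) list(description = "planted module",
                                    members = g))
    ## split() orders by factor level; keep archetype insertion order
    ord <- unique(truth$modules$module)
    sets <- sets[ord]
    for (i in seq_len(n_decoy_sets)) {
      sets[[sprintf("decoy_%02d", i)]] <-
        list(description = "uniform decoy",
             members = sample(truth$gene_ids, set_size))
    }
    structure(sets, class = "gene_set_collection")
  })
}

#' Write all artefacts of a synthetic dataset to a directory
#'
#' Writes `matrix.tsv`, `metadata.tsv`, `truth.tsv` (per-gene, per-tissue
#' roles and effects), `modules.tsv` and `sets.gmt`.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param sets Optional `gene_set_collection` (defaults to
#'   [generate_gene_sets()] with the dataset's seed).
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(dataset, dir, sets = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_matrix(dataset$matrix,
                          file.path(dir, "matrix.tsv"),
                          file.path(dir, "metadata.tsv"))
  write_table(dataset$truth$roles, file.path(dir, "truth.tsv"))
  write_table(dataset$truth$modules, file.path(dir, "modules.tsv"))
  if (is.null(sets) && nrow(dataset$truth$modules)) {
    sets <- generate_gene_sets(dataset$truth,
                               seed = derive_seed(dataset$truth$seed,
                                                  "gene_sets"))
  }
  if (!is.null(sets)) write_gene_sets(sets, file.path(dir, "sets.gmt"))
  invisible(dir)
}
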
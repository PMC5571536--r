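small_config <- function(...) {
  simulation_config(n_genes = 400, n_replicates = 3,
                    module_archetypes = default_archetypes(n_genes = 20L),
                    seed = 7, ...)
}

test_that("identical configs give bit-identical datasets", {
  a <- generate_dataset(small_config())
  b <- generate_dataset(small_config())
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$roles, b$truth$roles)
  expect_identical(a$truth$modules, b$truth$modules)
})

test_that("zero noise and zero effects collapse to constant genes", {
  cfg <- simulation_config(n_genes = 50, n_replicates = 3,
                           frac_disease_deg = 0, frac_reversed = 0,
                           frac_exacerbated = 0, frac_treatment_only = 0,
                           noise_sd_log2 = 0,
                           module_archetypes = list(), seed = 1)
  ds <- generate_dataset(cfg)
  rng <- apply(ds$matrix$values, 1, function(v) diff(range(v)))
  expect_true(all(rng == 0))   # identical within and across all groups
})

test_that("role bookkeeping matches the configured fractions exactly", {
  cfg <- simulation_config(n_genes = 2000, frac_disease_deg = 0.2,
                           frac_reversed = 0.6, frac_exacerbated = 0.3,
                           frac_treatment_only = 0.05,
                           module_archetypes = list(), seed = 3)
  ds <- generate_dataset(cfg)
  counts <- table(ds$truth$roles$tissue, ds$truth$roles$role)
  for (t in cfg$tissues) {
    expect_equal(unname(counts[t, "reversed"]), round(400 * 0.6))
    expect_equal(unname(counts[t, "exacerbated"]), round(400 * 0.3))
    expect_equal(unname(counts[t, "disease_only"]), 400 - 240 - 120)
    expect_equal(unname(counts[t, "treatment_only"]), 100)
  }
})

test_that("roles are consistent with stored effect signs", {
  ds <- generate_dataset(small_config())
  r <- ds$truth$roles
  rev <- r[r$role == "reversed", ]
  expect_true(all(sign(rev$disease_effect) * sign(rev$treatment_effect) == -1))
  exa <- r[r$role == "exacerbated", ]
  expect_true(all(sign(exa$disease_effect) * sign(exa$treatment_effect) == 1))
  expect_true(all(r$treatment_effect[r$role == "disease_only"] == 0))
  expect_true(all(r$disease_effect[r$role == "treatment_only"] == 0))
  expect_true(all(r$disease_effect[r$role == "null"] == 0 &
                    r$treatment_effect[r$role == "null"] == 0))
})

test_that("planted effects are realized in group-mean log2 differences", {
  cfg <- simulation_config(tissues = "SCN", groups = c("db/+", "db/db"),
                           disease_groups = "db/db",
                           treated_groups = character(0),
                           n_genes = 300, n_replicates = 200,
                           frac_disease_deg = c(SCN = 0.3),
                           frac_reversed = c(SCN = 0),
                           frac_exacerbated = c(SCN = 0),
                           frac_treatment_only = 0,
                           module_archetypes = list(), seed = 11)
  ds <- generate_dataset(cfg)
  y <- log2(ds$matrix$values + 1)
  md <- ds$matrix$metadata
  diff_hat <- rowMeans(y[, md$group == "db/db"]) -
    rowMeans(y[, md$group == "db/+"])
  r <- ds$truth$roles
  planted <- r[r$role == "disease_only", ]
  ## restrict to the additive regime (no truncation at FPKM = 0)
  m_ctl <- rowMeans(y[planted$gene, md$group == "db/+", drop = FALSE])
  m_dis <- rowMeans(y[planted$gene, md$group == "db/db", drop = FALSE])
  ok <- m_ctl > 0.5 & m_dis > 0.5
  expect_gt(sum(ok), 30)
  se <- cfg$noise_sd_log2 * sqrt(2 / cfg$n_replicates)
  expect_true(all(abs(diff_hat[planted$gene][ok] -
                        planted$disease_effect[ok]) < 3 * se + 0.02))
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(frac_reversed = 0.7, frac_exacerbated = 0.5),
               "must be <= 1")
  expect_error(simulation_config(n_replicates = 1), "n_replicates")
  expect_error(simulation_config(
    n_genes = 10, module_archetypes = default_archetypes(n_genes = 50L)),
    "exceed n_genes")
})

test_that("generated gene sets mirror planted modules plus decoys", {
  ds <- generate_dataset(small_config())
  sets <- generate_gene_sets(ds$truth, n_decoy_sets = 5, set_size = 30,
                             seed = 2)
  expect_length(sets, 3 + 5)
  for (m in unique(ds$truth$modules$module)) {
    expect_setequal(sets[[m]]$members,
                    ds$truth$modules$gene[ds$truth$modules$module == m])
  }
  sets2 <- generate_gene_sets(ds$truth, n_decoy_sets = 5, set_size = 30,
                              seed = 2)
  expect_identical(unclass(sets), unclass(sets2))
  expect_error(generate_gene_sets(ds$truth, set_size = 1e5),
               "exceeds number of genes")
})
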
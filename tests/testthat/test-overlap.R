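mk_deg_set <- function(members, tissue = "SCN", name = "test") {
  structure(list(contrast_name = name, tissue = tissue, members = members),
            class = "deg_set")
}

test_that("sign products partition shared genes into reversed/exacerbated", {
  disease <- mk_deg_set(c(a = 1, b = -1, c = 1))
  treatment <- mk_deg_set(c(b = 1, c = 1, d = -1))
  cls <- classify_overlap(disease, treatment)
  expect_identical(cls$reversed, "b")       # -1 * +1
  expect_identical(cls$exacerbated, "c")    # +1 * +1
  expect_identical(cls$disease_only, "a")
  expect_identical(cls$treatment_only, "d")
  expect_equal(cls$pct_reversed, 50)
  expect_equal(cls$pct_exacerbated, 50)

  up_up <- classify_overlap(mk_deg_set(c(x = 1)), mk_deg_set(c(x = 1)))
  expect_identical(up_up$exacerbated, "x")
  up_down <- classify_overlap(mk_deg_set(c(x = 1)), mk_deg_set(c(x = -1)))
  expect_identical(up_down$reversed, "x")
})

test_that("classification is symmetric under simultaneous sign flips", {
  set.seed(1)
  genes <- sprintf("g%02d", 1:40)
  d <- setNames(sample(c(-1, 1), 25, TRUE), sample(genes, 25))
  t_ <- setNames(sample(c(-1, 1), 25, TRUE), sample(genes, 25))
  a <- classify_overlap(mk_deg_set(d), mk_deg_set(t_))
  b <- classify_overlap(mk_deg_set(-d), mk_deg_set(-t_))
  expect_identical(a$reversed, b$reversed)
  expect_identical(a$exacerbated, b$exacerbated)
})

test_that("partition identities hold and percentages sum to 100", {
  set.seed(2)
  genes <- sprintf("g%02d", 1:60)
  d <- setNames(sample(c(-1, 1), 35, TRUE), sample(genes, 35))
  t_ <- setNames(sample(c(-1, 1), 30, TRUE), sample(genes, 30))
  cls <- classify_overlap(mk_deg_set(d), mk_deg_set(t_))
  all_sets <- list(cls$reversed, cls$exacerbated, cls$disease_only,
                   cls$treatment_only)
  expect_equal(sum(lengths(all_sets)),
               length(unique(c(unlist(all_sets)))))  # pairwise disjoint
  expect_equal(length(cls$disease_only) + length(cls$reversed) +
                 length(cls$exacerbated), length(d))
  expect_equal(length(cls$treatment_only) + length(cls$reversed) +
                 length(cls$exacerbated), length(t_))
  expect_equal(cls$pct_reversed + cls$pct_exacerbated, 100)
})

test_that("cross_tissue_compare counts overlaps", {
  r <- cross_tissue_compare(c("a", "b", "c"), c("a", "b", "c"), "X", "Y")
  expect_equal(r$n_shared, 3)
  expect_equal(r$n_a_only, 0)
  expect_equal(r$n_b_only, 0)
  expect_identical(r$shared, c("a", "b", "c"))

  r2 <- cross_tissue_compare(c("a", "b", "c"), c("d", "e", "f", "g"))
  expect_equal(unlist(r2[c("n_a", "n_b", "n_shared", "n_a_only", "n_b_only")]),
               c(n_a = 3, n_b = 4, n_shared = 0, n_a_only = 3, n_b_only = 4))
})

test_that("stratification reproduces the three tissue strata", {
  disease <- mk_deg_set(c(a = 1, b = -1, c = 1))
  treatment <- mk_deg_set(c(b = 1, c = 1, d = -1))
  cls <- classify_overlap(disease, treatment)
  strata <- stratify_deg_sets(cls, disease)
  expect_named(strata, c("SCN db/db only", "SCN Exacerbated", "SCN Reversed"))
  expect_identical(strata[["SCN db/db only"]], "a")
  expect_identical(strata[["SCN Exacerbated"]], "c")
  expect_identical(strata[["SCN Reversed"]], "b")
  expect_equal(sum(lengths(strata)), length(disease$members))

  empty_cls <- classify_overlap(mk_deg_set(c(a = 1, b = -1)),
                                mk_deg_set(c(z = 1)))
  s2 <- stratify_deg_sets(empty_cls, mk_deg_set(c(a = 1, b = -1)))
  expect_length(s2[["SCN Exacerbated"]], 0)
  expect_length(s2[["SCN Reversed"]], 0)
  expect_setequal(s2[["SCN db/db only"]], c("a", "b"))
  expect_true(is.na(empty_cls$pct_reversed))
})

test_that("planted roles are recovered through the DEG + overlap pipeline", {
  cfg <- simulation_config(n_genes = 2500, frac_disease_deg = 0.2,
                           frac_reversed = 0.5, frac_exacerbated = 0.4,
                           module_archetypes = list(), seed = 5)
  ds <- generate_dataset(cfg)
  dis <- extract_deg_set(call_degs(ds$matrix, "Glom", "db/+", "db/db"))
  trt <- extract_deg_set(call_degs(ds$matrix, "Glom", "db/db", "db/db PIO"))
  cls <- classify_overlap(dis, trt)
  truth <- ds$truth$roles[ds$truth$roles$tissue == "Glom", ]
  truth_role <- setNames(truth$role, truth$gene)
  called <- c(setNames(rep("reversed", length(cls$reversed)), cls$reversed),
              setNames(rep("exacerbated", length(cls$exacerbated)),
                       cls$exacerbated))
  agreement <- mean(truth_role[names(called)] == called)
  expect_gt(agreement, 0.95)
  ## planted share: 0.5 / 0.9 reversed among the 450 planted shared genes
  p_planted <- 0.5 / 0.9
  se_pct <- 100 * sqrt(p_planted * (1 - p_planted) / 450)
  expect_lt(abs(cls$pct_reversed - 100 * p_planted), 3 * se_pct)
})
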
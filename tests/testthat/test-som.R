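test_that("hexagonal lattice distances behave like a hex grid", {
  lat <- som_lattice_distances(7, 7)
  expect_equal(lat, t(lat))
  expect_true(all(diag(lat) == 0))
  expect_equal(sum(lat[25, ] == 1), 6)     # interior module has 6 neighbours
  expect_equal(lat[42, 49], 1)             # the classic merged pair is adjacent
  corner_neighbours <- sum(lat[1, ] == 1)
  expect_true(corner_neighbours %in% 2:3)
})

test_that("preprocessing floors, logs and centres condition means", {
  conds <- data.frame(tissue = rep(c("SCN", "Glom"), each = 3),
                      group = rep(c("A", "B", "C"), 2))
  n_cond <- nrow(conds)
  vals <- rbind(rep(10, n_cond),     # constant, retained, centred to 0
                rep(2.9, n_cond),    # below floor everywhere, removed
                c(0, 0, 0, 0, 0, 8)) # one condition above floor, retained
  em <- tiny_matrix(vals, tissues = conds$tissue, groups = conds$group)
  inp <- preprocess_for_som(em, conds, min_fpkm = 3)
  expect_identical(inp$gene_ids, c("g1", "g3"))
  expect_equal(inp$profiles[1, ], rep(0, n_cond))
  expect_true(all(abs(rowSums(inp$profiles)) < 1e-9))

  ## constructed case: exactly 40% of genes below the floor
  set.seed(3)
  n <- 200
  below <- seq_len(0.4 * n)
  v <- matrix(runif(n * n_cond, 5, 50), nrow = n)
  v[below, ] <- runif(length(below) * n_cond, 0, 2.9)
  em2 <- tiny_matrix(v, tissues = conds$tissue, groups = conds$group)
  inp2 <- preprocess_for_som(em2, conds, min_fpkm = 3)
  expect_length(inp2$gene_ids, 0.6 * n)

  em3 <- tiny_matrix(matrix(0.1, 2, n_cond), tissues = conds$tissue,
                     groups = conds$group)
  expect_error(preprocess_for_som(em3, conds), "below the expression floor")
})

test_that("training is deterministic and fixes identical profiles", {
  set.seed(8)
  inp <- som_input_from(matrix(rnorm(150 * 6), ncol = 6))
  g1 <- train_som(inp, epochs = 10, seed = 4)
  g2 <- train_som(inp, epochs = 10, seed = 4)
  expect_identical(g1$codebook, g2$codebook)

  v <- c(2, -1, -1, 1, 0, -1)
  const <- som_input_from(matrix(rep(v, each = 60), nrow = 60))
  g <- train_som(const, epochs = 5, seed = 1)
  asg <- assign_modules(g, const)
  expect_lt(asg$quantization_error, 1e-9)
  expect_true(all(abs(g$codebook - rep(const$profiles[1, ],
                                       each = 49)) < 1e-9))
})

test_that("BMU assignment equals brute-force nearest neighbour with low-index ties", {
  set.seed(12)
  inp <- som_input_from(matrix(rnorm(100 * 6), ncol = 6))
  grid <- train_som(inp, epochs = 8, seed = 2)
  asg <- assign_modules(grid, inp)
  for (i in seq_len(100)) {
    d <- apply(grid$codebook, 1,
               function(cb) sqrt(sum((inp$profiles[i, ] - cb)^2)))
    expect_equal(unname(asg$modules[i]), which.min(d))
  }
  expect_equal(asg$quantization_error,
               mean(vapply(seq_len(100), function(i) {
                 min(apply(grid$codebook, 1,
                           function(cb) sqrt(sum((inp$profiles[i, ] - cb)^2))))
               }, numeric(1))), tolerance = 1e-12)

  ## exact tie between modules 5 and 9 resolves to the lower index
  cb <- matrix(5, nrow = 49, ncol = 4)
  cb[5, ] <- c(1, 0, 0, 0)
  cb[9, ] <- c(-1, 0, 0, 0)
  tie_grid <- structure(list(width = 7L, height = 7L, codebook = cb,
                             condition_labels = sprintf("c%d", 1:4),
                             training_meta = list()), class = "som_grid")
  tie_inp <- structure(list(gene_ids = "g1",
                            condition_labels = sprintf("c%d", 1:4),
                            profiles = matrix(0, 1, 4)), class = "som_input")
  expect_equal(unname(assign_modules(tie_grid, tie_inp)$modules), 5)
})

test_that("training does not increase quantization error", {
  for (s in 1:5) {
    set.seed(s)
    inp <- som_input_from(matrix(rnorm(600 * 6, sd = 2), ncol = 6))
    init <- with(list(), {
      set.seed(s + 100)
      inp$profiles[sample(600, 49), ]
    })
    grid0 <- structure(list(width = 7L, height = 7L, codebook = init,
                            condition_labels = inp$condition_labels,
                            training_meta = list()), class = "som_grid")
    qe0 <- assign_modules(grid0, inp)$quantization_error
    grid <- train_som(inp, epochs = 30, seed = s, init = init)
    qe1 <- assign_modules(grid, inp)$quantization_error
    expect_lte(qe1, qe0)
  }
})

test_that("a near-zero radius batch epoch equals one Lloyd k-means step", {
  set.seed(33)
  x <- matrix(rnorm(100 * 4), ncol = 4)
  inp <- som_input_from(x)
  init <- inp$profiles[1:4, ]
  grid <- train_som(inp, width = 2, height = 2, epochs = 1,
                    radius_init = 1e-9, radius_final = 1e-9, init = init)
  km <- suppressWarnings(kmeans(inp$profiles, centers = init,
                                iter.max = 1, algorithm = "Lloyd"))
  expect_equal(grid$codebook, unname(km$centers), tolerance = 1e-12)
})

test_that("U-matrix distances are symmetric edge distances", {
  inp <- som_input_from(matrix(rnorm(200 * 6), ncol = 6))
  grid <- train_som(inp, epochs = 10, seed = 6)
  um <- compute_umatrix(grid)
  lat <- som_lattice_distances(7, 7)
  expect_equal(nrow(um), sum(lat == 1))
  key <- paste(um$module_a, um$module_b)
  rev_key <- paste(um$module_b, um$module_a)
  expect_equal(um$distance, um$distance[match(key, rev_key)])
  d_42_49 <- sqrt(sum((grid$codebook[42, ] - grid$codebook[49, ])^2))
  expect_equal(um$distance[um$module_a == 42 & um$module_b == 49], d_42_49)

  same <- structure(list(width = 3L, height = 3L,
                         codebook = matrix(1, 9, 6),
                         condition_labels = sprintf("c%d", 1:6),
                         training_meta = list()), class = "som_grid")
  expect_true(all(compute_umatrix(same)$distance == 0))
})

test_that("module merging validates connectivity and respects thresholds", {
  inp <- som_input_from(matrix(rnorm(300 * 6), ncol = 6))
  grid <- train_som(inp, epochs = 10, seed = 9)
  asg <- assign_modules(grid, inp)

  cl <- merge_modules(grid, asg, module_ids = c(42, 49))
  expect_s3_class(cl, "som_cluster")
  expect_identical(cl$module_ids, c(42L, 49L))
  expect_setequal(cl$member_genes,
                  names(asg$modules)[asg$modules %in% c(42, 49)])

  single <- merge_modules(grid, asg, module_ids = 7)
  expect_setequal(single$member_genes,
                  names(asg$modules)[asg$modules == 7])

  expect_error(merge_modules(grid, asg, module_ids = c(1, 49)),
               "not lattice-connected")
  expect_error(merge_modules(grid, asg, module_ids = 50), "out of range")

  ## strict threshold with generic codebooks: every occupied module alone
  cls <- merge_modules(grid, asg, correlation_threshold = 1.0)
  expect_true(all(lengths(lapply(cls, `[[`, "module_ids")) == 1))
  expect_setequal(unlist(lapply(cls, `[[`, "module_ids")),
                  sort(unique(asg$modules)))
})

test_that("well-separated archetypes map to contiguous, mergeable territories", {
  sim <- archetype_profiles(n_per = 50, noise_sd = 0.1, seed = 1)
  grid <- train_som(sim$input, epochs = 30, seed = 1)
  asg <- assign_modules(grid, sim$input)
  clusters <- merge_modules(grid, asg, correlation_threshold = 0.8)
  gene_cluster <- rep(NA_integer_, 150)
  for (i in seq_along(clusters)) {
    gene_cluster[match(clusters[[i]]$member_genes,
                       sim$input$gene_ids)] <- i
  }
  expect_gte(ari(sim$labels, gene_cluster), 0.9)

  ## topology preservation: same-archetype genes sit closer on the lattice
  lat <- som_lattice_distances(7, 7)
  bmu <- unname(asg$modules)
  pair_lat <- lat[bmu, bmu]
  same <- outer(sim$labels, sim$labels, "==") & upper.tri(pair_lat)
  diff_ <- outer(sim$labels, sim$labels, "!=") & upper.tri(pair_lat)
  expect_lt(mean(pair_lat[same]), mean(pair_lat[diff_]))
})
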
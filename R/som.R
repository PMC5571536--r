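## Batch Kohonen self-organizing map on a hexagonal lattice.
##
## Modules (lattice units) are indexed 1..width*height in row-major order.
## The lattice uses an odd-r offset layout (odd rows shifted half a cell);
## neighbourhoods use the integer axial hex distance.

# Axial coordinates (q, r) for every module of a width x height grid.
hex_axial_coords <- function(width, height) {
  idx <- seq_len(width * height) - 1L
  row <- idx %/% width
  col <- idx %% width
  data.frame(q = col - (row - (row %% 2L)) %/% 2L, r = row)
}

#' Hexagonal lattice distances between SOM modules
#'
#' @param width,height Grid dimensions.
#' @return Integer matrix of axial hex distances between all module pairs
#'   (row-major module indexing).
#' @export
som_lattice_distances <- function(width, height) {
  ax <- hex_axial_coords(width, height)
  dq <- outer(ax$q, ax$q, "-")
  dr <- outer(ax$r, ax$r, "-")
  (abs(dq) + abs(dr) + abs(dq + dr)) / 2
}

# Squared Euclidean distances from every profile row to every codebook
# row, computed term-by-term so that symmetric inputs give exact ties.
profile_dist2 <- function(profiles, codebook) {
  tx <- t(profiles)
  matrix(vapply(seq_len(nrow(codebook)),
                function(m) colSums((tx - codebook[m, ])^2),
                numeric(nrow(profiles))),
         nrow = nrow(profiles), ncol = nrow(codebook))
}

#' Prepare an expression matrix for SOM training
#'
#' Computes the mean FPKM of every gene in each requested condition
#' (tissue x group), removes genes whose maximum condition mean falls
#' below the expression floor, transforms the retained means to
#' log2(mean + 1), and centres each gene's profile at zero.
#'
#' @param matrix An [expression_matrix()].
#' @param conditions Data frame with columns `tissue`, `group`; the
#'   default is the six-condition panel of [default_module_conditions()].
#' @param min_fpkm Expression floor: genes with all condition means below
#'   this FPKM value are removed (default 3).
#' @return A `som_input`: list with `gene_ids`, `condition_labels`, and
#'   `profiles`, a genes x conditions matrix whose rows sum to zero.
#' @export
preprocess_for_som <- function(matrix, conditions = default_module_conditions(),
                               min_fpkm = 3) {
  stopifnot(inherits(matrix, "expression_matrix"))
  cm <- condition_means(matrix, conditions)
  keep <- apply(cm, 1L, max) >= min_fpkm
  if (!any(keep)) {
    stop("all genes fall below the expression floor", call. = FALSE)
  }
  prof <- log2(cm[keep, , drop = FALSE] + 1)
  prof <- prof - rowMeans(prof)
  structure(list(gene_ids = rownames(prof),
                 condition_labels = colnames(cm),
                 profiles = unname(prof)),
            class = "som_input")
}

#' Train a batch self-organizing map
#'
#' Batch Kohonen training: the codebook is initialized by seeded sampling
#' of input profiles; each epoch assigns every gene to its best-matching
#' unit (BMU, Euclidean distance) and then replaces every codebook vector
#' by the neighbourhood-weighted mean of all profiles, with a Gaussian
#' neighbourhood kernel over hexagonal lattice distance.  The
#' neighbourhood radius decays linearly from `radius_init` to
#' `radius_final` across epochs.  Training is deterministic given the
#' seed and independent of gene order.
#'
#' @param input A `som_input` from [preprocess_for_som()].
#' @param width,height Grid dimensions (default 7 x 7).
#' @param epochs Number of batch epochs (default 50).
#' @param seed Integer seed for codebook initialization.
#' @param radius_init,radius_final Neighbourhood radius schedule, in
#'   lattice-distance units; defaults `max(width, height) / 2` down
#'   to 0.5.
#' @param init Optional explicit initial codebook (modules x conditions
#'   matrix); overrides the seeded sampling.
#' @return A `som_grid`: list with `width`, `height`, `topology`,
#'   `codebook` (modules x conditions), `condition_labels`, and
#'   `training_meta`.
#' @export
train_som <- function(input, width = 7L, height = 7L, epochs = 50L,
                      seed = 1L,
                      radius_init = max(width, height) / 2,
                      radius_final = 0.5, init = NULL) {
  stopifnot(inherits(input, "som_input"), epochs >= 1L)
  x <- input$profiles
  n <- nrow(x)
  if (n == 0L) stop("empty SOM input", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite profile values", call. = FALSE)
  k <- as.integer(width) * as.integer(height)
  if (n < k) {
    warning(sprintf("fewer genes (%d) than modules (%d)", n, k))
  }
  codebook <- if (!is.null(init)) {
    stopifnot(is.matrix(init), nrow(init) == k, ncol(init) == ncol(x))
    unname(init)
  } else {
    with_seed(seed, x[sample(n, k, replace = n < k), , drop = FALSE])
  }
  lat <- som_lattice_distances(width, height)
  for (e in seq_len(epochs)) {
    frac <- if (epochs == 1L) 1 else (e - 1) / (epochs - 1)
    radius <- radius_init + frac * (radius_final - radius_init)
    d2 <- profile_dist2(x, codebook)
    bmu <- max.col(-d2, ties.method = "first")
    h <- exp(-lat^2 / (2 * radius^2))      # k x k neighbourhood kernel
    w <- h[, bmu, drop = FALSE]            # k x n influence weights
    denom <- rowSums(w)
    num <- w %*% x
    upd <- denom > 1e-12
    codebook[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 topology = "hexagonal, odd-r offset rows",
                 codebook = codebook,
                 condition_labels = input$condition_labels,
                 training_meta = list(seed = as.integer(seed),
                                      epochs = as.integer(epochs),
                                      radius_init = radius_init,
                                      radius_final = radius_final,
                                      init = if (is.null(init))
                                        "seeded profile sampling"
                                      else "user-supplied")),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("som_grid: %d x %d hexagonal lattice, %d conditions, %d epochs\n",
              x$width, x$height, ncol(x$codebook),
              x$training_meta$epochs))
  invisible(x)
}

#' Assign genes to their best-matching SOM modules
#'
#' The BMU of a gene is the module whose codebook vector is nearest in
#' Euclidean distance; exact ties are broken toward the lowest module
#' index.  The quantization error is the mean distance of profiles to
#' their BMU codebooks.
#'
#' @param grid A `som_grid`.
#' @param input A `som_input` with the same condition dimensionality.
#' @return A `module_assignment`: list with `modules` (named integer
#'   vector, gene -> module index) and `quantization_error`.
#' @export
assign_modules <- function(grid, input) {
  stopifnot(inherits(grid, "som_grid"), inherits(input, "som_input"))
  if (ncol(input$profiles) != ncol(grid$codebook)) {
    abort_config("input has %d conditions but grid expects %d",
                 ncol(input$profiles), ncol(grid$codebook))
  }
  d2 <- profile_dist2(input$profiles, grid$codebook)
  bmu <- max.col(-d2, ties.method = "first")
  qe <- mean(sqrt(d2[cbind(seq_len(nrow(d2)), bmu)]))
  structure(list(modules = stats::setNames(bmu, input$gene_ids),
                 quantization_error = qe,
                 n_modules = nrow(grid$codebook)),
            class = "module_assignment")
}

#' U-matrix: codebook distances between adjacent modules
#'
#' For every pair of hexagonally adjacent modules, the Euclidean distance
#' between their codebook vectors.  Low distances indicate similar
#' neighbouring modules; ridges of high distance separate module
#' territories.
#'
#' @param grid A `som_grid`.
#' @return Data frame with columns `module_a`, `module_b`, `distance`;
#'   each undirected edge appears in both orientations.
#' @export
compute_umatrix <- function(grid) {
  stopifnot(inherits(grid, "som_grid"))
  lat <- som_lattice_distances(grid$width, grid$height)
  edges <- which(lat == 1, arr.ind = TRUE)   # both orientations
  d <- sqrt(rowSums((grid$codebook[edges[, 1L], , drop = FALSE] -
                     grid$codebook[edges[, 2L], , drop = FALSE])^2))
  out <- data.frame(module_a = edges[, 1L], module_b = edges[, 2L],
                    distance = d)
  out[order(out$module_a, out$module_b), , drop = FALSE]
}

# Connected components of a module subset under hex adjacency, optionally
# restricted to edges passing `edge_ok(a, b)`.
module_components <- function(ids, lat, edge_ok = function(a, b) TRUE) {
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  next_comp <- 0L
  for (s in ids) {
    if (!is.na(comp[[as.character(s)]])) next
    next_comp <- next_comp + 1L
    queue <- s
    comp[[as.character(s)]] <- next_comp
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      nb <- ids[lat[cur, ids] == 1 &
                  is.na(comp[as.character(ids)])]
      nb <- nb[vapply(nb, function(b) isTRUE(edge_ok(cur, b)), logical(1))]
      if (length(nb)) {
        comp[as.character(nb)] <- next_comp
        queue <- c(queue, nb)
      }
    }
  }
  split(ids, comp[as.character(ids)])
}

#' Merge adjacent SOM modules into clusters
#'
#' Two modes.  *Explicit*: `module_ids` names a lattice-connected set of
#' modules (e.g. a hand-picked pair such as modules 42 and 49 on a 7 x 7
#' grid) and the single merged cluster is returned.  *Threshold*:
#' adjacent non-empty modules whose codebook vectors have Pearson
#' correlation at or above `correlation_threshold` are merged, and the
#' list of resulting clusters (connected components) is returned.
#' Modules with no assigned genes are excluded from threshold merging:
#' they represent no genes and would otherwise bridge unrelated
#' territories.
#'
#' @param grid A `som_grid`.
#' @param assignment A `module_assignment` for the same grid.
#' @param module_ids Integer vector of lattice-connected module indices
#'   (explicit mode).
#' @param correlation_threshold Pearson correlation threshold in
#'   threshold mode (default 0.8 when `module_ids` is absent).
#' @return Explicit mode: one `som_cluster` (list with `module_ids`,
#'   `member_genes`, `label`).  Threshold mode: a list of `som_cluster`
#'   objects ordered by their smallest module index.
#' @export
merge_modules <- function(grid, assignment, module_ids = NULL,
                          correlation_threshold = NULL) {
  stopifnot(inherits(grid, "som_grid"),
            inherits(assignment, "module_assignment"))
  k <- nrow(grid$codebook)
  lat <- som_lattice_distances(grid$width, grid$height)
  make_cluster <- function(ids, label) {
    structure(list(module_ids = sort(ids),
                   member_genes = sort(names(assignment$modules)[
                     assignment$modules %in% ids], method = "radix"),
                   label = label),
              class = "som_cluster")
  }
  if (!is.null(module_ids)) {
    module_ids <- unique(as.integer(module_ids))
    if (any(module_ids < 1L | module_ids > k)) {
      abort_config("module index out of range 1..%d", k)
    }
    comps <- module_components(module_ids, lat)
    if (length(comps) > 1L) {
      abort_config("module set {%s} is not lattice-connected",
                   paste(sort(module_ids), collapse = ", "))
    }
    return(make_cluster(module_ids,
                        paste0("modules_",
                               paste(sort(module_ids), collapse = "+"))))
  }
  threshold <- correlation_threshold %||% 0.8
  occupied <- sort(unique(assignment$modules))
  edge_ok <- function(a, b) {
    ca <- grid$codebook[a, ]; cb <- grid$codebook[b, ]
    if (stats::sd(ca) == 0 || stats::sd(cb) == 0) return(FALSE)
    stats::cor(ca, cb) >= threshold
  }
  comps <- module_components(occupied, lat, edge_ok)
  comps <- comps[order(vapply(comps, min, numeric(1)))]
  lapply(seq_along(comps), function(i) {
    make_cluster(as.integer(comps[[i]]), sprintf("cluster_%02d", i))
  })
}

#' @export
print.som_cluster <- function(x, ...) {
  cat(sprintf("som_cluster '%s': modules {%s}, %d genes\n", x$label,
              paste(x$module_ids, collapse = ", "),
              length(x$member_genes)))
  invisible(x)
}
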
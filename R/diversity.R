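#' Standardize a community count table
#'
#' Two standardizations are offered: `"relative"` divides each sample row by
#' its total (the default used throughout the pipeline), and `"rarefy"`
#' subsamples each row without replacement to a common depth.
#'
#' @param table Samples x taxa count matrix.
#' @param mode `"relative"` or `"rarefy"`.
#' @param depth Rarefaction depth; defaults to the minimum row sum.
#' @param seed Integer seed (required for `"rarefy"`).
#' @return Standardized matrix with attribute `standardized` set to the mode.
#' @export
standardize_table <- function(table, mode = c("relative", "rarefy"),
                              depth = NULL, seed = NULL) {
  mode <- match.arg(mode)
  rs <- rowSums(table)
  if (any(rs == 0)) stop_invalid("table has all-zero sample rows")
  if (mode == "relative") {
    out <- table / rs
  } else {
    if (is.null(depth)) depth <- min(rs)
    low <- rownames(table)[rs < depth]
    if (length(low) > 0L)
      stop_invalid(sprintf("rarefaction depth %d exceeds total reads of sample(s): %s",
                           as.integer(depth), paste(low, collapse = ", ")))
    if (any(table != round(table)))
      stop_invalid("rarefaction requires integer counts")
    if (!is.null(seed)) set.seed(seed)
    # rrarefy warns whenever every count exceeds the target depth; that is
    # exactly the intended use here
    out <- suppressWarnings(vegan::rrarefy(table, depth))
  }
  attr(out, "standardized") <- mode
  out
}

#' Hellinger transformation
#'
#' Replaces each entry by the square root of its within-sample relative
#' abundance, so each transformed row has unit Euclidean norm. The standard
#' pre-treatment before Euclidean-based ordination of abundance data.
#'
#' @param table Samples x taxa nonnegative matrix with positive row sums.
#' @return Transformed matrix.
#' @export
hellinger_transform <- function(table) {
  if (any(rowSums(table) == 0)) stop_invalid("table has all-zero sample rows")
  out <- vegan::decostand(table, method = "hellinger")
  out <- as.matrix(out)
  attr(out, "standardized") <- "hellinger"
  out
}

#' Alpha diversity: richness, Shannon index, and Faith's PD
#'
#' Richness is the count of taxa with nonzero abundance; the Shannon-Wiener
#' index is reported in natural-log units (nats); Faith's phylogenetic
#' diversity is the sum of branch lengths of the minimal subtree spanning
#' the taxa present in a sample. By default the path to the root is
#' included (`include_root = TRUE`).
#'
#' @param table Samples x taxa abundance matrix (counts or relative).
#' @param tree Optional `phylo` tree covering all table taxa (required for
#'   Faith's PD).
#' @param include_root Include the root path in Faith's PD (default `TRUE`).
#' @return A data.frame with columns `sample_id`, `richness`,
#'   `shannon_nats`, and (when a tree is supplied) `faith_pd`.
#' @export
alpha_diversity <- function(table, tree = NULL, include_root = TRUE) {
  out <- data.frame(
    sample_id = rownames(table),
    richness = as.integer(rowSums(table > 0)),
    shannon_nats = as.numeric(vegan::diversity(table, index = "shannon")),
    stringsAsFactors = FALSE
  )
  if (!is.null(tree)) {
    missing <- setdiff(colnames(table), tree$tip.label)
    if (length(missing) > 0L)
      stop_consist(sprintf("taxa absent from tree: %s",
                           paste(utils::head(missing, 5L), collapse = ", ")))
    pd <- picante::pd(1 * (table > 0), tree, include.root = include_root)
    out$faith_pd <- pd$PD
  }
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i), in `[0, 1]`.
#'
#' @param table Samples x taxa matrix with positive row sums.
#' @return Square symmetric matrix with zero diagonal, sample IDs as dimnames.
#' @export
bray_curtis_matrix <- function(table) {
  if (any(rowSums(table) == 0)) stop_invalid("table has all-zero sample rows")
  as.matrix(vegan::vegdist(table, method = "bray"))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower-centers `-0.5 * D^2` and eigendecomposes it. Coordinates are
#' returned only for positive eigenvalues and are scaled by the square root
#' of the eigenvalue, so Euclidean distances between coordinates reproduce
#' a Euclidean-embeddable input. Negative eigenvalues are counted and
#' reported, not corrected.
#'
#' @param dist Square symmetric distance matrix (zero diagonal).
#' @param n_axes Number of axes to return (capped at the number of positive
#'   eigenvalues).
#' @return List of class `ea_pcoa` with `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `proportion_explained` (per returned
#'   axis, relative to the sum of positive eigenvalues), and
#'   `n_negative_eigenvalues`.
#' @export
pcoa <- function(dist, n_axes = 2L) {
  check_dist(dist, "PCoA input")
  n <- nrow(dist)
  fit <- stats::cmdscale(stats::as.dist(dist), k = n - 1L, eig = TRUE)
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- sum(eig > 1e-12)
  k <- min(n_axes, pos)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    proportion_explained = if (k > 0) eig[seq_len(k)] / sum(eig[eig > 0]) else numeric(0),
    n_negative_eigenvalues = sum(eig < -1e-12 * max(abs(eig)))
  ), class = "ea_pcoa")
}

#' @export
print.ea_pcoa <- function(x, ...) {
  cat("Principal coordinates analysis\n")
  cat(sprintf("  samples: %d, axes returned: %d\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  if (length(x$proportion_explained) > 0)
    cat(sprintf("  proportion explained: %s\n",
                paste(sprintf("%.1f%%", 100 * x$proportion_explained), collapse = ", ")))
  cat(sprintf("  negative eigenvalues: %d\n", x$n_negative_eigenvalues))
  invisible(x)
}
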
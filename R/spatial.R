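#' Great-circle distance matrix between samples
#'
#' Haversine distances in kilometres between the sampling locations of all
#' samples, on a sphere of mean Earth radius 6371.0088 km.
#'
#' @param meta Metadata data.frame with columns `sample_id`, `lat`, `lon`.
#' @return Square symmetric matrix (km) keyed by sample ID.
#' @export
haversine_matrix <- function(meta) {
  for (col in c("lat", "lon")) {
    if (!col %in% names(meta)) stop_invalid(sprintf("metadata lacks column '%s'", col))
  }
  bad <- meta$sample_id[is.na(meta$lat) | is.na(meta$lon)]
  if (length(bad) > 0L)
    stop_invalid(sprintf("missing coordinates for sample(s): %s",
                         paste(bad, collapse = ", ")))
  pts <- cbind(meta$lon, meta$lat)
  m <- geosphere::distm(pts, fun = function(a, b)
    geosphere::distHaversine(a, b, r = 6371008.8)) / 1000
  dimnames(m) <- list(meta$sample_id, meta$sample_id)
  m
}

#' Environmental (Euclidean) distance matrix
#'
#' Each chosen variable is z-scored across the retained samples using the
#' sample (n-1) standard deviation, then pairwise Euclidean distances are
#' computed. Samples with missing values in any chosen variable are
#' excluded with a message.
#'
#' @param meta Metadata data.frame.
#' @param variables Character vector of metadata column names.
#' @return Square symmetric matrix keyed by the retained sample IDs.
#' @export
environmental_distance <- function(meta, variables) {
  if (length(variables) < 1L) stop_invalid("at least one variable is required")
  missing_cols <- setdiff(variables, names(meta))
  if (length(missing_cols) > 0L)
    stop_invalid(sprintf("metadata lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  x <- as.matrix(meta[, variables, drop = FALSE])
  keep <- stats::complete.cases(x)
  if (!all(keep))
    message("environmental_distance: excluded samples with missing values: ",
            paste(meta$sample_id[!keep], collapse = ", "))
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 2L) stop_invalid("fewer than two samples with complete data")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop_invalid(sprintf("zero-variance variable(s): %s",
                         paste(variables[sds == 0], collapse = ", ")))
  z <- scale(x, center = TRUE, scale = sds)
  m <- as.matrix(stats::dist(z, method = "euclidean"))
  dimnames(m) <- list(meta$sample_id[keep], meta$sample_id[keep])
  m
}

#' Distance-decay regression
#'
#' Ordinary least squares of community similarity (1 - dissimilarity, the
#' default) or dissimilarity on geographic (or environmental) distance over
#' the strict upper triangle of the two matrices. Pairs, not samples, are
#' the regression units; because pairs sharing a sample are not
#' independent, the reported p-value is anti-conservative and should be
#' read as descriptive.
#'
#' @param comm_dist Community dissimilarity matrix.
#' @param geo_dist Geographic (or environmental) distance matrix over the
#'   same samples.
#' @param response `"similarity"` (1 - dissimilarity; default) or
#'   `"distance"`.
#' @return List of class `ea_regression` with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n` (number of pairs), and `response`.
#' @export
distance_decay <- function(comm_dist, geo_dist,
                           response = c("similarity", "distance")) {
  response <- match.arg(response)
  check_dist(comm_dist, "community distance")
  check_dist(geo_dist, "geographic distance")
  if (!identical(rownames(comm_dist), rownames(geo_dist)))
    stop_consist("community and geographic matrices have different sample sets/orderings")
  if (nrow(comm_dist) < 4L) stop_invalid("at least 4 samples are required")
  y <- upper_vec(comm_dist)
  if (response == "similarity") y <- 1 - y
  x <- upper_vec(geo_dist)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits trigger an advisory warning
  p <- if (nrow(sm$coefficients) < 2L || sm$sigma == 0) {
    NA_real_
  } else {
    stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
              lower.tail = FALSE)
  }
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = sm$r.squared,
    p_value = unname(p),
    n = length(y),
    response = response
  ), class = "ea_regression")
}

#' @export
print.ea_regression <- function(x, ...) {
  cat(sprintf("Distance-decay OLS (%s ~ distance), %d pairs\n", x$response, x$n))
  cat(sprintf("  slope = %.4g, intercept = %.4g, R^2 = %.4f, p = %.4g\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strict upper triangles, with significance
#' from jointly permuting the rows and columns of the second matrix. The
#' default tail is upper one-sided (positive association);
#' `tail = "two-sided"` doubles-or-mirrors via |r|. With
#' `permutations = "exhaustive"` all n! relabelings are enumerated and the
#' p-value is the exact fraction (identity included).
#'
#' @param d1,d2 Distance matrices over the same samples.
#' @param n_perm Number of random permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @param tail `"upper"` (default) or `"two-sided"`.
#' @param permutations `"random"` (default) or `"exhaustive"` (n <= 8).
#' @return List of class `ea_mantel` with `r`, `p_value`, `n_permutations`,
#'   `tail`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = NULL,
                        tail = c("upper", "two-sided"),
                        permutations = c("random", "exhaustive")) {
  tail <- match.arg(tail)
  permutations <- match.arg(permutations)
  check_dist(d1, "d1"); check_dist(d2, "d2")
  if (!identical(rownames(d1), rownames(d2)))
    stop_consist("matrices have different sample sets/orderings")
  v1 <- upper_vec(d1); v2 <- upper_vec(d2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop_invalid("constant upper triangle: Mantel r is undefined")
  r_obs <- stats::cor(v1, v2)
  n <- nrow(d1)
  stat <- function(r) if (tail == "upper") r else abs(r)
  if (permutations == "exhaustive") {
    if (n > 8L) stop_invalid("exhaustive mode supports at most 8 samples")
    perms <- all_permutations(n)
    rs <- apply(perms, 1L, function(p) stats::cor(v1, upper_vec(d2[p, p])))
    p_val <- mean(stat(rs) >= stat(r_obs) - 1e-12)
    n_perm <- nrow(perms)
  } else {
    if (n_perm < 99L) stop_invalid("n_perm must be at least 99")
    if (!is.null(seed)) set.seed(seed)
    count <- 0L
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      r_b <- stats::cor(v1, upper_vec(d2[p, p]))
      if (stat(r_b) >= stat(r_obs) - 1e-12) count <- count + 1L
    }
    p_val <- (count + 1) / (n_perm + 1)
  }
  structure(list(r = r_obs, p_value = p_val, n_permutations = n_perm,
                 tail = tail), class = "ea_mantel")
}

#' @export
print.ea_mantel <- function(x, ...) {
  cat(sprintf("Mantel test (%s tail): r = %.4f, p = %.4g (%d permutations)\n",
              x$tail, x$r, x$p_value, x$n_permutations))
  invisible(x)
}
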
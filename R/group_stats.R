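#' Single-factor PERMANOVA
#'
#' Partitions a distance matrix into among- and within-group sums of
#' squares (Gower-centred inner-product decomposition; equivalently the
#' pairwise form SS_total = sum d^2 / n, SS_within = sum over groups of
#' within-group d^2 / n_g) and tests the pseudo-F statistic by permuting
#' group labels. `permutations = "exhaustive"` enumerates all n!
#' relabelings and returns the exact fraction (identity included);
#' otherwise the p-value uses the (count + 1)/(n_perm + 1) correction.
#'
#' @param dist Distance matrix keyed by sample ID.
#' @param grouping Named vector/factor of group labels (names = sample IDs),
#'   or an unnamed vector in matrix order.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed.
#' @param permutations `"random"` or `"exhaustive"` (n <= 8).
#' @return List of class `ea_permanova` with `pseudo_F`, `r_squared`,
#'   `p_value`, `df`, `n_permutations`, and `term` (the grouping name).
#' @export
permanova <- function(dist, grouping, n_perm = 999L, seed = NULL,
                      permutations = c("random", "exhaustive"),
                      term = "group") {
  permutations <- match.arg(permutations)
  check_dist(dist, "PERMANOVA input")
  n <- nrow(dist)
  if (!is.null(names(grouping))) {
    missing <- setdiff(rownames(dist), names(grouping))
    if (length(missing) > 0L)
      stop_consist(sprintf("grouping lacks sample(s): %s", paste(missing, collapse = ", ")))
    grouping <- grouping[rownames(dist)]
  } else if (length(grouping) != n) {
    stop_invalid("unnamed grouping must match the matrix dimension")
  }
  g <- factor(as.vector(grouping))
  if (nlevels(g) < 2L) stop_invalid("PERMANOVA needs at least two groups")
  if (any(table(g) < 2L)) stop_invalid("every group needs at least two samples")
  d2 <- dist^2
  ss_total <- sum(upper_vec(d2)) / n
  f_stat <- function(g) {
    ss_w <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ss_w <- ss_w + sum(upper_vec(d2[idx, idx, drop = FALSE])) / length(idx)
    }
    ss_a <- ss_total - ss_w
    a <- nlevels(g)
    (ss_a / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_stat(g)
  ss_w <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    ss_w <- ss_w + sum(upper_vec(d2[idx, idx, drop = FALSE])) / length(idx)
  }
  r2 <- (ss_total - ss_w) / ss_total
  if (permutations == "exhaustive") {
    if (n > 8L) stop_invalid("exhaustive mode supports at most 8 samples")
    perms <- all_permutations(n)
    fs <- apply(perms, 1L, function(p) f_stat(g[p]))
    p_val <- mean(fs >= f_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- 0L
    for (b in seq_len(n_perm)) {
      if (f_stat(g[sample.int(n)]) >= f_obs - 1e-12) count <- count + 1L
    }
    p_val <- (count + 1) / (n_perm + 1)
  }
  structure(list(pseudo_F = f_obs, r_squared = r2, p_value = p_val,
                 df = c(among = nlevels(g) - 1L, within = n - nlevels(g)),
                 n_permutations = n_perm, term = term),
            class = "ea_permanova")
}

#' @export
print.ea_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s): pseudo-F = %.4f, R^2 = %.4f, p = %.4g (%d permutations)\n",
              x$term, x$pseudo_F, x$r_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite (fractional)
#' degrees of freedom and a two-sided p-value.
#'
#' @param x,y Numeric vectors (each n >= 2).
#' @return List of class `ea_group_comparison` with `statistic`,
#'   `degrees_of_freedom`, `p_value`, and `group_means`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop_invalid("each group needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(structure(list(statistic = 0, degrees_of_freedom = length(x) + length(y) - 2,
                            p_value = 1, group_means = c(mean(x), mean(y)),
                            test = "welch_t"), class = "ea_group_comparison"))
    }
    stop_invalid("both groups have zero variance")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  structure(list(
    statistic = unname(ht$statistic),
    degrees_of_freedom = unname(ht$parameter),
    p_value = ht$p.value,
    group_means = unname(ht$estimate),
    test = "welch_t"
  ), class = "ea_group_comparison")
}

#' One-way ANOVA with Tukey-Kramer multiple comparisons
#'
#' Omnibus one-way ANOVA F-test followed by Tukey honest significant
#' difference pairwise comparisons (studentized range with the pooled
#' within-group variance; Tukey-Kramer for unbalanced designs).
#'
#' @param values Numeric response vector.
#' @param grouping Group labels, same length as `values`.
#' @param alpha Family-wise level used for the Tukey intervals (default 0.05).
#' @return List of class `ea_group_comparison` with `statistic` (F),
#'   `degrees_of_freedom` (c(between, within)), `p_value`, `group_means`,
#'   and `tukey` (data.frame: pair, diff, p_adj).
#' @export
anova_tukey <- function(values, grouping, alpha = 0.05) {
  g <- factor(grouping)
  if (any(table(g) < 1L) || nlevels(g) < 2L)
    stop_invalid("need >= 2 non-empty groups")
  if (any(table(g) < 2L)) stop_invalid("every group needs at least two values")
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  structure(list(
    statistic = an[["F value"]][1L],
    degrees_of_freedom = an[["Df"]],
    p_value = an[["Pr(>F)"]][1L],
    group_means = tapply(values, g, mean),
    tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL,
                       stringsAsFactors = FALSE),
    test = "anova_tukey"
  ), class = "ea_group_comparison")
}

#' @export
print.ea_group_comparison <- function(x, ...) {
  if (x$test == "welch_t") {
    cat(sprintf("Welch t-test: t = %.4f, df = %.3f, p = %.4g\n",
                x$statistic, x$degrees_of_freedom, x$p_value))
  } else {
    cat(sprintf("One-way ANOVA: F = %.4f (df %d, %d), p = %.4g\n",
                x$statistic, x$degrees_of_freedom[1L], x$degrees_of_freedom[2L],
                x$p_value))
    if (!is.null(x$tukey)) {
      cat("Tukey pairwise comparisons:\n")
      print(x$tukey, digits = 4)
    }
  }
  invisible(x)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors, n >= 3, nonconstant.
#' @return List with `r` and `p_value` (two-sided).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y lengths differ")
  if (length(x) < 3L) stop_invalid("n >= 3 required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_invalid("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Diel coefficient of variation per depth and unit
#'
#' For repeated (time-point) sampling at fixed depths, computes for every
#' depth and taxonomic/functional unit the coefficient of variation
#' (sample sd / mean) of relative abundance across time points. Units with
#' zero mean at a depth are reported as `NA` (undefined), not 0. Depths
#' with a single time point are excluded with a warning.
#'
#' @param table Samples x units relative-abundance matrix (rows sum to 1;
#'   aggregate taxa to orders or functional groups first, e.g. with
#'   [group_relative_abundance()]).
#' @param meta Metadata with `sample_id`, `depth_m`, and `time_point`.
#' @return Long data.frame with columns `depth_m`, `unit`, `cv`,
#'   `n_time_points`.
#' @export
diel_cv <- function(table, meta) {
  for (col in c("sample_id", "depth_m", "time_point")) {
    if (!col %in% names(meta)) stop_invalid(sprintf("metadata lacks column '%s'", col))
  }
  meta <- meta[meta$sample_id %in% rownames(table), , drop = FALSE]
  out <- list()
  for (d in sort(unique(meta$depth_m))) {
    ids <- meta$sample_id[meta$depth_m == d]
    if (length(unique(meta$time_point[meta$depth_m == d])) < 2L) {
      warning(sprintf("depth %g has a single time point; excluded", d), call. = FALSE)
      next
    }
    sub <- table[ids, , drop = FALSE]
    mu <- colMeans(sub)
    s <- apply(sub, 2L, stats::sd)
    cv <- ifelse(mu > 0, s / mu, NA_real_)
    out[[length(out) + 1L]] <- data.frame(
      depth_m = d, unit = colnames(sub), cv = unname(cv),
      n_time_points = length(ids), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop_invalid("no depth has >= 2 time points")
  do.call(rbind, out)
}

#' Assign trophic functional groups from taxonomy strings
#'
#' Each taxon's taxonomy is a vector of rank names from coarse to fine.
#' The deepest (finest) rank with a lookup entry wins; taxa with no match
#' are assigned `"unknown"`.
#'
#' @param taxonomy Named list: taxon ID -> character vector of rank names
#'   (coarse to fine).
#' @param lookup Named character vector token -> group (see
#'   [read_functional_lookup()]).
#' @return Named character vector taxon -> group.
#' @export
assign_trophic_groups <- function(taxonomy, lookup) {
  if (length(lookup) == 0L) stop_invalid("empty functional lookup")
  vapply(taxonomy, function(ranks) {
    hit <- "unknown"
    for (r in ranks) {           # coarse -> fine: last match is deepest
      if (r %in% names(lookup)) hit <- unname(lookup[[r]])
    }
    hit
  }, character(1L))
}

#' Aggregate a standardized table to functional-group relative abundances
#'
#' @param table Samples x taxa relative-abundance matrix.
#' @param mapping Named character vector taxon -> group. Taxa absent from
#'   the mapping are assigned `"unknown"` with a message.
#' @return Samples x groups matrix; rows sum to the original row sums.
#' @export
group_relative_abundance <- function(table, mapping) {
  taxa <- colnames(table)
  unmapped <- setdiff(taxa, names(mapping))
  if (length(unmapped) > 0L) {
    message("group_relative_abundance: unmapped taxa assigned 'unknown': ",
            paste(utils::head(unmapped, 5L), collapse = ", "),
            if (length(unmapped) > 5L) ", ..." else "")
    mapping <- c(mapping, stats::setNames(rep("unknown", length(unmapped)), unmapped))
  }
  grp <- factor(mapping[taxa])
  out <- sapply(levels(grp), function(lev)
    rowSums(table[, grp == lev, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                       dimnames = list(rownames(table), levels(grp)))
  out
}
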
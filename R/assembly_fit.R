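#' Infer community assembly processes from a count table and tree
#'
#' The package's main entry point. Runs the full null-model inference on a
#' samples x taxa count table and its phylogeny: abundance-weighted
#' betaMNTD and its tip-shuffle z-score (betaNTI, computed on the
#' relative-abundance table), abundance-based Raup-Crick (computed on the
#' raw counts), per-pair process classification, and per-stratum process
#' fractions (entire / euphotic / aphotic when metadata with an
#' `irradiance_zone` column is supplied).
#'
#' @param table Samples x taxa integer count matrix.
#' @param tree `phylo` tree covering the table's taxa.
#' @param meta Optional metadata (`sample_id`, `irradiance_zone`, ...).
#' @param n_null Null replicates for both null models (default 999).
#' @param seed Integer seed. The betaNTI null stream uses `seed`, the
#'   Raup-Crick stream `seed + 1`.
#' @param abundance_weighted Abundance weighting for betaMNTD (default
#'   `TRUE`).
#' @return An object of class `assembly_fit` with components `pairs` (the
#'   per-pair classification), `fractions`, `bnti`, `rc`, `bmntd`,
#'   `n_null`, `seed`, `call`.
#' @seealso [bnti_matrix()], [rc_bray_matrix()], [classify_assembly()]
#' @examples
#' tree <- simulate_yule_tree(20, seed = 1)
#' traits <- simulate_bm_traits(tree, 1, seed = 2)
#' meta <- simulate_transect_metadata(3, c(20, 200, 500), seed = 3)
#' spec <- scenario_spec("drift", n_taxa = 20, n_sites = 9,
#'                       reads_per_sample = 500, seed = 4)
#' tab <- simulate_metacommunity(spec, tree, traits, meta)
#' fit <- community_assembly(tab, tree, meta, n_null = 99, seed = 5)
#' fit
#' @export
community_assembly <- function(table, tree, meta = NULL, n_null = 999L,
                               seed = 1L, abundance_weighted = TRUE) {
  if (nrow(table) < 2L) stop_invalid("at least two samples are required")
  aligned <- align_inputs(table, tree, meta)
  tab <- aligned$table
  bnti <- bnti_matrix(tab, aligned$tree, n_null = n_null, seed = seed,
                      abundance_weighted = abundance_weighted)
  rc <- rc_bray_matrix(tab, n_null = n_null, seed = seed + 1L)
  pairs <- classify_assembly(bnti, rc)
  strata <- NULL
  if (!is.null(aligned$meta) && "irradiance_zone" %in% names(aligned$meta)) {
    strata <- pair_strata(pairs, aligned$meta)
    pairs$stratum <- strata
  }
  structure(list(
    pairs = pairs,
    fractions = summarize_process_fractions(pairs, strata),
    bnti = bnti,
    rc = rc,
    bmntd = attr(bnti, "bmntd_obs"),
    n_null = n_null,
    seed = seed,
    abundance_weighted = abundance_weighted,
    call = match.call()
  ), class = "assembly_fit")
}

#' @export
print.assembly_fit <- function(x, ...) {
  cat("Community assembly null-model inference\n")
  cat(sprintf("  %d samples, %d pairs, n_null = %d, seed = %d\n",
              nrow(x$bnti), nrow(x$pairs), x$n_null, x$seed))
  tab <- x$fractions[x$fractions$stratum == "entire", ]
  cat("  process fractions (entire):\n")
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("    %-22s %6.1f%%\n", tab$process[i], 100 * tab$fraction[i]))
  }
  if (tab$n_excluded[1L] > 0L)
    cat(sprintf("  pairs excluded (non-finite betaNTI): %d\n", tab$n_excluded[1L]))
  invisible(x)
}

#' @export
summary.assembly_fit <- function(object, ...) {
  structure(list(
    fractions = object$fractions,
    bnti_range = range(object$pairs$bnti, na.rm = TRUE),
    rc_range = range(object$pairs$rc),
    n_pairs = nrow(object$pairs),
    n_excluded = sum(is.na(object$pairs$process)),
    n_null = object$n_null
  ), class = "summary.assembly_fit")
}

#' @export
print.summary.assembly_fit <- function(x, ...) {
  cat("Assembly process fractions by stratum\n")
  print(x$fractions, digits = 3, row.names = FALSE)
  cat(sprintf("betaNTI range: [%.2f, %.2f]; RC range: [%.2f, %.2f]\n",
              x$bnti_range[1L], x$bnti_range[2L], x$rc_range[1L], x$rc_range[2L]))
  invisible(x)
}

#' @export
as.data.frame.assembly_fit <- function(x, ...) x$pairs

#' Plot an assembly fit
#'
#' Scatter of per-pair betaNTI against Raup-Crick with the classification
#' thresholds (betaNTI = +/-2, RC = +/-0.95) drawn as reference lines.
#'
#' @param x An `assembly_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.assembly_fit <- function(x, ...) {
  ok <- !is.na(x$pairs$bnti)
  cols <- c(variable_selection = "#D55E00", homogeneous_selection = "#0072B2",
            dispersal_limitation = "#009E73", homogenizing_dispersal = "#CC79A7",
            undominated = "grey50")
  graphics::plot(x$pairs$rc[ok], x$pairs$bnti[ok],
                 col = cols[as.character(x$pairs$process[ok])], pch = 19,
                 xlab = "Raup-Crick (RC)", ylab = expression(beta * "NTI"),
                 xlim = c(-1, 1), ...)
  graphics::abline(h = c(-2, 2), lty = 2, col = "grey40")
  graphics::abline(v = c(-0.95, 0.95), lty = 3, col = "grey40")
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 19,
                   cex = 0.7, bty = "n")
  invisible(x)
}
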
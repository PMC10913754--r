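# Core null-model machinery: betaMNTD, betaNTI (tip-shuffle null),
# abundance-based Raup-Crick, and the process classification.

# betaMNTD for one sample pair.
# D: taxa x taxa patristic distances; pk/pm: indices of taxa present;
# wk/wm: relative-abundance weights over pk/pm (sum 1); tp: permutation
# mapping taxon index -> tip index (identity for the observed value).
bmntd_pair <- function(D, pk, pm, wk, wm, tp = NULL) {
  ik <- if (is.null(tp)) pk else tp[pk]
  im <- if (is.null(tp)) pm else tp[pm]
  sub <- D[ik, im, drop = FALSE]
  dk <- sub[cbind(seq_along(ik), max.col(-sub, ties.method = "first"))]
  tsub <- t(sub)
  dm <- tsub[cbind(seq_along(im), max.col(-tsub, ties.method = "first"))]
  0.5 * sum(wk * dk) + 0.5 * sum(wm * dm)
}

# Presence indices and weights for every sample of a relative-abundance table.
bmntd_prep <- function(rel) {
  lapply(seq_len(nrow(rel)), function(i) {
    p <- which(rel[i, ] > 0)
    if (length(p) == 0L) stop_invalid(sprintf("sample '%s' has zero taxa", rownames(rel)[i]))
    list(p = p, w = rel[i, p] / sum(rel[i, p]))
  })
}

#' Pairwise beta mean nearest taxon distance (betaMNTD)
#'
#' For each sample pair (k, m), the abundance-weighted mean over the taxa
#' of each community of the patristic distance to the closest relative in
#' the other community, averaged over the two directions:
#' betaMNTD = 1/2 sum_i f_ik min_j d_ij + 1/2 sum_j f_jm min_i d_ij.
#' With `abundance_weighted = FALSE` taxa get uniform weights 1/S.
#'
#' @param table Samples x taxa abundance matrix (standardized to relative
#'   abundance internally).
#' @param tree `phylo` tree whose tips cover the table's taxa.
#' @param abundance_weighted Weight by relative abundance (default `TRUE`).
#' @return Symmetric samples x samples matrix with zero diagonal, plus the
#'   attribute `abundance_weighted`.
#' @export
pairwise_bmntd <- function(table, tree, abundance_weighted = TRUE) {
  miss <- setdiff(colnames(table), tree$tip.label)
  if (length(miss) > 0L)
    stop_consist(sprintf("taxa absent from tree: %s",
                         paste(utils::head(miss, 5L), collapse = ", ")))
  D <- ape::cophenetic.phylo(tree)[colnames(table), colnames(table)]
  rel <- table / rowSums(table)
  if (!abundance_weighted) rel <- 1 * (rel > 0)
  prep <- bmntd_prep(rel)
  n <- nrow(table)
  out <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (k in seq_len(n - 1L)) for (m in seq.int(k + 1L, n)) {
    v <- bmntd_pair(D, prep[[k]]$p, prep[[m]]$p, prep[[k]]$w, prep[[m]]$w)
    out[k, m] <- out[m, k] <- v
  }
  attr(out, "abundance_weighted") <- abundance_weighted
  out
}

#' Beta nearest taxon index (betaNTI)
#'
#' z-score of the observed betaMNTD against a null distribution obtained
#' by shuffling taxon labels across all tips of the tree (the regional
#' pool). One joint tip permutation per null replicate is shared across
#' all sample pairs, which preserves the correlation structure of the null
#' across pairs; set `joint_permutation = FALSE` for per-pair independent
#' shuffles. Pairs whose null standard deviation is zero (e.g. a star-like
#' tree with constant distances) are flagged `NA` with a message.
#'
#' @inheritParams pairwise_bmntd
#' @param n_null Number of null replicates (>= 99; default 999).
#' @param seed Integer seed; the permutation for replicate r is drawn from
#'   a stream advanced deterministically from this seed.
#' @param joint_permutation Share one tip permutation per replicate across
#'   all pairs (default `TRUE`).
#' @return Symmetric matrix of betaNTI z-scores (attributes: `bmntd_obs`
#'   matrix, `n_null`, `seed`, `n_flagged`).
#' @export
bnti_matrix <- function(table, tree, n_null = 999L, seed = 1L,
                        abundance_weighted = TRUE, joint_permutation = TRUE) {
  if (n_null < 99L) stop_invalid("n_null must be at least 99")
  miss <- setdiff(colnames(table), tree$tip.label)
  if (length(miss) > 0L)
    stop_consist(sprintf("taxa absent from tree: %s",
                         paste(utils::head(miss, 5L), collapse = ", ")))
  D <- ape::cophenetic.phylo(tree)[colnames(table), colnames(table)]
  rel <- table / rowSums(table)
  if (!abundance_weighted) rel <- 1 * (rel > 0)
  prep <- bmntd_prep(rel)
  n <- nrow(table)
  t_n <- ncol(table)
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  obs <- vapply(seq_len(np), function(q)
    bmntd_pair(D, prep[[pairs[1L, q]]]$p, prep[[pairs[2L, q]]]$p,
               prep[[pairs[1L, q]]]$w, prep[[pairs[2L, q]]]$w), numeric(1L))
  set.seed(seed)
  null <- matrix(0, np, n_null)
  for (r in seq_len(n_null)) {
    if (joint_permutation) {
      tp <- sample.int(t_n)
      for (q in seq_len(np)) {
        null[q, r] <- bmntd_pair(D, prep[[pairs[1L, q]]]$p, prep[[pairs[2L, q]]]$p,
                                 prep[[pairs[1L, q]]]$w, prep[[pairs[2L, q]]]$w, tp)
      }
    } else {
      for (q in seq_len(np)) {
        tp <- sample.int(t_n)
        null[q, r] <- bmntd_pair(D, prep[[pairs[1L, q]]]$p, prep[[pairs[2L, q]]]$p,
                                 prep[[pairs[1L, q]]]$w, prep[[pairs[2L, q]]]$w, tp)
      }
    }
  }
  mu <- rowMeans(null)
  sdv <- apply(null, 1L, stats::sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  n_flagged <- sum(sdv == 0)
  if (n_flagged > 0L)
    message(sprintf("bnti_matrix: %d pair(s) with zero null sd flagged NA", n_flagged))
  out <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  bm <- out
  for (q in seq_len(np)) {
    out[pairs[1L, q], pairs[2L, q]] <- out[pairs[2L, q], pairs[1L, q]] <- z[q]
    bm[pairs[1L, q], pairs[2L, q]] <- bm[pairs[2L, q], pairs[1L, q]] <- obs[q]
  }
  attr(out, "bmntd_obs") <- bm
  attr(out, "n_null") <- n_null
  attr(out, "seed") <- seed
  attr(out, "n_flagged") <- n_flagged
  out
}

# One null community under the Raup-Crick assembly model: draw `richness`
# species without replacement with probability proportional to regional
# occupancy, give each one read, then distribute the remaining reads
# multinomially proportional to regional relative abundance over the drawn
# species.
rc_null_sample <- function(n_taxa, richness, reads, occupancy, rel_abund) {
  s <- sample.int(n_taxa, richness, replace = FALSE, prob = occupancy)
  cnt <- integer(n_taxa)
  cnt[s] <- 1L
  if (reads > richness) {
    cnt[s] <- cnt[s] + stats::rmultinom(1L, reads - richness, rel_abund[s])[, 1L]
  }
  cnt
}

bray_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)

#' Abundance-based Raup-Crick beta diversity (RC-Bray)
#'
#' For each sample pair, the observed Bray-Curtis dissimilarity is located
#' within a null distribution of dissimilarities between communities
#' reassembled at random while preserving each sample's richness and read
#' total: species are drawn without replacement with probability
#' proportional to regional occupancy, then reads are distributed
#' proportional to regional relative abundance over the drawn species.
#' RC = ((n_less + n_equal/2) / n_null - 0.5) * 2, bounded in `[-1, 1]`;
#' ties count half.
#'
#' `method = "exact"` replaces Monte-Carlo sampling with exhaustive
#' enumeration of the null outcome distribution; it is restricted to tiny
#' problems in which every sample's read total equals its richness (no
#' multinomial stage) and is intended for verification.
#'
#' @param table Samples x taxa matrix of integer counts.
#' @param n_null Null replicates (>= 99; default 999). Ignored for
#'   `method = "exact"`.
#' @param seed Integer seed.
#' @param method `"sample"` (Monte-Carlo, default) or `"exact"`.
#' @param occupancy,rel_abund Optional regional profile (per-taxon
#'   occupancy fraction and relative abundance) to use for the null
#'   assembly instead of estimating both from `table` -- for calibration
#'   studies or when a larger reference data set defines the pool.
#' @return Symmetric matrix of RC values in `[-1, 1]` (attributes `n_null`,
#'   `seed`, `method`).
#' @export
rc_bray_matrix <- function(table, n_null = 999L, seed = 1L,
                           method = c("sample", "exact"),
                           occupancy = NULL, rel_abund = NULL) {
  method <- match.arg(method)
  if (any(table != round(table)) || any(table < 0))
    stop_invalid("Raup-Crick requires the raw nonnegative integer count table")
  storage.mode(table) <- "integer"
  n <- nrow(table); t_n <- ncol(table)
  if (is.null(occupancy)) occupancy <- colMeans(table > 0)
  if (is.null(rel_abund)) rel_abund <- colSums(table) / sum(table)
  if (length(occupancy) != t_n || length(rel_abund) != t_n)
    stop_consist("regional profile length does not match the number of taxa")
  richness <- rowSums(table > 0)
  reads <- rowSums(table)
  out <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  eps <- 1e-9
  if (method == "exact") {
    if (t_n > 8L || any(reads != richness))
      stop_invalid("exact mode requires <= 8 taxa and read totals equal to richness")
    dists <- lapply(seq_len(n), function(i)
      rc_exact_distribution(t_n, richness[i], occupancy))
    for (k in seq_len(n - 1L)) for (m in seq.int(k + 1L, n)) {
      obs <- bray_pair(table[k, ], table[m, ])
      p_less <- 0; p_eq <- 0
      for (a in seq_along(dists[[k]]$prob)) for (b in seq_along(dists[[m]]$prob)) {
        bc <- bray_pair(dists[[k]]$counts[a, ], dists[[m]]$counts[b, ])
        pr <- dists[[k]]$prob[a] * dists[[m]]$prob[b]
        if (bc < obs - eps) p_less <- p_less + pr
        else if (abs(bc - obs) <= eps) p_eq <- p_eq + pr
      }
      out[k, m] <- out[m, k] <- ((p_less + 0.5 * p_eq) - 0.5) * 2
    }
    attr(out, "n_null") <- Inf
  } else {
    if (n_null < 99L) stop_invalid("n_null must be at least 99")
    set.seed(seed)
    for (k in seq_len(n - 1L)) for (m in seq.int(k + 1L, n)) {
      obs <- bray_pair(table[k, ], table[m, ])
      n_less <- 0L; n_eq <- 0L
      for (r in seq_len(n_null)) {
        xk <- rc_null_sample(t_n, richness[k], reads[k], occupancy, rel_abund)
        xm <- rc_null_sample(t_n, richness[m], reads[m], occupancy, rel_abund)
        bc <- bray_pair(xk, xm)
        if (bc < obs - eps) n_less <- n_less + 1L
        else if (abs(bc - obs) <= eps) n_eq <- n_eq + 1L
      }
      out[k, m] <- out[m, k] <- ((n_less + 0.5 * n_eq) / n_null - 0.5) * 2
    }
    attr(out, "n_null") <- n_null
  }
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  out
}

# Exact distribution of a Raup-Crick null community when reads == richness:
# enumerate ordered without-replacement draws proportional to occupancy and
# collapse to unordered occupancy sets.
rc_exact_distribution <- function(n_taxa, richness, occupancy) {
  sets <- utils::combn(n_taxa, richness)
  probs <- numeric(ncol(sets))
  for (j in seq_len(ncol(sets))) {
    s <- sets[, j]
    perms <- all_permutations(length(s))
    p_set <- 0
    for (r in seq_len(nrow(perms))) {
      ord <- s[perms[r, ]]
      p <- 1; rem <- sum(occupancy)
      for (i in ord) {
        p <- p * occupancy[i] / rem
        rem <- rem - occupancy[i]
      }
      p_set <- p_set + p
    }
    probs[j] <- p_set
  }
  counts <- matrix(0L, ncol(sets), n_taxa)
  for (j in seq_len(ncol(sets))) counts[j, sets[, j]] <- 1L
  list(counts = counts, prob = probs / sum(probs))
}

#' Classify sample pairs into assembly processes
#'
#' Applies the standard betaNTI / Raup-Crick decision rule per pair:
#' betaNTI > +2 -> variable selection; betaNTI < -2 -> homogeneous
#' selection; otherwise RC > +0.95 -> dispersal limitation; RC < -0.95 ->
#' homogenizing dispersal; otherwise undominated. All inequalities are
#' strict, so boundary values (betaNTI exactly +/-2, RC exactly +/-0.95)
#' fall through to the stochastic / undominated side. Pairs with a
#' non-finite betaNTI are classified `NA` and excluded from downstream
#' fraction denominators.
#'
#' @param bnti betaNTI matrix (from [bnti_matrix()]).
#' @param rc RC matrix (from [rc_bray_matrix()]) over the same samples.
#' @return Long data.frame with columns `sample_a`, `sample_b`, `bnti`,
#'   `rc`, `process` (factor over the five processes, `NA` when excluded).
#' @export
classify_assembly <- function(bnti, rc) {
  if (!identical(dimnames(bnti), dimnames(rc)))
    stop_consist("betaNTI and RC matrices cover different sample pairs")
  n <- nrow(bnti)
  pairs <- utils::combn(n, 2L)
  b <- bnti[t(pairs)]
  r <- rc[t(pairs)]
  proc <- ifelse(is.na(b), NA_character_,
          ifelse(b > 2, "variable_selection",
          ifelse(b < -2, "homogeneous_selection",
          ifelse(r > 0.95, "dispersal_limitation",
          ifelse(r < -0.95, "homogenizing_dispersal", "undominated")))))
  n_excluded <- sum(is.na(b))
  if (n_excluded > 0L)
    message(sprintf("classify_assembly: %d pair(s) with non-finite betaNTI excluded", n_excluded))
  data.frame(
    sample_a = rownames(bnti)[pairs[1L, ]],
    sample_b = rownames(bnti)[pairs[2L, ]],
    bnti = b, rc = r,
    process = factor(proc, levels = assembly_processes()),
    stringsAsFactors = FALSE
  )
}

#' The five assembly process labels
#' @return Character vector of the closed label set.
#' @export
assembly_processes <- function() {
  c("variable_selection", "homogeneous_selection", "dispersal_limitation",
    "homogenizing_dispersal", "undominated")
}

#' Stratify sample pairs by irradiance zone
#'
#' A pair is "euphotic" if both samples are photic, "aphotic" if both are
#' aphotic, and "mixed" otherwise; mixed pairs count only toward the
#' entire-data-set summary.
#'
#' @param result Classification data.frame from [classify_assembly()].
#' @param meta Metadata with `sample_id` and `irradiance_zone`
#'   ("photic"/"aphotic").
#' @return Character vector of strata aligned to `result` rows.
#' @export
pair_strata <- function(result, meta) {
  z <- stats::setNames(meta$irradiance_zone, meta$sample_id)
  za <- unname(z[result$sample_a]); zb <- unname(z[result$sample_b])
  ifelse(za == "photic" & zb == "photic", "euphotic",
  ifelse(za == "aphotic" & zb == "aphotic", "aphotic", "mixed"))
}

#' Per-stratum fractions of assembly processes
#'
#' @param result Classification data.frame from [classify_assembly()].
#' @param strata Optional character vector (one entry per pair). The
#'   summary always includes an `"entire"` stratum covering every pair;
#'   additional rows are produced per stratum level except `"mixed"`,
#'   which contributes to `"entire"` only.
#' @return Data.frame with columns `stratum`, `process`, `fraction`,
#'   `n_pairs` (classified pairs in the stratum), `n_excluded`.
#' @export
summarize_process_fractions <- function(result, strata = NULL) {
  one <- function(sub, name) {
    ok <- !is.na(sub$process)
    n_ok <- sum(ok)
    frac <- if (n_ok > 0) {
      as.numeric(table(sub$process[ok])) / n_ok
    } else {
      rep(NA_real_, length(assembly_processes()))
    }
    data.frame(stratum = name, process = assembly_processes(),
               fraction = frac, n_pairs = n_ok,
               n_excluded = sum(!ok), stringsAsFactors = FALSE)
  }
  out <- list(one(result, "entire"))
  if (!is.null(strata)) {
    if (length(strata) != nrow(result))
      stop_consist("strata length does not match number of pairs")
    for (s in setdiff(unique(strata), "mixed")) {
      out[[length(out) + 1L]] <- one(result[strata == s, , drop = FALSE], s)
    }
  }
  do.call(rbind, out)
}
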
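#' Read a community abundance table
#'
#' Reads a tab-separated samples x taxa abundance table. The first column
#' holds sample IDs and the header row holds taxon IDs. Rows are assumed to
#' be samples; set `orientation = "auto"` to transpose when the file clearly
#' has taxa as rows (more rows than columns and row IDs matching a supplied
#' taxon set is not attempted -- auto only compares dimensions).
#'
#' @param path Path to a TSV file.
#' @param orientation `"samples"` (default; rows are samples) or `"auto"`.
#' @return A numeric matrix (samples x taxa) with sample IDs as rownames and
#'   taxon IDs as colnames. The attribute `standardized` is `FALSE` for a
#'   freshly read table.
#' @export
read_community_table <- function(path, orientation = c("samples", "auto")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop_format("community table needs an ID column plus at least one taxon column")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop_format(sprintf("duplicate sample ID '%s' in %s",
                        ids[duplicated(ids)][1L], path))
  if (anyDuplicated(names(raw)[-1L]))
    stop_format(sprintf("duplicate taxon ID '%s' in %s",
                        names(raw)[-1L][duplicated(names(raw)[-1L])][1L], path))
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2L, as.numeric))) & !is.na(mat),
                 arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop_format(sprintf("non-numeric cell at sample '%s', taxon '%s'",
                          ids[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]]))
    mat <- apply(mat, 2L, as.numeric)
  }
  rownames(mat) <- ids
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop_format(sprintf("negative abundance at sample '%s', taxon '%s'",
                        rownames(mat)[neg[1L, 1L]], colnames(mat)[neg[1L, 2L]]))
  if (orientation == "auto" && nrow(mat) > ncol(mat)) {
    mat <- t(mat)
  }
  zero <- rownames(mat)[rowSums(mat) == 0]
  if (length(zero) > 0L)
    stop_format(sprintf("all-zero sample row(s): %s", paste(zero, collapse = ", ")))
  attr(mat, "standardized") <- FALSE
  mat
}

#' Write a community table to TSV
#'
#' @param table Samples x taxa matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phylogenetic tree from a Newick file
#'
#' The tree is treated as rooted-as-written; no re-rooting is applied.
#' Branch lengths are required. Zero-length branches and single-tip trees
#' are accepted with a warning; polytomies are permitted.
#'
#' @param path Path to a single-tree Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop_format(sprintf("Newick parse error in %s: %s",
                                                           path, conditionMessage(e))))
  if (is.null(tree)) stop_format(sprintf("Newick parse error in %s", path))
  if (inherits(tree, "multiPhylo")) stop_format("expected a single tree")
  if (is.null(tree$edge.length))
    stop_format("tree has no branch lengths; a tree with branch lengths is required")
  if (length(tree$tip.label) == 1L)
    warning("single-tip tree", call. = FALSE)
  if (any(tree$edge.length == 0))
    warning("tree contains zero-length branches", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop_format("tree contains negative branch lengths")
  tree
}

#' Read sample metadata from TSV
#'
#' Required columns: `sample_id` and `depth_m`. All other columns are
#' optional; blank environmental cells are preserved as `NA`, never coerced
#' to zero.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data.frame keyed by `sample_id`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  validate_sample_metadata(df)
}

#' Validate a sample metadata table
#'
#' @param df A data.frame with at least `sample_id` and `depth_m` columns.
#' @return The validated data.frame (invisibly identical content).
#' @export
validate_sample_metadata <- function(df) {
  for (col in c("sample_id", "depth_m")) {
    if (!col %in% names(df))
      stop_format(sprintf("metadata is missing required column '%s'", col))
  }
  if (anyDuplicated(df$sample_id))
    stop_format(sprintf("duplicate sample ID '%s' in metadata",
                        df$sample_id[duplicated(df$sample_id)][1L]))
  if (any(!is.na(df$depth_m) & df$depth_m <= 0))
    stop_format("depth_m must be positive")
  if ("lat" %in% names(df) && any(!is.na(df$lat) & abs(df$lat) > 90))
    stop_format("latitude outside [-90, 90]")
  if ("lon" %in% names(df) && any(!is.na(df$lon) & abs(df$lon) > 180))
    stop_format("longitude outside [-180, 180]")
  rownames(df) <- df$sample_id
  df
}

#' Write sample metadata to TSV
#' @param meta Metadata data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy-to-trophic-group lookup table
#'
#' Two-column TSV: `token` (a taxonomy rank name, e.g. "Syndiniales") and
#' `group` (one of autotroph, mixotroph, parasite, osmotroph, phagotroph,
#' heterotroph, unknown).
#'
#' @param path Path to the lookup TSV.
#' @return Named character vector token -> group.
#' @export
read_functional_lookup <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("token", "group") %in% names(df)))
    stop_format("lookup needs columns 'token' and 'group'")
  if (anyDuplicated(df$token))
    stop_format("duplicate tokens in functional lookup")
  groups <- c("autotroph", "mixotroph", "parasite", "osmotroph",
              "phagotroph", "heterotroph", "unknown")
  bad <- setdiff(unique(df$group), groups)
  if (length(bad) > 0L)
    stop_format(sprintf("unknown trophic group(s): %s", paste(bad, collapse = ", ")))
  stats::setNames(df$group, df$token)
}

#' Align a community table, tree, and metadata to a common ID set
#'
#' Restricts the table to samples present in the metadata and to taxa
#' present in the tree, prunes the tree to the table's taxa, and reorders
#' all three objects to shared orderings. Dropped samples/taxa are reported
#' via `message()` so runs leave an audit trail.
#'
#' @param table Samples x taxa matrix.
#' @param tree `phylo` tree over (a superset of) the table's taxa.
#' @param meta Metadata data.frame with `sample_id`.
#' @return A list with elements `table`, `tree`, `meta`, plus `dropped_taxa`
#'   and `dropped_samples` character vectors.
#' @export
align_inputs <- function(table, tree, meta = NULL) {
  taxa <- intersect(colnames(table), tree$tip.label)
  if (length(taxa) == 0L)
    stop_consist("no taxa shared between community table and tree")
  dropped_taxa <- union(setdiff(colnames(table), taxa),
                        setdiff(tree$tip.label, taxa))
  samples <- rownames(table)
  dropped_samples <- character(0)
  if (!is.null(meta)) {
    samples <- intersect(rownames(table), meta$sample_id)
    if (length(samples) == 0L)
      stop_consist("no samples shared between community table and metadata")
    dropped_samples <- union(setdiff(rownames(table), samples),
                             setdiff(meta$sample_id, samples))
  }
  if (length(dropped_taxa) > 0L)
    message("align_inputs: dropped taxa: ", paste(sort(dropped_taxa), collapse = ", "))
  if (length(dropped_samples) > 0L)
    message("align_inputs: dropped samples: ", paste(sort(dropped_samples), collapse = ", "))
  tab <- table[samples, taxa, drop = FALSE]
  tr <- if (length(taxa) < length(tree$tip.label)) {
    ape::keep.tip(tree, taxa)
  } else {
    tree
  }
  # order table columns by tree tip order for a stable shared ordering
  tab <- tab[, tr$tip.label, drop = FALSE]
  out <- list(table = tab, tree = tr,
              meta = if (is.null(meta)) NULL else
                meta[match(samples, meta$sample_id), , drop = FALSE],
              dropped_taxa = sort(dropped_taxa),
              dropped_samples = sort(dropped_samples))
  out
}
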
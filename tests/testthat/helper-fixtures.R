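# Shared fixtures built in code.

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

toy_table <- function() {
  m <- rbind(s1 = c(A = 1, B = 2, C = 3),
             s2 = c(A = 2, B = 0, C = 1),
             s3 = c(A = 0, B = 1, C = 4))
  m
}

toy_meta <- function(n = 3) {
  data.frame(
    sample_id = paste0("s", seq_len(n)),
    station = paste0("st", rep_len(1:2, n)),
    depth_m = seq(20, by = 100, length.out = n),
    lat = rep(-30, n),
    lon = seq(-150, by = 5, length.out = n),
    temperature = seq(25, by = -3, length.out = n),
    irradiance_zone = ifelse(seq(20, by = 100, length.out = n) <= 162,
                             "photic", "aphotic"),
    time_point = "T1",
    stringsAsFactors = FALSE
  )
}

# Independent brute-force betaMNTD: naive double loop over taxa, written
# directly from the definition, sharing no code with the implementation.
bmntd_bruteforce <- function(table, tree, abundance_weighted = TRUE) {
  D <- ape::cophenetic.phylo(tree)
  n <- nrow(table)
  out <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (k in seq_len(n)) for (m in seq_len(n)) {
    if (k == m) next
    tk <- colnames(table)[table[k, ] > 0]
    tm <- colnames(table)[table[m, ] > 0]
    wk <- setNames(as.numeric(table[k, tk]) / sum(table[k, tk]), tk)
    wm <- setNames(as.numeric(table[m, tm]) / sum(table[m, tm]), tm)
    if (!abundance_weighted) {
      wk <- rep(1 / length(tk), length(tk))
      wm <- rep(1 / length(tm), length(tm))
      names(wk) <- tk; names(wm) <- tm
    }
    acc <- 0
    for (i in tk) {
      best <- Inf
      for (j in tm) best <- min(best, D[i, j])
      acc <- acc + 0.5 * wk[[i]] * best
    }
    for (j in tm) {
      best <- Inf
      for (i in tk) best <- min(best, D[i, j])
      acc <- acc + 0.5 * wm[[j]] * best
    }
    out[k, m] <- acc
  }
  (out + t(out)) / 2
}

random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(n * 3), n)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  d
}
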
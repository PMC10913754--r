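test_that("PERMANOVA agrees with vegan::adonis2 on F and R^2", {
  d <- random_distance_matrix(10, 21)
  g <- rep(c("a", "b"), each = 5)
  names(g) <- rownames(d)
  mine <- permanova(d, g, n_perm = 199, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ grp,
                        data = data.frame(grp = g), permutations = 99)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA separates tight clusters at the minimum attainable p", {
  set.seed(2)
  pts <- rbind(matrix(rnorm(9, 0, 0.01), 3), matrix(rnorm(9, 50, 0.01), 3))
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3); names(g) <- rownames(d)
  r <- permanova(d, g, permutations = "exhaustive")
  # 720 relabelings; the partition into {1:3},{4:6} is realized by
  # 2 * 3! * 3! = 72 of them, all tied at the maximal F
  expect_equal(r$p_value, 72 / 720)
})

test_that("exhaustive PERMANOVA p on 2+2 designs is a multiple of 1/3", {
  d <- random_distance_matrix(4, 31)
  g <- c("a", "a", "b", "b"); names(g) <- rownames(d)
  r <- permanova(d, g, permutations = "exhaustive")
  expect_equal(r$p_value * 3, round(r$p_value * 3))
  expect_gte(r$p_value, 1 / 3 - 1e-12)
})

test_that("PERMANOVA R^2 partitions total variance and F is relabel-invariant", {
  d <- random_distance_matrix(9, 41)
  g <- rep(c("a", "b", "c"), each = 3); names(g) <- rownames(d)
  r <- permanova(d, g, n_perm = 99, seed = 5)
  # recompute residual R^2 directly from sums of squares
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / 9
  ss_w <- sum(sapply(c("a", "b", "c"), function(lev) {
    idx <- which(g == lev)
    sum(d2[idx, idx][upper.tri(diag(3))]) / 3
  }))
  expect_equal(r$r_squared + ss_w / ss_total, 1, tolerance = 1e-10)
  # jointly permuting matrix and labels leaves F unchanged
  p <- sample(9)
  r2 <- permanova(d[p, p], g[p], n_perm = 99, seed = 5)
  expect_equal(r2$pseudo_F, r$pseudo_F, tolerance = 1e-12)
  expect_error(permanova(d, setNames(rep("a", 9), rownames(d))),
               class = "ea_invalid_argument")
  expect_error(permanova(d, setNames(c("a", rep("b", 8)), rownames(d))),
               class = "ea_invalid_argument")
})

test_that("Welch t matches the closed-form statistic and df", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 10)
  r <- welch_t_test(x, y)
  # closed forms computed from first principles
  se2 <- var(x) / 5 + var(y) / 5
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 5)^2 / 4 + (var(y) / 5)^2 / 4)
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$statistic, -1.8974, tolerance = 1e-4)
  expect_equal(r$degrees_of_freedom, df_hand, tolerance = 1e-12)
  expect_equal(r$degrees_of_freedom, 5.882, tolerance = 1e-3)
  # identical samples
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # equal variances and n: Welch df = 2n - 2
  a <- c(1, 2, 3, 4); b <- c(11, 12, 13, 14)
  expect_equal(welch_t_test(a, b)$degrees_of_freedom, 6)
})

test_that("Welch df stays within its algebraic bounds", {
  set.seed(8)
  for (r in 1:20) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1), sd = runif(1, 0.1, 3))
    d <- welch_t_test(x, y)$degrees_of_freedom
    expect_gte(d, min(length(x), length(y)) - 1 - 1e-9)
    expect_lte(d, length(x) + length(y) - 2 + 1e-9)
  }
})

test_that("ANOVA + Tukey flags only the separated group", {
  set.seed(5)
  vals <- c(0, 0, 0, 0, 10, 10) + rnorm(6, 0, 1e-3)
  g <- c("g1", "g1", "g2", "g2", "g3", "g3")
  r <- anova_tukey(vals, g)
  expect_lt(r$p_value, 1e-3)
  sig <- r$tukey$p_adj < 0.05
  expect_equal(grepl("g3", r$tukey$pair), sig)
})

test_that("Tukey with two groups equals the unadjusted comparison", {
  set.seed(6)
  vals <- rnorm(8); g <- rep(c("a", "b"), each = 4)
  r <- anova_tukey(vals, g)
  expect_equal(r$tukey$p_adj, r$p_value, tolerance = 1e-6)
})

test_that("Tukey-adjusted p is never below the unadjusted pairwise p", {
  set.seed(7)
  vals <- rnorm(12); g <- rep(c("a", "b", "c"), each = 4)
  r <- anova_tukey(vals, g)
  # unadjusted pairwise p from the pooled within-group variance
  ms_w <- sum(tapply(vals, g, function(v) sum((v - mean(v))^2))) / 9
  for (i in seq_len(nrow(r$tukey))) {
    gs <- strsplit(r$tukey$pair[i], "-")[[1]]
    diff <- mean(vals[g == gs[1]]) - mean(vals[g == gs[2]])
    t0 <- abs(diff) / sqrt(ms_w * (1 / 4 + 1 / 4))
    p_un <- 2 * pt(t0, 9, lower.tail = FALSE)
    expect_gte(r$tukey$p_adj[i] + 1e-12, p_un)
  }
})

test_that("Pearson correlation matches hand values", {
  expect_equal(pearson_correlation(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(pearson_correlation(1:5, -(1:5))$r, -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), class = "ea_invalid_argument")
})

test_that("diel CV matches the sample-sd definition and flags absent units", {
  tab <- rbind(t1 = c(u1 = 2, u2 = 0.5, u3 = 0),
               t2 = c(u1 = 4, u2 = 0.5, u3 = 0),
               t3 = c(u1 = 6, u2 = 0.5, u3 = 0),
               t4 = c(u1 = 8, u2 = 0.5, u3 = 0))
  meta <- data.frame(sample_id = rownames(tab), depth_m = 20,
                     time_point = c("02:00", "08:00", "14:00", "21:00"))
  r <- diel_cv(tab, meta)
  expect_equal(r$cv[r$unit == "u1"], sqrt(20 / 3) / 5, tolerance = 1e-9)
  expect_equal(r$cv[r$unit == "u2"], 0)
  expect_true(is.na(r$cv[r$unit == "u3"]))
  # a depth with a single time point is excluded with a warning
  meta2 <- rbind(meta, data.frame(sample_id = "x", depth_m = 100, time_point = "02:00"))
  tab2 <- rbind(tab, x = c(1, 1, 1))
  expect_warning(r2 <- diel_cv(tab2, meta2), "single time point")
  expect_false(100 %in% r2$depth_m)
})

test_that("trophic assignment takes the deepest matching rank", {
  lookup <- c(Dinophyceae = "mixotroph", Gymnodiniales = "heterotroph",
              Syndiniales = "parasite")
  taxonomy <- list(
    asv1 = c("Alveolata", "Dinophyceae", "Syndiniales"),
    asv2 = c("Alveolata", "Dinophyceae", "Gymnodiniales"),
    asv3 = c("Alveolata", "Dinophyceae"),
    asv4 = character(0),
    asv5 = c("Stramenopila")
  )
  out <- assign_trophic_groups(taxonomy, lookup)
  expect_equal(unname(out[c("asv1", "asv2", "asv3", "asv4", "asv5")]),
               c("parasite", "heterotroph", "mixotroph", "unknown", "unknown"))
})

test_that("functional-group aggregation conserves abundance", {
  tab <- rbind(s1 = c(a = 0.3, b = 0.7), s2 = c(a = 0.5, b = 0.5))
  mapping <- c(a = "parasite", b = "mixotroph")
  out <- group_relative_abundance(tab, mapping)
  expect_equal(unname(out["s1", c("mixotroph", "parasite")]), c(0.7, 0.3))
  expect_equal(unname(rowSums(out)), c(1, 1), tolerance = 1e-12)
  # invariance to taxon order
  out2 <- group_relative_abundance(tab[, c("b", "a")], mapping)
  expect_equal(out, out2)
  # unmapped taxa land in "unknown" with a message
  expect_message(out3 <- group_relative_abundance(cbind(tab, c = c(0.1, 0.1)),
                                                  mapping), "unknown")
  expect_equal(unname(out3[, "unknown"]), c(0.1, 0.1))
})
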
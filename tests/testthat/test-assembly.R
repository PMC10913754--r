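test_that("betaMNTD matches hand-worked patristic examples", {
  tr <- toy_tree()
  t1 <- rbind(s1 = c(A = 1, B = 0, C = 0), s2 = c(A = 0, B = 0, C = 1))
  expect_equal(pairwise_bmntd(t1, tr)["s1", "s2"], 4)
  t2 <- rbind(s1 = c(A = 1, B = 0, C = 0), s2 = c(A = 0, B = 0.5, C = 0.5))
  expect_equal(pairwise_bmntd(t2, tr)["s1", "s2"], 2.5)
  t3 <- rbind(s1 = c(A = 2, B = 1, C = 1), s2 = c(A = 2, B = 1, C = 1))
  expect_equal(pairwise_bmntd(t3, tr)["s1", "s2"], 0)
})

test_that("betaMNTD equals an independent brute-force implementation", {
  set.seed(1)
  for (r in 1:12) {
    n_taxa <- sample(3:6, 1); n_samp <- sample(2:4, 1)
    tr <- ape::rtree(n_taxa)
    tab <- matrix(rpois(n_samp * n_taxa, 2), n_samp,
                  dimnames = list(paste0("s", 1:n_samp), tr$tip.label))
    tab[rowSums(tab) == 0, 1] <- 1
    for (aw in c(TRUE, FALSE)) {
      mine <- pairwise_bmntd(tab, tr, abundance_weighted = aw)
      ref <- bmntd_bruteforce(tab, tr, abundance_weighted = aw)
      expect_lt(max(abs(mine - ref)), 1e-10)
    }
  }
})

test_that("betaMNTD agrees with picante::comdistnt", {
  set.seed(2)
  tr <- ape::rtree(8)
  tab <- matrix(rpois(4 * 8, 3), 4, dimnames = list(paste0("s", 1:4), tr$tip.label))
  tab[tab == 0 & col(tab) == 1] <- 1
  mine <- pairwise_bmntd(tab, tr, abundance_weighted = TRUE)
  ref <- as.matrix(picante::comdistnt(tab, ape::cophenetic.phylo(tr),
                                      abundance.weighted = TRUE))
  expect_lt(max(abs(mine - ref[rownames(mine), colnames(mine)])), 1e-10)
})

test_that("betaNTI flags zero-variance nulls on distance-constant trees", {
  # star-like tree: every patristic distance is 2
  tr <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  tab <- rbind(s1 = c(A = 1, B = 1, C = 0, D = 0),
               s2 = c(A = 0, B = 0, C = 1, D = 1))
  expect_message(b <- bnti_matrix(tab, tr, n_null = 99, seed = 1), "zero null sd")
  expect_true(is.na(b["s1", "s2"]))
  expect_equal(attr(b, "n_flagged"), 1L)
})

test_that("betaNTI is deterministic given a seed and symmetric", {
  sc <- simulate_scenario(scenario_spec("drift", n_taxa = 20, n_sites = 8,
                                        reads_per_sample = 400, seed = 3))
  b1 <- bnti_matrix(sc$table, sc$tree, n_null = 99, seed = 9)
  b2 <- bnti_matrix(sc$table, sc$tree, n_null = 99, seed = 9)
  expect_identical(b1, b2)
  expect_lt(max(abs(b1 - t(b1)), na.rm = TRUE), 1e-12)
  b3 <- bnti_matrix(sc$table, sc$tree, n_null = 99, seed = 10)
  expect_false(identical(b1, b3))
})

test_that("Raup-Crick values are bounded and identical samples score <= 0", {
  sc <- simulate_scenario(scenario_spec("drift", n_taxa = 20, n_sites = 8,
                                        reads_per_sample = 400, seed = 4))
  rc <- rc_bray_matrix(sc$table, n_null = 99, seed = 5)
  expect_true(all(rc >= -1 & rc <= 1))
  expect_lt(max(abs(rc - t(rc))), 1e-12)
  # duplicated sample: observed BC = 0 is the minimum attainable
  tab <- sc$table[c(1, 1, 2), ]
  rownames(tab) <- c("a", "b", "c")
  rc2 <- rc_bray_matrix(tab, n_null = 99, seed = 6)
  expect_lte(rc2["a", "b"], 0)
  expect_error(rc_bray_matrix(sc$table / 2, n_null = 99, seed = 1),
               class = "ea_invalid_argument")
})

test_that("exact Raup-Crick matches a brute-force enumeration oracle", {
  # 2 taxa, 2 samples, richness 1, one read each: null outcomes enumerable
  tab <- rbind(s1 = c(A = 1L, B = 0L), s2 = c(A = 0L, B = 1L))
  rc <- rc_bray_matrix(tab, method = "exact")
  # oracle: each null sample picks one taxon with probability proportional
  # to occupancy (1/2 each); BC_null = 0 if same taxon else 1; obs BC = 1
  p_same <- 0.5
  p_less <- p_same          # BC 0 < 1
  p_eq <- 1 - p_same        # BC 1 == 1, ties count half
  expect_equal(rc["s1", "s2"], ((p_less + 0.5 * p_eq) - 0.5) * 2)
  # three samples with unequal occupancy: A occupies 2/3, B 1/3, so each
  # null sample draws A with probability 2/3 and P(same draw) = 5/9
  tab2 <- rbind(s1 = c(A = 1L, B = 0L), s2 = c(A = 1L, B = 0L),
                s3 = c(A = 0L, B = 1L))
  rc2 <- rc_bray_matrix(tab2, method = "exact")
  p_same2 <- (2 / 3)^2 + (1 / 3)^2
  expect_equal(rc2["s1", "s3"], ((p_same2 + 0.5 * (1 - p_same2)) - 0.5) * 2)
  expect_equal(rc2["s1", "s2"], ((0 + 0.5 * p_same2) - 0.5) * 2)
})

test_that("Monte-Carlo Raup-Crick converges to the exact value", {
  tab <- rbind(s1 = c(A = 1L, B = 0L, C = 0L), s2 = c(A = 0L, B = 1L, C = 0L),
               s3 = c(A = 0L, B = 0L, C = 1L))
  exact <- rc_bray_matrix(tab, method = "exact")
  mc <- rc_bray_matrix(tab, n_null = 4999, seed = 8)
  expect_lt(max(abs(exact - mc)), 0.06)
})

test_that("assembly classification follows the strict threshold rules", {
  mk <- function(b, r) {
    bm <- matrix(c(0, b, b, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
    rm <- matrix(c(0, r, r, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
    as.character(classify_assembly(bm, rm)$process)
  }
  expect_equal(mk(2.5, 0), "variable_selection")
  expect_equal(mk(-2.5, 0), "homogeneous_selection")
  expect_equal(mk(0.5, 0.96), "dispersal_limitation")
  expect_equal(mk(0.5, -0.96), "homogenizing_dispersal")
  expect_equal(mk(0, 0), "undominated")
  # boundary values fall through to the stochastic / undominated side
  expect_equal(mk(2, 0.96), "dispersal_limitation")
  expect_equal(mk(-2, -0.96), "homogenizing_dispersal")
  expect_equal(mk(2, 0.95), "undominated")
  expect_equal(mk(-2, -0.95), "undominated")
})

test_that("process fractions count pairs and obey the law of total probability", {
  pairs <- data.frame(
    sample_a = c("a", "a", "a", "b"), sample_b = c("b", "c", "d", "c"),
    bnti = c(3, -3, 0, 0), rc = c(0, 0, 0.96, 0.96),
    process = factor(c("variable_selection", "homogeneous_selection",
                       "dispersal_limitation", "dispersal_limitation"),
                     levels = assembly_processes()))
  fr <- summarize_process_fractions(pairs)
  expect_equal(fr$fraction, c(0.25, 0.25, 0.5, 0, 0))
  expect_equal(unique(fr$n_pairs), 4L)
  # strata partition: pair-count-weighted stratum fractions = entire fractions
  strata <- c("u", "u", "v", "v")
  fr2 <- summarize_process_fractions(pairs, strata)
  ent <- fr2[fr2$stratum == "entire", ]
  by_s <- lapply(c("u", "v"), function(s0) fr2[fr2$stratum == s0, ])
  w <- vapply(by_s, function(x) x$n_pairs[1], numeric(1))
  mixed <- Reduce(`+`, Map(function(x, wi) x$fraction * wi, by_s, w)) / sum(w)
  expect_equal(ent$fraction, mixed, tolerance = 1e-12)
})

test_that("pair strata follow the both-photic / both-aphotic rule", {
  meta <- data.frame(sample_id = c("p1", "p2", "a1"),
                     irradiance_zone = c("photic", "photic", "aphotic"))
  pairs <- data.frame(sample_a = c("p1", "p1", "p2"), sample_b = c("p2", "a1", "a1"))
  expect_equal(pair_strata(pairs, meta), c("euphotic", "mixed", "mixed"))
})

test_that("community_assembly returns a coherent classed fit", {
  sc <- simulate_scenario(scenario_spec("drift", n_taxa = 20, n_sites = 8,
                                        reads_per_sample = 400, seed = 12))
  fit <- community_assembly(sc$table, sc$tree, sc$meta, n_null = 99, seed = 13)
  expect_s3_class(fit, "assembly_fit")
  expect_equal(nrow(fit$pairs), choose(8, 2))
  expect_true(all(fit$fractions$fraction >= 0 & fit$fractions$fraction <= 1,
                  na.rm = TRUE))
  ent <- fit$fractions[fit$fractions$stratum == "entire", ]
  expect_equal(sum(ent$fraction), 1, tolerance = 1e-12)
  expect_output(print(fit), "process fractions")
  expect_output(print(summary(fit)), "stratum")
  expect_identical(as.data.frame(fit), fit$pairs)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})
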
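test_that("adjacency follows the soft-threshold closed forms", {
  v <- vectors_with_cor(0.5, n = 24)
  m <- rbind(g1 = v$x, g2 = v$y)
  colnames(m) <- sprintf("s%02d", 1:24)
  a6 <- adjacency(m, network_config(power = 6))
  expect_equal(a6["g1", "g2"], 0.5^6, tolerance = 1e-12)
  expect_equal(unname(diag(a6)), c(1, 1))
  a1 <- adjacency(m, network_config(power = 1))
  expect_equal(a1["g1", "g2"], 0.5, tolerance = 1e-12)
  s6 <- adjacency(m, network_config(power = 6, sign = "signed"))
  expect_equal(s6["g1", "g2"], ((1 + 0.5) / 2)^6, tolerance = 1e-12)
  # perfect correlation saturates at 1 for any power
  m2 <- rbind(g1 = v$x, g2 = 2 * v$x + 3)
  colnames(m2) <- colnames(m)
  expect_equal(adjacency(m2, network_config(power = 9))["g1", "g2"], 1)
})

test_that("zero-variance genes are excluded with a warning", {
  m <- small_matrix(5, 8)
  m[3, ] <- 7
  expect_warning(a <- adjacency(m, network_config()), "zero-variance")
  expect_equal(nrow(a), 4)
  expect_false("g03" %in% rownames(a))
})

test_that("TOM reduces to the adjacency for two genes and is exact on hand cases", {
  for (t in c(0.2, 0.5, 0.9)) {
    a <- matrix(c(1, t, t, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
    expect_equal(topological_overlap(a)["a", "b"], t, tolerance = 1e-12)
  }
  # identical binary neighborhoods with a_ij = 1 give overlap 1
  a <- matrix(1, 4, 4)
  dimnames(a) <- list(letters[1:4], letters[1:4])
  expect_true(all(abs(topological_overlap(a) - 1) < 1e-12))
})

test_that("matrix TOM equals the brute-force triple loop and stays in [0,1]", {
  withr::with_seed(21, {
    for (i in 1:3) {
      r <- matrix(runif(15 * 15), 15)
      a <- (r + t(r)) / 2
      diag(a) <- 1
      dimnames(a) <- list(paste0("g", 1:15), paste0("g", 1:15))
      tom <- topological_overlap(a)
      expect_lt(max(abs(tom - tom_bruteforce(a))), 1e-10)
      expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
      expect_equal(tom, t(tom), tolerance = 1e-12)
    }
  })
})

test_that("scale-free fit recognizes an exact power-law degree sequence", {
  k <- rep(1:12, times = round(4000 * (1:12)^-2.2))
  f <- scale_free_fit(k, n_bins = 12)
  expect_gt(f$r_squared, 0.95)
  expect_lt(f$slope, 0)
  # frequencies increasing with degree give a negative signed fit
  f2 <- scale_free_fit(rep(1:10, times = 10 * (1:10)), n_bins = 10)
  expect_lt(f2$r_squared, 0)
})

test_that("soft-threshold overrides are honored and the fit table is complete", {
  m <- recovery_sim()$expr[1:300, ]
  r6 <- pick_soft_threshold(m, candidate_powers = c(4, 6, 8), override = 6)
  expect_equal(r6$power, 6)
  r8 <- pick_soft_threshold(m, candidate_powers = c(4, 6, 8), override = 8)
  expect_equal(r8$power, 8)
  expect_equal(r8$fit_table$power, c(4, 6, 8))
  expect_true(all(c("r_squared", "slope", "mean_k") %in% names(r8$fit_table)))
})

test_that("three strongly loaded blocks are recovered exactly", {
  cfg <- sim_config(n_genes = 600, module_sizes = rep(100L, 3), n_per_group = 12,
                    loading_range = c(0.8, 0.95), n_de_genes = 0,
                    trait_linked_modules = numeric(0), disrupted_modules = list(),
                    module_group_effect = 0, seed = 3)
  sim <- simulate_expression(cfg)
  tom <- topological_overlap(adjacency(sim$expr, network_config(power = 6)))
  asg <- detect_modules(tom, network_config(deep_split = 2))
  expect_equal(length(setdiff(unique(asg), "grey")), 3)
  expect_gte(adjusted_rand_index(sim$truth$module_of_gene, asg), 0.9)
  # labels follow the color sequence by descending size
  sizes <- sort(table(asg[asg != "grey"]), decreasing = TRUE)
  expect_true(all(names(sizes) %in% c("turquoise", "blue", "brown")))
})

test_that("a pure-noise matrix is left almost entirely unassigned", {
  cfg <- sim_config(n_genes = 600, module_sizes = integer(0), n_per_group = 12,
                    n_de_genes = 0, trait_linked_modules = numeric(0),
                    disrupted_modules = list(), seed = 2)
  sim <- simulate_expression(cfg)
  tom <- topological_overlap(adjacency(sim$expr, network_config(power = 6)))
  asg <- suppressWarnings(detect_modules(tom, network_config(deep_split = 2)))
  expect_gte(mean(asg == "grey"), 0.9)
})

test_that("higher deep split never coarsens the partition of nested blocks", {
  withr::with_seed(11, {
    n <- 500; ns <- 40
    f_super <- matrix(rnorm(2 * ns), 2)
    f_sub <- matrix(rnorm(4 * ns), 4)
    x <- matrix(rnorm(n * ns) * 0.9, n, ns)
    blk <- rep(c(1, 1, 2, 2, 0), each = 100)
    sub <- rep(c(1, 2, 3, 4, 0), each = 100)
    for (g in seq_len(n)) {
      if (blk[g] > 0) x[g, ] <- x[g, ] + 0.6 * f_super[blk[g], ] + 0.8 * f_sub[sub[g], ]
    }
  })
  dimnames(x) <- list(sprintf("g%03d", 1:n), sprintf("s%02d", 1:ns))
  tom <- topological_overlap(adjacency(x, network_config(power = 6)))
  counts <- vapply(0:3, function(ds) {
    asg <- detect_modules(tom, network_config(deep_split = ds))
    length(setdiff(unique(asg), "grey"))
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_gte(counts[4], counts[1])
})

test_that("module detection is invariant to gene input order", {
  sim <- recovery_sim()
  m <- sim$expr[1:800, ]
  tom <- topological_overlap(adjacency(m, network_config(power = 6)))
  asg1 <- detect_modules(tom, network_config(deep_split = 2))
  withr::with_seed(33, perm <- sample(nrow(tom)))
  asg2 <- detect_modules(tom[perm, perm], network_config(deep_split = 2))
  common <- names(asg1)
  expect_equal(adjusted_rand_index(asg1[common], asg2[common]), 1)
})

test_that("eigengenes obey the rank-1, orientation, and optimality contracts", {
  v <- withr::with_seed(5, rnorm(12))
  prof <- as.numeric(scale(v))
  m <- rbind(g1 = 2 * v + 1, g2 = 3 * v - 2, g3 = v)
  colnames(m) <- sprintf("s%02d", 1:12)
  assign <- setNames(rep("mod1", 3), rownames(m))
  eig <- module_eigengenes(m, assign)
  expect_equal(abs(cor(eig["mod1", ], prof)), 1, tolerance = 1e-12)
  expect_gt(cor(eig["mod1", ], prof), 0)       # oriented with the mean profile
  expect_equal(mean(eig["mod1", ]), 0, tolerance = 1e-12)
  # negating members negates the eigengene; kME magnitudes unchanged
  eig_neg <- module_eigengenes(-m, assign)
  expect_equal(eig_neg["mod1", ], -eig["mod1", ], tolerance = 1e-10)
  # first-PC optimality on a noisy module: mean squared correlation with the
  # eigengene beats mean squared correlation with any single member profile
  mm <- recovery_sim()$expr[1:50, ]
  asg <- setNames(rep("m", 50), rownames(mm))
  e <- module_eigengenes(mm, asg)["m", ]
  r2_eig <- mean(cor(t(mm), e)^2)
  r2_single <- max(vapply(1:50, function(i) mean(cor(t(mm), mm[i, ])^2), numeric(1)))
  expect_gte(r2_eig, r2_single - 1e-10)
})

test_that("connectivity statistics respect their bounds and separate members from outsiders", {
  sim <- recovery_sim()
  m <- sim$expr[c(1:100, 1501:1600), ]   # one module + background
  a <- adjacency(m, network_config(power = 6))
  assign <- truth_assignment(sim)[rownames(m)]
  eig <- module_eigengenes(m, assign)
  con <- connectivity_stats(a, assign, eig, m)
  mem <- con$module == "M1"
  expect_true(all(con$kIM[mem] <= con$kTotal[mem] + 1e-12))
  expect_true(all(abs(con$kME[mem]) <= 1))
  expect_true(all(is.na(con$kIM[!mem])))
  expect_true(all(con$kTotal >= 0))
  # members' kME dominates that of random non-members
  kme_bg <- cor(t(m[101:200, ]), eig["M1", ])
  expect_gte(mean(outer(con$kME[mem], abs(kme_bg), `>`)), 0.95)
})
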
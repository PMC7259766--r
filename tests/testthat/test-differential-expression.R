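test_that("the four-group design yields the six canonical labeled contrasts", {
  m <- small_matrix(10, 16, seed = 2)
  ann <- balanced_ann(m)
  de <- pairwise_contrasts(m, ann)
  expect_equal(sort(unique(de$contrast)), paste0("C", 1:6))
  expect_equal(nrow(de), 10 * 6)
  # C1 compares CIE Drinking with Air Drinking by mean difference
  grp <- sample_groups(ann)
  lr <- rowMeans(m[, grp == "CIE Drinking"]) - rowMeans(m[, grp == "Air Drinking"])
  expect_equal(de$log_ratio[de$contrast == "C1"], unname(lr), tolerance = 1e-12)
})

test_that("identical group means give log-ratio 0, t 0, p 1 for that contrast", {
  m <- small_matrix(5, 16, seed = 3)
  ann <- balanced_ann(m)
  grp <- sample_groups(ann)
  m[, grp == "Air Drinking"] <- m[, grp == "CIE Drinking"]
  de <- pairwise_contrasts(m, ann)
  c1 <- de[de$contrast == "C1", ]
  expect_equal(c1$log_ratio, rep(0, 5))
  expect_equal(c1$t, rep(0, 5))
  expect_equal(c1$p_value, rep(1, 5))
})

test_that("pairwise t statistics agree with the per-gene linear-model oracle", {
  m <- small_matrix(8, 20, seed = 6)
  ann <- balanced_ann(m)
  grp <- sample_groups(ann)
  de <- pairwise_contrasts(m, ann)
  for (i in 1:8) {
    fit <- stats::lm(m[i, ] ~ 0 + grp)
    cf <- summary(fit)$coefficients
    v <- stats::vcov(fit)
    lr <- cf["grpCIE Drinking", 1] - cf["grpAir Drinking", 1]
    se <- sqrt(v["grpCIE Drinking", "grpCIE Drinking"] +
                 v["grpAir Drinking", "grpAir Drinking"])
    t_or <- lr / se
    row <- de[de$contrast == "C1" & de$probeset == rownames(m)[i], ]
    expect_equal(row$t, unname(t_or), tolerance = 1e-10)
    expect_equal(row$p_value, 2 * pt(-abs(unname(t_or)), fit$df.residual),
                 tolerance = 1e-10)
  }
})

test_that("log-ratios are transitive through shared groups", {
  m <- small_matrix(12, 16, seed = 7)
  ann <- balanced_ann(m)
  de <- pairwise_contrasts(m, ann)
  lr <- function(cc) de$log_ratio[de$contrast == cc]
  # (CIE D - Air ND) = (CIE D - CIE ND) + (CIE ND - Air ND)
  expect_equal(lr("C4"), lr("C3") + lr("C2"), tolerance = 1e-12)
  # (CIE D - Air D) = (CIE D - Air ND) - (Air D - Air ND)
  expect_equal(lr("C1"), lr("C4") - lr("C6"), tolerance = 1e-12)
})

test_that("BH step-up adjustment matches hand computations and rejects bad input", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("BH adjustment equals an independent brute-force step-up on random vectors", {
  worst <- withr::with_seed(42, {
    max(vapply(1:50, function(i) {
      p <- runif(sample(1:200, 1))^sample(1:3, 1)
      max(abs(bh_fdr(p) - bh_bruteforce(p)))
    }, numeric(1)))
  })
  expect_lt(worst, 1e-14)
})

test_that("adjusted values are monotone nondecreasing in p and bounded in [0,1]", {
  withr::with_seed(1, p <- runif(500)^2)
  q <- bh_fdr(p)
  expect_true(all(q >= 0 & q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
})

test_that("the two-factor model recovers a planted interaction and handles degenerate input", {
  m <- small_matrix(40, 48, seed = 9)
  ann <- balanced_ann(m)
  grp <- sample_groups(ann)
  m[1:10, grp == "CIE Drinking"] <- m[1:10, grp == "CIE Drinking"] + 3
  tf <- two_factor_model(m, ann)
  inter <- tf[tf$contrast == "interaction", ]
  expect_true(all(inter$p_value[1:10] < 1e-2))
  expect_true(all(inter$p_value[11:40] > 1e-3))
  # a cell-specific shift loads on both main effects and the interaction
  vap <- tf[tf$contrast == "vapor", ]
  expect_true(all(vap$p_value[1:10] < 0.05))
  # constant probeset: flagged, p = 1
  m2 <- m
  m2[5, ] <- 3
  tf2 <- two_factor_model(m2, ann)
  expect_true(all(tf2$zero_variance[tf2$probeset == "g05"]))
  expect_equal(tf2$p_value[tf2$probeset == "g05"], rep(1, 3))
})

test_that("interaction type-I rate is nominal under additive effects", {
  cfg <- sim_config(n_genes = 4000, module_sizes = integer(0), n_per_group = 12,
                    n_de_genes = 0, trait_linked_modules = numeric(0),
                    disrupted_modules = list(), seed = 13)
  sim <- simulate_expression(cfg)
  # additive main effects, no interaction
  grp <- sample_groups(sim$ann)
  m <- sim$expr
  m[, sim$ann$vapor == "CIE"] <- m[, sim$ann$vapor == "CIE"] + 1.0
  m[, sim$ann$drinking == "Drinking"] <- m[, sim$ann$drinking == "Drinking"] + 0.6
  tf <- two_factor_model(m, sim$ann)
  rate <- mean(tf$p_value[tf$contrast == "interaction"] < 0.05)
  se <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(rate - 0.05), 3 * se)
  # main effects are detected essentially everywhere
  expect_gt(mean(tf$fdr[tf$contrast == "vapor"] < 0.01), 0.95)
})

test_that("contrast overlaps count 2- and 3-way intersections of significant sets", {
  res <- tibble::tibble(
    probeset = c("a", "b", "c", "a", "b", "a"),
    contrast = c("C1", "C1", "C1", "C3", "C3", "C4"),
    fdr = 0.001
  )
  ov <- contrast_overlap(res, fdr = 0.01)
  expect_equal(ov$n_overlap[ov$contrasts == "C1&C3"], 2)
  expect_equal(ov$n_overlap[ov$contrasts == "C1&C4"], 1)
  expect_equal(ov$n_overlap[ov$contrasts == "C3&C4"], 1)
  expect_equal(ov$n_overlap[ov$contrasts == "C1&C3&C4"], 1)
})

test_that("mean shifts planted in CIE-Drinking are captured by the C1/C3/C4 triple", {
  cfg <- sim_config(n_genes = 3000, module_sizes = integer(0), n_per_group = 12,
                    n_de_genes = 200, de_effect = 2,
                    trait_linked_modules = numeric(0),
                    disrupted_modules = list(), seed = 14)
  sim <- simulate_expression(cfg)
  de <- pairwise_contrasts(sim$expr, sim$ann)
  sig <- function(cc) de$probeset[de$contrast == cc & de$fdr <= 0.01]
  triple <- Reduce(intersect, list(sig("C1"), sig("C3"), sig("C4")))
  expect_gte(length(intersect(triple, sim$truth$de_genes)) /
               length(sim$truth$de_genes), 0.9)
  expect_setequal(names(sim$truth$de_genes_per_contrast), paste0("C", 1:6))
  expect_equal(sim$truth$de_genes_per_contrast$C2, character(0))
})
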
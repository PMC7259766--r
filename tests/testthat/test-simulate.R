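test_that("drinking records have the study layout and NonDrinking mice are all zero", {
  cfg <- sim_config(n_genes = 100, module_sizes = integer(0), n_per_group = 12,
                    n_de_genes = 0, trait_linked_modules = numeric(0),
                    disrupted_modules = list(), seed = 1)
  d <- simulate_drinking(cfg)
  expect_equal(nrow(d), 48 * 50)
  expect_equal(length(unique(d$mouse_id)), 48)
  expect_equal(sort(unique(d$session)), 1:50)
  expect_setequal(unique(d$phase), c(paste0("baseline", 1:6), paste0("cie", 1:4)))
  nd <- d[d$drinking == "NonDrinking", ]
  expect_true(all(nd$intake_gkg == 0))
  expect_equal(length(unique(nd$mouse_id)), 24)
  expect_true(all(d$intake_gkg >= 0))
})

test_that("zero escalation gives CIE-Drinking and Air-Drinking equal phase means within noise", {
  cfg <- sim_config(n_genes = 100, module_sizes = integer(0), n_per_group = 12,
                    n_de_genes = 0, trait_linked_modules = numeric(0),
                    disrupted_modules = list(),
                    cie_escalation = rep(0, 4), air_escalation = rep(0, 4),
                    seed = 2)
  d <- simulate_drinking(cfg)
  dk <- d[d$drinking == "Drinking" & grepl("^cie", d$phase), ]
  means <- tapply(dk$intake_gkg, dk$vapor, mean)
  # both groups sit at the common baseline mean; difference is sampling noise
  per_mouse <- tapply(dk$intake_gkg, dk$mouse_id, mean)
  vap <- tapply(dk$vapor, dk$mouse_id, `[`, 1)
  sem <- sqrt(var(per_mouse[vap == "CIE"]) / 12 + var(per_mouse[vap == "Air"]) / 12)
  expect_lt(abs(means[["CIE"]] - means[["Air"]]), 3 * sem)
})

test_that("CIE-Drinking escalation at cycle 4 matches the configured phase-mean difference", {
  cfg <- sim_config(seed = 1)
  d <- simulate_drinking(cfg)
  cd <- d[d$group == "CIE Drinking", ]
  per_mouse_diff <- vapply(split(cd, cd$mouse_id), function(x) {
    mean(x$intake_gkg[x$phase == "cie4"]) -
      mean(x$intake_gkg[grepl("^baseline", x$phase)])
  }, numeric(1))
  obs <- mean(per_mouse_diff)
  sem <- sd(per_mouse_diff) / sqrt(length(per_mouse_diff))
  expect_lt(abs(obs - cfg$cie_escalation[4]), 2 * sem)
  # and the escalation is a real increase over baseline
  expect_gt(obs, 0)
})

test_that("simulation is bit-identical under a fixed seed and differs across seeds", {
  cfg <- sim_config(n_genes = 200, module_sizes = c(40L, 30L), n_per_group = 4,
                    n_de_genes = 20, seed = 9)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$truth, s2$truth)
  cfg2 <- sim_config(n_genes = 200, module_sizes = c(40L, 30L), n_per_group = 4,
                     n_de_genes = 20, seed = 10)
  expect_false(identical(simulate_expression(cfg2)$expr, s1$expr))
})

test_that("planted modules are more correlated than background", {
  sim <- recovery_sim()
  cr <- abs(cor(t(sim$expr[1:100, ])))       # module 1 genes
  bg <- abs(cor(t(sim$expr[1501:1600, ])))   # background genes
  expect_gt(mean(cr[upper.tri(cr)]), mean(bg[upper.tri(bg)]) * 3)
})

test_that("high loadings and vanishing noise drive within-module correlations to 1", {
  cfg <- sim_config(n_genes = 30, module_sizes = 20L, n_per_group = 4,
                    loading_range = c(0.9, 0.9), noise_sd = 1e-4,
                    n_de_genes = 0, trait_linked_modules = numeric(0),
                    disrupted_modules = list(), seed = 3)
  sim <- simulate_expression(cfg)
  cr <- abs(cor(t(sim$expr[1:20, ])))
  expect_gt(min(cr), 0.999)
})

test_that("planted disruption decorrelates the module in the target group only", {
  cfg <- sim_config(n_genes = 300, module_sizes = c(100L, 100L), n_per_group = 12,
                    n_de_genes = 0, trait_linked_modules = numeric(0),
                    module_group_effect = 0,
                    disrupted_modules = list(M1 = list(group = "CIE Drinking",
                                                       fraction = 1)),
                    seed = 4)
  sim <- simulate_expression(cfg)
  grp <- sample_groups(sim$ann)
  mean_abs_cor <- function(rows, cols) {
    cr <- abs(cor(t(sim$expr[rows, cols])))
    mean(cr[upper.tri(cr)])
  }
  m1 <- 1:100; m2 <- 101:200; bg <- 201:300
  # in the disrupted group, module correlations collapse to the noise floor
  expect_lt(mean_abs_cor(m1, grp == "CIE Drinking"),
            1.5 * mean_abs_cor(bg, grp == "CIE Drinking"))
  expect_gt(mean_abs_cor(m1, grp == "Air NonDrinking"),
            1.8 * mean_abs_cor(bg, grp == "Air NonDrinking"))
  # the undisrupted module keeps comparable structure in both groups
  r2 <- mean_abs_cor(m2, grp == "CIE Drinking") /
    mean_abs_cor(m2, grp == "Air NonDrinking")
  expect_gt(r2, 0.7)
  expect_lt(r2, 1.4)
})

test_that("every gene belongs to exactly one module or the background set", {
  sim <- recovery_sim()
  mo <- sim$truth$module_of_gene
  expect_equal(length(mo), 2000)
  expect_setequal(unique(mo), c("background", paste0("M", 1:5)))
  expect_equal(sum(mo != "background"), 500)
  expect_false(anyDuplicated(names(mo)) > 0)
})

test_that("the all-null generator is calibrated: one-way ANOVA type-I rate is nominal", {
  cfg <- sim_config(n_genes = 6000, module_sizes = integer(0), n_per_group = 12,
                    n_de_genes = 0, trait_linked_modules = numeric(0),
                    disrupted_modules = list(), seed = 6)
  sim <- simulate_expression(cfg)
  res <- row_anova(sim$expr, sample_groups(sim$ann))
  rate <- mean(res$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / 6000)
  expect_lt(abs(rate - 0.05), 2 * se + 1e-9)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_genes = 50, module_sizes = c(40L, 30L)), "exceeds")
  expect_error(sim_config(module_sizes = c(2L)), ">= 3")
  expect_error(sim_config(disrupted_modules = list(M1 = list(group = "CIE Drinking",
                                                             fraction = 1.2))),
               "fraction")
  expect_error(sim_config(loading_range = c(0.9, 0.5)), "interval")
  expect_error(sim_config(n_genes = 300, module_sizes = c(100L, 100L, 99L),
                          n_de_genes = 50), "background")
  expect_error(sim_config(de_group = "CIE Drnking"), "de_group")
})
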
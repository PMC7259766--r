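# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the planted-module recovery dataset: 5 modules of 100 genes in 2,000,
# 12 mice per group (48 arrays), loadings 0.5-0.9, module 1 linked to the
# cycle-4 drinking change at population Spearman 0.7
recovery_sim <- function() {
  cache_fixture("recovery_sim", function() {
    cfg <- sim_config(
      n_genes = 2000, module_sizes = rep(100L, 5), n_per_group = 12,
      loading_range = c(0.5, 0.9), n_de_genes = 0,
      disrupted_modules = list(), seed = 1
    )
    drinking <- simulate_drinking(cfg)
    sim <- simulate_expression(cfg, drinking)
    sim$drinking <- drinking
    sim$cfg <- cfg
    sim
  })
}

recovery_tom <- function() {
  cache_fixture("recovery_tom", function() {
    sim <- recovery_sim()
    topological_overlap(adjacency(sim$expr, network_config(power = 6)))
  })
}

# planted truth as a module assignment (background -> grey)
truth_assignment <- function(sim) {
  asg <- sim$truth$module_of_gene
  asg[asg == "background"] <- "grey"
  asg
}

# a small deterministic expression matrix with named dims
small_matrix <- function(n_genes = 6, n_samples = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples, 8, 1), n_genes, n_samples)
  })
  dimnames(m) <- list(sprintf("g%02d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  m
}

# annotation for a balanced 2x2 design over the columns of m
balanced_ann <- function(m) {
  n <- ncol(m)
  stopifnot(n %% 4 == 0)
  per <- n / 4
  tibble::tibble(
    sample_id = colnames(m),
    vapor = rep(c("CIE", "CIE", "Air", "Air"), each = per),
    drinking = rep(c("Drinking", "NonDrinking", "Drinking", "NonDrinking"),
                   each = per),
    mouse_id = paste0("m", seq_len(n))
  )
}

# independent brute-force BH step-up: q_(i) = min_{j >= i} m * p_(j) / j
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  running <- Inf
  for (i in seq(n, 1)) {
    running <- min(running, n * p[o[i]] / i)
    q_sorted[i] <- min(1, running)
  }
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

# brute-force TOM by triple loop
tom_bruteforce <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  out <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, -i])
      kj <- sum(a[j, -j])
      out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  out
}

# exact hypergeometric upper tail by direct pmf summation
hyper_tail_bruteforce <- function(k, m, n, big_n) {
  kk <- max(0, m + n - big_n):min(m, n)
  pmf <- choose(m, kk) * choose(big_n - m, n - kk) / choose(big_n, n)
  sum(pmf[kk >= k])
}

# two vectors with an exact sample Pearson correlation r
vectors_with_cor <- function(r, n = 20, seed = 4) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    z <- rnorm(n)
  })
  x <- as.numeric(scale(x))
  z <- resid(lm(z ~ x))
  z <- as.numeric(scale(z))
  y <- r * x + sqrt(1 - r^2) * z
  list(x = x, y = y)
}
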
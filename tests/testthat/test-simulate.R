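test_that("simulated pedigrees satisfy structural invariants", {
  cfg <- sim_config(n_founders_f = 30, n_founders_m = 25, n_generations = 3,
                    mean_offspring_per_mother = 2, seed = 5)
  set.seed(5)
  truth <- simulate_pedigree_population(cfg)
  ind <- truth$individuals

  # parent sexes
  sex_of <- stats::setNames(ind$sex, ind$id)
  expect_true(all(sex_of[stats::na.omit(ind$mother)] == "F"))
  expect_true(all(sex_of[stats::na.omit(ind$father)] == "M"))
  # founders parentless, non-founders fully parented
  expect_true(all(is.na(ind$mother) == (ind$generation == 1)))
  # acyclic: generation strictly increases along parent edges
  gen_of <- stats::setNames(ind$generation, ind$id)
  kids <- ind[!is.na(ind$mother), ]
  expect_true(all(gen_of[kids$mother] < kids$generation))
  expect_true(all(gen_of[kids$father] < kids$generation))
  # explicit ancestor walk: nobody is its own ancestor
  mo <- stats::setNames(ind$mother, ind$id)
  fa <- stats::setNames(ind$father, ind$id)
  is_own_ancestor <- vapply(ind$id, function(i) {
    stack <- c(mo[[i]], fa[[i]])
    stack <- stack[!is.na(stack)]
    while (length(stack)) {
      cur <- stack[[1]]
      stack <- stack[-1]
      if (cur == i) return(TRUE)
      p <- c(mo[[cur]], fa[[cur]])
      stack <- c(stack, p[!is.na(p)])
    }
    FALSE
  }, logical(1))
  expect_false(any(is_own_ancestor))
})

test_that("a zero offspring rate yields a founders-only population", {
  cfg <- sim_config(n_founders_f = 5, n_founders_m = 5,
                    mean_offspring_per_mother = 0, seed = 1)
  set.seed(1)
  truth <- simulate_pedigree_population(cfg)
  expect_true(all(is.na(truth$individuals$mother)))
  expect_error(sim_config(n_generations = 1), "n_generations")
})

test_that("offspring counts follow the Poisson litter model", {
  cfg <- sim_config(n_founders_f = 100, n_founders_m = 50,
                    n_generations = 2, mean_offspring_per_mother = 2,
                    cub_prob = 0, seed = 8)
  set.seed(8)
  truth <- simulate_pedigree_population(cfg)
  n_off <- sum(!is.na(truth$individuals$mother))
  # oracle: 99% interval of Poisson(100 mothers x 2)
  expect_gte(n_off, qpois(0.005, 200))
  expect_lte(n_off, qpois(0.995, 200))
})

test_that("home ranges follow the sex-specific kernels", {
  cfg <- small_sim_config(seed = 3, disp_mean_f_km = 0, disp_mean_m_km = 0,
                          cub_prob = 0)
  set.seed(3)
  truth <- assign_home_ranges(simulate_pedigree_population(cfg), cfg)
  ind <- truth$individuals
  off <- ind[!is.na(ind$mother), ]
  mi <- match(off$mother, ind$id)
  expect_equal(off$x_m, ind$x_m[mi])
  expect_equal(off$y_m, ind$y_m[mi])

  # kernel magnitudes reproduce the configured male mean
  set.seed(42)
  mags <- draw_kernel_magnitude(10000, 33.8)
  se <- sd(mags) / sqrt(length(mags))
  expect_lt(abs(mean(mags) - 33.8), 2 * se)

  # direction is isotropic: mean displacement vector vanishes
  set.seed(7)
  theta <- runif(20000, 0, 2 * pi)
  m <- draw_kernel_magnitude(20000, 12.9)
  expect_lt(abs(mean(m * cos(theta))), 3 * sd(m * cos(theta)) / sqrt(20000))
  expect_lt(abs(mean(m * sin(theta))), 3 * sd(m * sin(theta)) / sqrt(20000))
})

test_that("error-free genotypes are Mendelian and replicate-identical", {
  cfg <- small_sim_config(seed = 11, epsilon = 0, dropout_rate = 0,
                          invalid_rate = 0)
  sim <- simulate_population(cfg)
  G <- sim$genotypes$true_genotypes
  ind <- sim$truth$individuals
  auto <- which(sim$panel$class == "autosomal")
  off <- which(!is.na(ind$mother))
  for (i in off) {
    mi <- match(ind$mother[i], ind$id)
    fi <- match(ind$father[i], ind$id)
    # opposite homozygotes with a true parent are impossible
    expect_false(any(abs(G[i, auto] - G[mi, auto]) == 2))
    expect_false(any(abs(G[i, auto] - G[fi, auto]) == 2))
  }
  # replicated samples of one individual agree exactly when error-free
  calls <- sim$genotypes$calls
  by_ind <- split(seq_len(nrow(calls)), sim$genotypes$samples$individual_id)
  for (rows in by_ind[lengths(by_ind) > 1]) {
    expect_true(all(apply(calls[rows, , drop = FALSE], 2, function(x)
      length(unique(x[!is.na(x)])) <= 1)))
  }
})

test_that("sex-linked and mitochondrial transmission rules hold", {
  cfg <- small_sim_config(seed = 13, epsilon = 0, dropout_rate = 0,
                          invalid_rate = 0)
  sim <- simulate_population(cfg)
  G <- sim$genotypes$true_genotypes
  ind <- sim$truth$individuals
  male <- ind$sex == "M"
  ycols <- which(sim$panel$class == "Y")
  xcols <- which(sim$panel$class == "X")
  mtcols <- which(sim$panel$class == "mtDNA")
  # Y present only in males; males never heterozygous on X
  expect_true(all(is.na(G[!male, ycols])))
  expect_true(all(G[male, ycols] %in% c(0, 2)))
  expect_false(any(G[male, xcols] == 1, na.rm = TRUE))
  # mtDNA pattern is matrilineally constant
  off <- which(!is.na(ind$mother))
  mi <- match(ind$mother[off], ind$id)
  expect_equal(G[off, mtcols], G[mi, mtcols], ignore_attr = TRUE)
  expect_equal(ind$mt_hap[off], ind$mt_hap[mi])
})

test_that("observed miscall and dropout rates match binomial oracles", {
  # package error process on replicated samples of founders; oracle is the
  # closed-form discordance expectation under the same per-allele model
  eps <- 0.01
  cfg <- sim_config(n_founders_f = 150, n_founders_m = 150,
                    n_generations = 2, mean_offspring_per_mother = 0,
                    L_autosomal = 100, maf_mean = 0.5, prop_sampled = 1,
                    epsilon = eps, dropout_rate = 0, invalid_rate = 0,
                    seed = 21)
  set.seed(21)
  panel <- make_marker_panel(auto_freq_a = rep(0.5, 100))
  truth <- assign_home_ranges(simulate_pedigree_population(cfg), cfg)
  ids <- truth$individuals$id
  samples <- data.frame(sample_id = paste0(rep(ids, each = 2), "_r", 1:2),
                        individual_id = rep(ids, each = 2))
  gt <- simulate_genotypes(truth, panel, samples, epsilon = eps,
                           dropout_rate = 0, invalid_rate = 0)
  est <- estimate_error_rates(gt)

  E <- genotype_error_matrix(eps)
  hw <- c(0.25, 0.5, 0.25)
  p_het <- sum(hw * (1 - (1 - E[, 2])^2))
  p_diff_het <- sum(hw * ((1 - rowSums(E^2)) - 2 * E[, 1] * E[, 3]))
  expected <- p_diff_het / p_het
  se <- sqrt(expected * (1 - expected) / est$n_het_comparisons)
  expect_lt(abs(est$error_rate - expected), 3 * se)

  # dropout: one-allele model turns d of true heterozygotes homozygous
  d <- 0.05
  gt2 <- simulate_genotypes(truth, panel, samples, epsilon = 0,
                            dropout_rate = d, invalid_rate = 0, seed = 22)
  est2 <- estimate_error_rates(gt2)
  expected_do <- d * (1 - d) / (1 - d^2)   # = d / (1 + d)
  se2 <- sqrt(expected_do * (1 - expected_do) / est2$n_het_comparisons)
  expect_lt(abs(est2$dropout_rate - 0.05), 3 * se2 + abs(expected_do - 0.05))
  # direct convergence of the het -> hom fraction to d
  auto <- which(panel$class == "autosomal")
  het_s <- gt2$true_genotypes[match(samples$individual_id, ids), auto] == 1
  frac_hom <- mean(gt2$calls[, auto][het_s] != 1)
  expect_lt(abs(frac_hom - d), 3 * sqrt(d * (1 - d) / sum(het_s)))
})

test_that("fecal sampling respects the count distribution and seed", {
  cfg <- small_sim_config(seed = 17, sample_scatter_km = 0, cub_prob = 0)
  sim <- simulate_population(cfg, genotypes = FALSE)
  s <- sim$samples
  ind <- sim$truth$individuals
  mi <- match(s$individual_id, ind$id)
  expect_equal(s$x_m, ind$x_m[mi])
  expect_equal(s$y_m, ind$y_m[mi])
  expect_lte(max(table(s$individual_id)), 19)

  sim2 <- simulate_population(cfg, genotypes = FALSE)
  expect_identical(sim$samples, sim2$samples)
})
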
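test_that("the genotype error model composes per-allele flips correctly", {
  expect_equal(genotype_error_matrix(0), diag(3), ignore_attr = TRUE)
  for (e in c(0.01, 0.1, 0.4)) {
    E <- genotype_error_matrix(e)
    expect_equal(unname(rowSums(E)), rep(1, 3))
  }
  # oracle: exhaustive enumeration of flips of the two alleles of AB
  e <- 0.01
  p_obs <- c(AA = 0, AB = 0, BB = 0)
  for (flip1 in 0:1) {
    for (flip2 in 0:1) {
      alleles <- c(if (flip1) "B" else "A", if (flip2) "A" else "B")
      obs <- paste(sort(alleles), collapse = "")
      pr <- e^flip1 * (1 - e)^(1 - flip1) * e^flip2 * (1 - e)^(1 - flip2)
      p_obs[obs] <- p_obs[obs] + pr
    }
  }
  expect_equal(unname(genotype_error_matrix(e)["AB", ]), unname(p_obs))
})

test_that("Mendelian transmission sums to one and matches textbook cases", {
  expect_equal(transmission_prob(1, 0, 2), 1)
  expect_equal(transmission_prob(0, 1, 1), 0.25)
  expect_equal(transmission_prob(1, 1, 1), 0.5)
  for (gm in 0:2) {
    for (gf in 0:2) {
      expect_equal(sum(vapply(0:2, transmission_prob, numeric(1),
                              g_m = gm, g_f = gf)), 1)
    }
  }
})

test_that("triad likelihoods detect exclusions and ignore locus order", {
  freq <- c(0.6, 0.4, 0.5)
  g_o <- c(0L, 1L, 2L)
  g_m <- c(0L, 1L, 2L)
  g_f <- c(0L, 1L, 2L)
  ll <- triad_loglik(g_o, g_m, g_f, freq, 0)
  expect_true(is.finite(ll))
  # opposite homozygotes at one locus exclude the trio outright
  expect_equal(triad_loglik(c(2L, 1L, 2L), g_m, g_f, freq, 0), -Inf)
  perm <- c(3, 1, 2)
  expect_equal(triad_loglik(g_o[perm], g_m[perm], g_f[perm], freq[perm], 0),
               ll)
})

test_that("dyad likelihood equals the HWE-marginalized triad at zero error", {
  freq <- c(0.6, 0.3)
  expect_equal(exp(dyad_loglik(c(0L, 0L), c(0L, 0L), freq, 0)),
               prod(freq))
  expect_equal(dyad_loglik(c(2L, 0L), c(0L, 0L), freq, 0), -Inf)
  hw <- function(g, p) c(p^2, 2 * p * (1 - p), (1 - p)^2)[g + 1]
  for (g_o in list(c(1L, 0L), c(2L, 1L))) {
    for (g_m in list(c(1L, 1L), c(2L, 0L))) {
      if (!is.finite(dyad_loglik(g_o, g_m, freq, 0))) next
      marg <- 0
      for (f1 in 0:2) {
        for (f2 in 0:2) {
          tl <- triad_loglik(g_o, g_m, c(f1, f2), freq, 0)
          marg <- marg + hw(f1, freq[1]) * hw(f2, freq[2]) * exp(tl)
        }
      }
      expect_equal(exp(dyad_loglik(g_o, g_m, freq, 0)), marg,
                   tolerance = 1e-10)
    }
  }
})

test_that("true triads outscore substituted mothers and orient correctly", {
  set.seed(55)
  freq <- 1 - simulate_allele_frequencies(87, 0.37)
  n <- 200
  mo <- hwe_genotypes(n, freq)
  fa <- hwe_genotypes(n, freq)
  off <- mendel_offspring(mo, fa)
  rand_f <- hwe_genotypes(n, freq)
  eps <- 4e-4
  beats <- orient <- logical(n)
  for (i in seq_len(n)) {
    true_ll <- triad_loglik(off[i, ], mo[i, ], fa[i, ], freq, eps)
    subst <- triad_loglik(off[i, ], rand_f[i, ], fa[i, ], freq, eps)
    beats[i] <- true_ll > subst
    orient[i] <- infer_triad_offspring(mo[i, ], fa[i, ], off[i, ],
                                       freq, eps) == 3L
  }
  expect_gte(mean(beats), 0.99)
  expect_gte(mean(orient), 0.99)
})

test_that("two unrelated individuals yield no retained assignment", {
  set.seed(60)
  freq <- 1 - simulate_allele_frequencies(87, 0.37)
  panel <- make_marker_panel(auto_freq_a = freq)
  L <- nrow(panel)
  calls <- matrix(NA_integer_, 2, L)
  auto <- which(panel$class == "autosomal")
  calls[, auto] <- hwe_genotypes(2, freq)
  gt <- make_gt(calls, c("A", "B"), panel)
  inds <- consolidate_replicates(gt)
  inds$info$sex <- c("F", "M")
  pr <- assign_parentage(inds, parentage_config(), freq_a = freq)
  expect_equal(nrow(pr$retained), 0)
})

test_that("per-focal hypothesis posteriors form a distribution", {
  cfg <- small_sim_config(seed = 61, epsilon = 0, dropout_rate = 0,
                          invalid_rate = 0)
  sim <- simulate_population(cfg)
  inds <- call_sexes(consolidate_replicates(sim$genotypes))
  pr <- assign_parentage(inds, parentage_config(), details = TRUE)
  sums <- vapply(pr$hypotheses, function(h) sum(h$posterior), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-8))
  expect_true(all(pr$assignments$posterior >= 0 &
                    pr$assignments$posterior <= 1))
})

test_that("pedigree assembly respects chains, slot limits and sex roles", {
  asn <- data.frame(
    offspring = c("b", "c"),
    mother = c("a", "b"), father = NA_character_,
    loglik = c(-10, -12), lr = c(20, 18), posterior = c(0.99, 0.98),
    mother_post = c(0.99, 0.98), father_post = NA_real_,
    arity = "dyad", stringsAsFactors = FALSE
  )
  sexes <- c(a = "F", b = "F", c = "F")
  ped <- assemble_pedigree(asn, sexes)
  expect_equal(nrow(ped$components), 1)
  expect_equal(ped$components$size, 3)
  expect_equal(ped$components$span, 3)

  # a conflicting second mother with weaker support is rejected
  asn2 <- rbind(asn, data.frame(
    offspring = "b", mother = "d", father = NA_character_,
    loglik = -15, lr = 10, posterior = 0.97, mother_post = 0.97,
    father_post = NA_real_, arity = "dyad", stringsAsFactors = FALSE))
  ped2 <- assemble_pedigree(asn2, c(sexes, d = "F"))
  expect_equal(ped2$parents$mother[ped2$parents$id == "b"], "a")

  # a male cannot take the mother slot
  asn3 <- asn
  asn3$mother[1] <- "m"
  ped3 <- assemble_pedigree(asn3, c(sexes, m = "M"))
  expect_true(is.na(ped3$parents$mother[ped3$parents$id == "b"]))
})

test_that("random assignment orders never produce cycles or double mothers", {
  set.seed(70)
  ids <- paste0("i", 1:12)
  for (rep in 1:25) {
    n <- 20
    asn <- data.frame(
      offspring = sample(ids, n, replace = TRUE),
      mother = sample(ids, n, replace = TRUE),
      father = NA_character_,
      loglik = rnorm(n), lr = runif(n, 0, 30), posterior = runif(n),
      mother_post = runif(n), father_post = NA_real_,
      arity = "dyad", stringsAsFactors = FALSE
    )
    asn <- asn[asn$offspring != asn$mother, ]
    sexes <- stats::setNames(rep("F", 12), ids)
    ped <- assemble_pedigree(asn, sexes)
    pr <- ped$parents
    expect_true(all(table(pr$id) == 1))
    mo <- stats::setNames(pr$mother, pr$id)
    fa <- stats::setNames(pr$father, pr$id)
    for (i in pr$id) {
      expect_false(kindisp:::.is_ancestor(i, i, mo, fa))
    }
  }
})

test_that("dyads orient only under structural constraint", {
  # isolated dyad: either direction is possible, so it stays unoriented
  asn <- data.frame(
    offspring = "b", mother = "a", father = NA_character_,
    loglik = -10, lr = 20, posterior = 0.99, mother_post = 0.99,
    father_post = NA_real_, arity = "dyad", stringsAsFactors = FALSE)
  ped <- orient_dyads(assemble_pedigree(asn, c(a = "F", b = "F")))
  expect_false(ped$parents$mother_oriented[ped$parents$id == "b"])

  # if the assigned parent already has a mother, a female focal cannot be
  # re-parented onto it: the dyad direction is forced
  asn2 <- rbind(asn, data.frame(
    offspring = "a", mother = "g", father = NA_character_,
    loglik = -9, lr = 25, posterior = 0.99, mother_post = 0.99,
    father_post = NA_real_, arity = "dyad", stringsAsFactors = FALSE))
  ped2 <- orient_dyads(assemble_pedigree(asn2, c(a = "F", b = "F",
                                                 g = "F")))
  expect_true(ped2$parents$mother_oriented[ped2$parents$id == "b"])

  # triad offspring are oriented by construction
  asn3 <- data.frame(
    offspring = "o", mother = "a", father = "f",
    loglik = -10, lr = 30, posterior = 0.99, mother_post = 0.99,
    father_post = 0.99, arity = "triad", stringsAsFactors = FALSE)
  ped3 <- orient_dyads(assemble_pedigree(asn3, c(a = "F", f = "M",
                                                 o = "F")))
  expect_true(ped3$parents$mother_oriented[ped3$parents$id == "o"])
})

test_that("assignment recall degrades as sampling proportion drops", {
  recall_at <- function(prop, seed) {
    cfg <- sim_config(n_founders_f = 18, n_founders_m = 15,
                      n_generations = 2, mean_offspring_per_mother = 2,
                      prop_sampled = prop, epsilon = 0, dropout_rate = 0,
                      invalid_rate = 0, seed = seed)
    sim <- simulate_population(cfg)
    inds <- call_sexes(consolidate_replicates(sim$genotypes))
    pr <- assign_parentage(inds, parentage_config())
    truth <- sim$truth$individuals
    off <- truth[!is.na(truth$mother) & truth$sampled, ]
    if (nrow(off) == 0) return(NA_real_)
    got <- pr$retained$mother[match(off$id, pr$retained$offspring)]
    mean(!is.na(got) & got == off$mother)
  }
  seeds <- 1:5
  rec <- vapply(c(1, 0.6, 0.3), function(p)
    mean(vapply(seeds, function(s) recall_at(p, s), numeric(1)),
         na.rm = TRUE), numeric(1))
  expect_true(all(diff(rec) < 0))
})
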
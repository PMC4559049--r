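test_that("median centers are robust coordinate-wise medians", {
  expect_equal(median_center(rbind(c(0, 0))), c(0, 0))
  expect_equal(median_center(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))),
               c(1, 1))
  expect_equal(median_center(rbind(c(0, 0), c(1, 1), c(100, 100))), c(1, 1))
  expect_error(median_center(matrix(numeric(0), 0, 2)), "empty")

  # the coordinate-wise median minimizes the per-axis L1 objective
  set.seed(3)
  pts <- cbind(runif(7, 0, 10), runif(7, 0, 10))
  ctr <- median_center(pts)
  obj <- function(x, y) sum(abs(pts[, 1] - x)) + sum(abs(pts[, 2] - y))
  grid <- expand.grid(x = seq(0, 10, 0.05), y = seq(0, 10, 0.05))
  best <- min(mapply(obj, grid$x, grid$y))
  expect_lte(obj(ctr[1], ctr[2]), best + 1e-9)
})

test_that("Euclidean distances convert meters to kilometers", {
  expect_equal(euclidean_km(c(0, 0), c(3000, 4000)), 5)
  expect_equal(euclidean_km(c(10, 20), c(10, 20)), 0)
  expect_equal(euclidean_km(c(0, 0), c(1, 1)), euclidean_km(c(1, 1), c(0, 0)))

  centers <- data.frame(individual_id = c("a", "b", "c"),
                        x_m = c(0, 3000, 0), y_m = c(0, 4000, 1000))
  D <- distance_matrix_km(centers)
  expect_equal(D["a", "b"], 5)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
})

test_that("the Mantel statistic and exact p-value match enumeration", {
  set.seed(5)
  X <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(dist(X))
  R <- -D
  res <- mantel_test(D, R, n_perm = 99, seed = 1)
  expect_equal(res$statistic, -1)

  # oracle: enumerate the 24 relabelings by hand-rolled recursion
  perms_of <- function(n) {
    if (n == 1) return(list(1))
    do.call(c, lapply(seq_len(n), function(i) {
      lapply(perms_of(n - 1), function(p) c(i, seq_len(n)[-i][p]))
    }))
  }
  n <- 4
  D4 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  R4 <- matrix(rnorm(16), 4, 4)
  R4 <- (R4 + t(R4)) / 2
  diag(R4) <- 0
  ut <- upper.tri(D4)
  obs <- cor(D4[ut], R4[ut])
  stats_all <- vapply(perms_of(n), function(p)
    cor(D4[ut], R4[p, p][ut]), numeric(1))
  for (alt in c("greater", "less", "two.sided")) {
    expected_p <- switch(alt,
      greater = mean(stats_all >= obs - 1e-12),
      less = mean(stats_all <= obs + 1e-12),
      two.sided = mean(abs(stats_all) >= abs(obs) - 1e-12))
    res4 <- mantel_test(D4, R4, alternative = alt, exact = TRUE)
    expect_equal(res4$p_value, expected_p)
    expect_equal(res4$n_perm, 24)
  }
  expect_error(mantel_test(matrix(1, 4, 4), R4), "constant")
})

test_that("the Mantel statistic is invariant to joint relabeling", {
  set.seed(9)
  D <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  R <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
  perm <- sample(10)
  a <- mantel_test(D, R, n_perm = 9, seed = 1)$statistic
  b <- mantel_test(D[perm, perm], R[perm, perm], n_perm = 9,
                   seed = 1)$statistic
  expect_equal(a, b)
})

test_that("the Mantel statistic agrees with vegan", {
  skip_if_not_installed("vegan")
  set.seed(12)
  D <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  R <- as.matrix(dist(matrix(rnorm(30), 15, 2)))
  ours <- mantel_test(D, R, n_perm = 99, seed = 1)$statistic
  theirs <- vegan::mantel(D, R, permutations = 0)$statistic
  expect_equal(ours, unname(theirs), tolerance = 1e-12)
})

test_that("sex-stratified IBD reports the expected pair counts", {
  set.seed(20)
  nf <- 86
  nm <- 55
  ids <- c(sprintf("f%02d", 1:nf), sprintf("m%02d", 1:nm))
  sexes <- stats::setNames(c(rep("F", nf), rep("M", nm)), ids)
  centers <- data.frame(individual_id = ids,
                        x_m = runif(nf + nm, 0, 2e5),
                        y_m = runif(nf + nm, 0, 2e5))
  n <- nf + nm
  R <- matrix(rnorm(n * n, 0, 0.1), n, n,
              dimnames = list(ids, ids))
  R <- (R + t(R)) / 2
  diag(R) <- NA
  out <- ibd_by_sex(centers, R, sexes, parents = ids, n_perm = 19)
  expect_equal(out$n_pairs[out$stratum == "all"], choose(141, 2))  # 9870
  expect_equal(out$n_pairs[out$stratum == "FF"], choose(86, 2))    # 3655
  expect_equal(out$n_pairs[out$stratum == "MM"], choose(55, 2))    # 1485
  expect_equal(out$n_pairs[out$stratum == "FM"], 86 * 55)          # 4730
  expect_true(all(out$mantel_p[!is.na(out$mantel_p)] > 0 &
                    out$mantel_p[!is.na(out$mantel_p)] <= 1))

  expect_warning(
    ibd_by_sex(centers[1:4, ], R[1:4, 1:4], sexes[1:4],
               parents = ids[1:4], n_perm = 19),
    "fewer than 3")
})

test_that("female philopatry produces stronger female-female IBD", {
  # strong female isolation by distance, none for males
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    nf <- 40
    nm <- 40
    ids <- c(sprintf("f%02d", 1:nf), sprintf("m%02d", 1:nm))
    sexes <- stats::setNames(c(rep("F", nf), rep("M", nm)), ids)
    centers <- data.frame(individual_id = ids,
                          x_m = runif(nf + nm, 0, 1e5),
                          y_m = runif(nf + nm, 0, 1e5))
    D <- distance_matrix_km(centers)
    R <- matrix(rnorm((nf + nm)^2, 0, 0.03), nf + nm,
                dimnames = list(ids, ids))
    R <- (R + t(R)) / 2
    fem <- seq_len(nf)
    R[fem, fem] <- R[fem, fem] - 0.001 * D[fem, fem]  # females: r falls with km
    out <- ibd_by_sex(centers, R, sexes, parents = ids, n_perm = 99,
                      seed = s)
    ff <- out[out$stratum == "FF", ]
    mm <- out[out$stratum == "MM", ]
    if (ff$mantel_r < mm$mantel_r && ff$mantel_p < 0.05 &&
        mm$mantel_p > 0.05) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_seeds, 0.8)
})
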
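# Home-range centers from fecal sample sites, pairwise distances, and
# isolation-by-distance (Mantel / Pearson) tests stratified by sex.

#' Median center of a set of points
#'
#' Coordinate-wise median (for an even number of points, the midpoint of
#' the two central values per axis), a home-range center estimate that is
#' insensitive to occasional excursions outside the range. A single point
#' is returned unchanged.
#'
#' @param points Two-column matrix or data frame of planar coordinates.
#' @return Numeric length-2 vector (x, y).
#' @examples
#' median_center(rbind(c(0, 0), c(1, 1), c(100, 100)))
#' @export
median_center <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("median center of an empty point set")
  c(stats::median(points[, 1]), stats::median(points[, 2]))
}

#' Home-range centers for all individuals
#'
#' @param samples Data frame with columns `individual_id`, `x_m`, `y_m`.
#' @return Data frame `individual_id`, `x_m`, `y_m`, `n_points`.
#' @export
compute_centers <- function(samples) {
  groups <- split(samples, samples$individual_id)
  out <- do.call(rbind, lapply(groups, function(g) {
    ctr <- median_center(g[, c("x_m", "y_m")])
    data.frame(individual_id = g$individual_id[1],
               x_m = ctr[1], y_m = ctr[2], n_points = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Euclidean distance in kilometers
#'
#' Planar (Pythagorean) distance between two points given in meters, e.g.
#' projected RT90-style coordinates.
#'
#' @param a,b Length-2 numeric vectors (x, y) in meters.
#' @return Distance in km.
#' @export
euclidean_km <- function(a, b) {
  sqrt(sum((a - b)^2)) / 1000
}

#' Pairwise distance matrix in kilometers
#'
#' @param centers Data frame with `individual_id`, `x_m`, `y_m`.
#' @return Symmetric matrix of km distances with zero diagonal.
#' @export
distance_matrix_km <- function(centers) {
  D <- as.matrix(stats::dist(centers[, c("x_m", "y_m")])) / 1000
  dimnames(D) <- list(centers$individual_id, centers$individual_id)
  D
}

#' Mantel permutation test
#'
#' Tests the association between two symmetric matrices. The statistic is
#' the Pearson correlation of the upper-triangle entries; the null
#' distribution is built by jointly permuting the rows and columns of the
#' second matrix. The p-value is `(1 + k) / (n_perm + 1)` where `k` counts
#' permuted statistics at least as extreme as the observed one under
#' `alternative` (`"auto"`, the default, tests one-sided in the direction
#' of the observed sign). With `exact = TRUE` all `n!` relabelings are
#' enumerated instead and the p-value is the exact fraction of relabelings
#' (including the identity) at least as extreme.
#'
#' @param D,R Symmetric numeric matrices of equal order (n >= 3).
#' @param n_perm Number of random permutations.
#' @param seed Optional seed for the permutation draw.
#' @param alternative `"auto"`, `"two.sided"`, `"less"` or `"greater"`.
#' @param exact Enumerate all permutations (feasible for small n).
#' @return List with `statistic`, `p_value`, `alternative`, `n_perm`.
#' @export
mantel_test <- function(D, R, n_perm = 999, seed = NULL,
                        alternative = c("auto", "two.sided", "less",
                                        "greater"),
                        exact = FALSE) {
  alternative <- match.arg(alternative)
  D <- as.matrix(D)
  R <- as.matrix(R)
  n <- nrow(D)
  stopifnot(n >= 3, all(dim(D) == n), all(dim(R) == n))
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(D)
  if (stats::sd(D[ut]) == 0 || stats::sd(R[ut]) == 0) {
    stop("constant matrix: Mantel correlation undefined")
  }
  obs <- stats::cor(D[ut], R[ut])
  if (alternative == "auto") {
    alternative <- if (obs < 0) "less" else "greater"
  }
  extreme <- switch(alternative,
    two.sided = function(s) abs(s) >= abs(obs) - 1e-12,
    less = function(s) s <= obs + 1e-12,
    greater = function(s) s >= obs - 1e-12
  )
  stat_of <- function(perm) stats::cor(D[ut], R[perm, perm][ut])

  if (exact) {
    perms <- .all_permutations(n)
    stats_all <- vapply(perms, stat_of, numeric(1))
    p <- mean(extreme(stats_all))
    n_used <- length(perms)
  } else {
    stats_all <- vapply(seq_len(n_perm), function(i) {
      stat_of(sample.int(n))
    }, numeric(1))
    p <- (1 + sum(extreme(stats_all))) / (n_perm + 1)
    n_used <- n_perm
  }
  list(statistic = obs, p_value = p, alternative = alternative,
       n_perm = n_used)
}

# all permutations of 1..n as a list (n small)
.all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (tail in .all_permutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1]] <- c(i, rest[tail])
    }
  }
  out
}

#' Isolation by distance stratified by sex
#'
#' Runs the isolation-by-distance analyses of a pedigree-based dispersal
#' study on the individuals identified as putative parents: Mantel tests of
#' pairwise Euclidean distance against pairwise relatedness for all pairs,
#' female-female pairs and male-male pairs, plus a Pearson correlation for
#' each stratum and for opposite-sex pairs (whose pair set is an
#' asymmetric rectangle, so no Mantel test applies).
#'
#' @param centers Data frame `individual_id`, `x_m`, `y_m`.
#' @param rmat A `relatedness_matrix` (or plain symmetric matrix with
#'   dimnames) covering the individuals.
#' @param sexes Named vector of `"F"`/`"M"` per individual.
#' @param parents Character vector of putative-parent ids to analyze.
#' @param n_perm,seed Passed to [mantel_test()].
#' @return Data frame with one row per stratum (`all`, `FF`, `MM`, `FM`):
#'   `n_ind`, `n_pairs`, `mantel_r`, `mantel_p`, `pearson_r`.
#' @export
ibd_by_sex <- function(centers, rmat, sexes, parents,
                       n_perm = 999, seed = NULL) {
  R <- if (inherits(rmat, "relatedness_matrix")) rmat$r else as.matrix(rmat)
  ids <- intersect(parents, centers$individual_id)
  ids <- intersect(ids, rownames(R))
  centers <- centers[match(ids, centers$individual_id), , drop = FALSE]
  D <- distance_matrix_km(centers)
  R <- R[ids, ids]
  sx <- sexes[ids]
  if (!is.null(seed)) set.seed(seed)

  stratum <- function(name, sub) {
    if (length(sub) < 3) {
      warning("stratum ", name, " has fewer than 3 individuals; skipped")
      return(NULL)
    }
    Ds <- D[sub, sub]
    Rs <- R[sub, sub]
    off_diag_na <- is.na(Rs)
    diag(off_diag_na) <- FALSE
    drop_na <- rowSums(off_diag_na) > 0
    if (any(drop_na)) {
      Ds <- Ds[!drop_na, !drop_na]
      Rs <- Rs[!drop_na, !drop_na]
    }
    if (nrow(Ds) < 3) {
      warning("stratum ", name, " has fewer than 3 individuals; skipped")
      return(NULL)
    }
    m <- mantel_test(Ds, Rs, n_perm = n_perm)
    ut <- upper.tri(Ds)
    data.frame(stratum = name, n_ind = nrow(Ds),
               n_pairs = sum(ut), mantel_r = m$statistic,
               mantel_p = m$p_value,
               pearson_r = stats::cor(Ds[ut], Rs[ut]),
               stringsAsFactors = FALSE)
  }
  fem <- ids[sx == "F"]
  mal <- ids[sx == "M"]
  out <- rbind(stratum("all", ids), stratum("FF", fem), stratum("MM", mal))

  if (length(fem) >= 1 && length(mal) >= 1) {
    Dr <- D[fem, mal, drop = FALSE]
    Rr <- R[fem, mal, drop = FALSE]
    keep <- !is.na(Rr)
    out <- rbind(out, data.frame(
      stratum = "FM", n_ind = length(fem) + length(mal),
      n_pairs = sum(keep), mantel_r = NA_real_, mantel_p = NA_real_,
      pearson_r = stats::cor(Dr[keep], Rr[keep]),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
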
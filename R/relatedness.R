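# Pairwise Lynch-Ritland relatedness with locus weighting, plus pedigree
# relationship categories for comparing r against expectation.

#' Estimate allele frequencies from genotypes
#'
#' @param G Integer genotype matrix (individuals x loci, B-allele counts;
#'   missing/invalid ignored).
#' @return Vector of A-allele frequencies per locus.
#' @export
estimate_allele_freqs <- function(G) {
  freq_b <- apply(G, 2, function(g) {
    g <- g[geno_valid(g)]
    if (length(g) == 0) NA_real_ else mean(g) / 2
  })
  1 - freq_b
}

#' Lynch-Ritland relatedness for one pair
#'
#' Computes the locus-weighted Lynch-Ritland regression estimator of
#' relatedness. With reference individual x carrying alleles (a, b) and the
#' other individual y carrying (c, d), the single-locus estimate is
#' \deqn{\hat r_x = \frac{p_a(S_{bc}+S_{bd}) + p_b(S_{ac}+S_{ad}) -
#'   4 p_a p_b}{(1+S_{ab})(p_a+p_b) - 4 p_a p_b}}
#' where S is the allele-identity indicator. Loci are combined with the
#' Lynch-Ritland weights (the denominator scaled by \eqn{1/(2 p_a p_b)}),
#' i.e. the multilocus estimate is the ratio of the summed scaled numerators
#' to the summed scaled denominators. The reported value is the arithmetic
#' mean of the two reciprocal estimates (x as reference, then y). Loci with
#' a missing call in either individual, or monomorphic in the frequency
#' vector, are excluded from both sums.
#'
#' @param gx,gy Integer genotype codes over the same autosomal loci.
#' @param freq_a A-allele frequency per locus (estimated from the sample;
#'   see [estimate_allele_freqs()]).
#' @return The symmetrized estimate, with the number of loci used attached
#'   as attribute `"n_loci"`.
#' @examples
#' lynch_ritland_pair(c(0, 1), c(0, 1), freq_a = c(0.5, 0.6))
#' @export
lynch_ritland_pair <- function(gx, gy, freq_a) {
  stopifnot(length(gx) == length(gy), length(gx) == length(freq_a))
  usable <- geno_valid(gx) & geno_valid(gy) &
    !is.na(freq_a) & freq_a > 0 & freq_a < 1
  if (!any(usable)) stop("no shared valid loci: relatedness undefined")
  one_direction <- function(gref, goth) {
    num <- den <- 0
    for (l in which(usable)) {
      # allele states of the reference (1 = A, 2 = B) and their frequencies
      ref <- c(if (gref[l] <= 1) 1 else 2, if (gref[l] >= 1) 2 else 1)
      oth <- c(if (goth[l] <= 1) 1 else 2, if (goth[l] >= 1) 2 else 1)
      p <- c(freq_a[l], 1 - freq_a[l])
      pa <- p[ref[1]]
      pb <- p[ref[2]]
      S <- function(u, v) as.numeric(u == v)
      nl <- pa * (S(ref[2], oth[1]) + S(ref[2], oth[2])) +
        pb * (S(ref[1], oth[1]) + S(ref[1], oth[2])) - 4 * pa * pb
      dl <- (1 + S(ref[1], ref[2])) * (pa + pb) - 4 * pa * pb
      w <- 2 * pa * pb
      num <- num + nl / w
      den <- den + dl / w
    }
    num / den
  }
  r <- (one_direction(gx, gy) + one_direction(gy, gx)) / 2
  attr(r, "n_loci") <- sum(usable)
  r
}

# per-locus lookup tables for the vectorized estimator: rows/cols indexed by
# genotype state 1..4 (1 = AA, 2 = AB, 3 = BB, 4 = missing); scaled
# numerator depends on both genotypes, scaled denominator on the reference
.lr_tables <- function(p) {
  q <- 1 - p
  num <- matrix(0, 4, 4)
  den <- matrix(0, 4, 4)
  ka <- c(2, 1, 0)   # A alleles in the other individual's genotype
  for (gy in 1:3) {
    num[1, gy] <- ka[gy] / p - 2
    num[3, gy] <- (2 - ka[gy]) / q - 2
    num[2, gy] <- (p * (2 - ka[gy]) + q * ka[gy] - 4 * p * q) / (2 * p * q)
  }
  den[1, 1:3] <- 2 * q / p
  den[3, 1:3] <- 2 * p / q
  den[2, 1:3] <- (1 - 4 * p * q) / (2 * p * q)
  list(num = num, den = den)
}

#' Lynch-Ritland relatedness for matched pairs
#'
#' Vectorized version of [lynch_ritland_pair()] for row-matched genotype
#' matrices: pair `i` is (`GX[i, ]`, `GY[i, ]`).
#'
#' @param GX,GY Integer genotype matrices (pairs x loci).
#' @param freq_a Per-locus A-allele frequencies.
#' @return Numeric vector of symmetrized estimates, one per pair.
#' @export
lynch_ritland_pairs <- function(GX, GY, freq_a) {
  stopifnot(all(dim(GX) == dim(GY)), ncol(GX) == length(freq_a))
  n <- nrow(GX)
  usable <- !is.na(freq_a) & freq_a > 0 & freq_a < 1
  NUMx <- DENx <- NUMy <- DENy <- numeric(n)
  for (l in which(usable)) {
    tabs <- .lr_tables(freq_a[l])
    sx <- ifelse(geno_valid(GX[, l]), GX[, l] + 1L, 4L)
    sy <- ifelse(geno_valid(GY[, l]), GY[, l] + 1L, 4L)
    idx <- cbind(sx, sy)
    NUMx <- NUMx + tabs$num[idx]
    DENx <- DENx + tabs$den[idx]
    idx2 <- cbind(sy, sx)
    NUMy <- NUMy + tabs$num[idx2]
    DENy <- DENy + tabs$den[idx2]
  }
  (NUMx / DENx + NUMy / DENy) / 2
}

#' Pairwise Lynch-Ritland relatedness matrix
#'
#' Computes the symmetrized, locus-weighted Lynch-Ritland estimate for every
#' pair of individuals (n(n-1)/2 pairs) over the autosomal loci.
#'
#' @param x An `individual_set`, or an integer genotype matrix of autosomal
#'   B-allele counts (individuals x loci).
#' @param freq_a Per-locus A-allele frequencies; defaults to frequencies
#'   estimated from `x` itself (all individuals, no exclusion of the pair
#'   under evaluation).
#' @return List of class `relatedness_matrix`: `r` (symmetric matrix, NA
#'   diagonal), `n_loci` (loci used per pair), `freq_a`.
#' @export
relatedness_matrix <- function(x, freq_a = NULL) {
  if (inherits(x, "individual_set")) {
    G <- x$genotypes[, panel_cols(x$panel, "autosomal"), drop = FALSE]
  } else {
    G <- x
  }
  n <- nrow(G)
  if (n < 2) stop("need at least two individuals")
  if (is.null(freq_a)) freq_a <- estimate_allele_freqs(G)
  usable_locus <- !is.na(freq_a) & freq_a > 0 & freq_a < 1

  NUM <- DEN <- CNT <- matrix(0, n, n)
  for (l in which(usable_locus)) {
    tabs <- .lr_tables(freq_a[l])
    g <- G[, l]
    state <- ifelse(geno_valid(g), g + 1L, 4L)
    NUM <- NUM + tabs$num[state, state]
    DEN <- DEN + tabs$den[state, state]
    v <- state != 4L
    CNT <- CNT + (v %o% v)
  }
  RX <- NUM / DEN                      # reference individual in rows
  R <- (RX + t(RX)) / 2
  R[CNT == 0] <- NA
  diag(R) <- NA
  diag(CNT) <- 0
  dimnames(R) <- dimnames(CNT) <- list(rownames(G), rownames(G))
  out <- list(r = R, n_loci = CNT, freq_a = freq_a)
  class(out) <- "relatedness_matrix"
  out
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  v <- x$r[upper.tri(x$r)]
  cat("<relatedness_matrix> ", nrow(x$r), " individuals, ",
      sum(!is.na(v)), " pairs; mean r = ",
      round(mean(v, na.rm = TRUE), 4), " (SD ",
      round(stats::sd(v, na.rm = TRUE), 4), ")\n", sep = "")
  invisible(x)
}

#' Classify pairs by pedigree relationship
#'
#' Derives relationship categories from a parent table: `PO`
#' (parent-offspring edge), `FS` (both parents shared and known), `HS`
#' (exactly one parent shared), `GG` (grandparent-grandchild), `MT` (mates:
#' at least one common offspring). Each pair receives the closest applicable
#' category in that priority order; unrelated pairs get `NA`.
#'
#' @param parents Data frame with columns `id`, `mother`, `father`.
#' @param ids Optional subset of individuals to consider (default: all).
#' @return Data frame `id1`, `id2`, `category` for every unordered pair.
#' @export
categorize_pairs <- function(parents, ids = parents$id) {
  mo <- stats::setNames(parents$mother, parents$id)
  fa <- stats::setNames(parents$father, parents$id)
  par_of <- function(i) c(mo[[i]], fa[[i]])
  gp_of <- function(i) {
    p <- par_of(i)
    unlist(lapply(p[!is.na(p) & p %in% names(mo)], par_of))
  }
  kids <- split(parents$id, list(
    m = ifelse(is.na(parents$mother), "", parents$mother),
    f = ifelse(is.na(parents$father), "", parents$father)),
    drop = TRUE)

  classify <- function(a, b) {
    pa <- par_of(a)
    pb <- par_of(b)
    if ((!is.na(pa[1]) && pa[1] == b) || (!is.na(pa[2]) && pa[2] == b) ||
        (!is.na(pb[1]) && pb[1] == a) || (!is.na(pb[2]) && pb[2] == a)) {
      return("PO")
    }
    shared <- sum(!is.na(pa) & !is.na(pb) & pa == pb)
    if (shared == 2) return("FS")
    if (shared == 1) return("HS")
    ga <- gp_of(a)
    gb <- gp_of(b)
    if ((length(ga) && b %in% ga) || (length(gb) && a %in% gb)) {
      return("GG")
    }
    mated <- any(vapply(kids, function(k) {
      any(mo[k] == a & fa[k] == b, na.rm = TRUE) ||
        any(mo[k] == b & fa[k] == a, na.rm = TRUE)
    }, logical(1)))
    if (mated) return("MT")
    NA_character_
  }

  pairs <- utils::combn(ids, 2)
  data.frame(
    id1 = pairs[1, ], id2 = pairs[2, ],
    category = vapply(seq_len(ncol(pairs)), function(k) {
      classify(pairs[1, k], pairs[2, k])
    }, character(1)),
    stringsAsFactors = FALSE
  )
}
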
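# Marker panel: locus metadata and population allele frequencies.
#
# Genotype coding used throughout the package: integer count of the B allele
# (0 = A/A, 1 = A/B, 2 = B/B), NA = missing ("no call"), -1 = invalid
# (ambiguous cluster; excluded from every statistic but counted separately
# from missing in the call rate). Haploid calls (Y, mtDNA, male X) are stored
# as the matching homozygote code (0 or 2).

#' Construct a SNP marker panel
#'
#' A marker panel describes the loci of a genotyping assay: an identifier,
#' a class (`autosomal`, `X`, `Y` or `mtDNA`), and the population frequency
#' of the A allele. The default layout mirrors a 96-SNP noninvasive panel:
#' 87 autosomal loci, 3 X-linked loci, 2 Y-linked loci and 4 diagnostic
#' mitochondrial loci.
#'
#' @param auto_freq_a Numeric vector of A-allele frequencies for the
#'   autosomal loci, each in (0, 1). By convention A is the major allele, so
#'   the minor allele frequency of locus `l` is `1 - auto_freq_a[l]`.
#' @param x_freq_a A-allele frequencies for the X-linked loci.
#' @param y_freq_a A-allele frequencies for the Y-linked loci (frequency of
#'   the A state among male haplotypes).
#' @param n_mt Number of diagnostic mitochondrial loci.
#' @return An object of class `marker_panel`: a data frame with columns
#'   `locus_id`, `class` and `freq_a` (NA for mtDNA loci, whose states are
#'   set by the haplotype key; see [default_mt_key()]).
#' @examples
#' panel <- make_marker_panel(auto_freq_a = rep(0.63, 87))
#' table(panel$class)
#' @export
make_marker_panel <- function(auto_freq_a,
                              x_freq_a = c(0.6, 0.7, 0.5),
                              y_freq_a = c(0.7, 0.4),
                              n_mt = 4) {
  stopifnot(length(auto_freq_a) >= 1, n_mt >= 1)
  if (any(auto_freq_a <= 0 | auto_freq_a >= 1) ||
      any(x_freq_a <= 0 | x_freq_a >= 1) ||
      any(y_freq_a <= 0 | y_freq_a >= 1)) {
    stop("allele frequencies must lie strictly inside (0, 1)")
  }
  df <- data.frame(
    locus_id = c(
      sprintf("auto%03d", seq_along(auto_freq_a)),
      sprintf("x%02d", seq_along(x_freq_a)),
      sprintf("y%02d", seq_along(y_freq_a)),
      sprintf("mt%02d", seq_len(n_mt))
    ),
    class = c(
      rep("autosomal", length(auto_freq_a)),
      rep("X", length(x_freq_a)),
      rep("Y", length(y_freq_a)),
      rep("mtDNA", n_mt)
    ),
    freq_a = c(auto_freq_a, x_freq_a, y_freq_a, rep(NA_real_, n_mt)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("marker_panel", "data.frame")
  df
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", nrow(x), " loci: ",
      paste(sprintf("%d %s", as.integer(table(x$class)[unique(x$class)]),
                    unique(x$class)), collapse = ", "), "\n", sep = "")
  auto <- x$freq_a[x$class == "autosomal"]
  cat("  mean autosomal MAF: ", round(mean(1 - auto), 3), "\n", sep = "")
  invisible(x)
}

#' Simulate per-locus minor allele frequencies
#'
#' Draws minor allele frequencies on (0, 0.5] from a scaled Beta
#' distribution whose mean equals `maf_mean`, emulating a panel selected
#' for common, informative SNPs.
#'
#' @param L Number of loci (>= 1).
#' @param maf_mean Target mean minor allele frequency, in (0, 0.5].
#' @param seed Optional integer seed for reproducible draws.
#' @param concentration Beta concentration (a + b); larger values give
#'   frequencies tighter around the mean.
#' @return Numeric vector of length `L` with values in (0, 0.5].
#' @examples
#' maf <- simulate_allele_frequencies(87, 0.37, seed = 1)
#' mean(maf)
#' @export
simulate_allele_frequencies <- function(L, maf_mean, seed = NULL,
                                        concentration = 10) {
  stopifnot(L >= 1)
  if (!is.numeric(maf_mean) || maf_mean <= 0 || maf_mean > 0.5) {
    stop("maf_mean must lie in (0, 0.5]")
  }
  if (!is.null(seed)) set.seed(seed)
  m <- maf_mean / 0.5
  if (m >= 1) return(rep(0.5, L))
  a <- concentration * m
  b <- concentration * (1 - m)
  0.5 * stats::rbeta(L, a, b)
}

#' Multilocus probability of identity
#'
#' Probability that two individuals drawn at random from a population in
#' Hardy-Weinberg equilibrium share an identical multilocus genotype,
#' computed as the product over unlinked biallelic loci of
#' \eqn{p^4 + 4 p^2 q^2 + q^4}.
#'
#' @param freq_a Vector of A-allele frequencies, one per locus (the formula
#'   is symmetric in `p` and `q`, so either allele's frequency may be given).
#' @return A single probability; the per-locus factors are attached as the
#'   `"per_locus"` attribute.
#' @examples
#' pid_identity(0.5)              # one maximally informative locus: 0.375
#' pid_identity(rep(0.63, 87))    # an 87-locus panel at MAF 0.37
#' @export
pid_identity <- function(freq_a) {
  stopifnot(is.numeric(freq_a), all(freq_a >= 0 & freq_a <= 1))
  p <- freq_a
  q <- 1 - p
  per_locus <- p^4 + 4 * p^2 * q^2 + q^4
  out <- prod(per_locus)
  attr(out, "per_locus") <- per_locus
  out
}

#' Default mitochondrial haplotype key
#'
#' Maps four-locus mitochondrial allele patterns to regional haplotype
#' labels. Patterns are character vectors of `"A"`/`"B"` states, one per
#' mtDNA locus in panel order.
#'
#' @return Named list of allele-state patterns.
#' @export
default_mt_key <- function() {
  list(
    south  = c("A", "A", "A", "A"),
    middle = c("B", "B", "A", "A"),
    north  = c("B", "B", "B", "B")
  )
}

# Internal helpers shared across modules -------------------------------------

# TRUE where a call is a valid genotype (not missing, not invalid)
geno_valid <- function(g) !is.na(g) & g >= 0L

# columns of a call matrix belonging to a panel class
panel_cols <- function(panel, classes) which(panel$class %in% classes)
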
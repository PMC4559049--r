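# Genotype quality control: replicate consolidation, error and dropout
# rates, Y/X sex calling, mtDNA haplotype assignment and panel summaries.

#' Consolidate replicated samples into individuals
#'
#' Samples sharing a replicate group (here: an individual id) are reduced to
#' one consensus genotype per locus by majority vote over valid calls; ties
#' become missing. Groups whose replicates disagree at more than
#' `mismatch_threshold` of pairwise-comparable autosomal loci are flagged as
#' probable contamination and dropped.
#'
#' @param gt A `genotype_table` (see [simulate_genotypes()] or
#'   [read_genotypes()]).
#' @param mismatch_threshold Maximum tolerated mean pairwise autosomal
#'   mismatch fraction within a replicate group.
#' @return An object of class `individual_set`: list with `genotypes`
#'   (consensus matrix, individuals x loci), `info` (data frame:
#'   `individual_id`, `n_samples`), `panel`, and `dropped` (character vector
#'   of contaminated group ids).
#' @export
consolidate_replicates <- function(gt, mismatch_threshold = 0.2) {
  stopifnot(inherits(gt, "genotype_table"))
  groups <- split(seq_len(nrow(gt$calls)), gt$samples$individual_id)
  if (any(lengths(groups) == 0)) stop("empty replicate group")
  auto <- panel_cols(gt$panel, "autosomal")
  ids <- names(groups)
  L <- ncol(gt$calls)
  cons <- matrix(NA_integer_, length(ids), L,
                 dimnames = list(ids, colnames(gt$calls)))
  contaminated <- character(0)

  for (k in seq_along(groups)) {
    rows <- gt$calls[groups[[k]], , drop = FALSE]
    if (nrow(rows) > 1) {
      mm <- .pairwise_mismatch(rows[, auto, drop = FALSE])
      if (!is.nan(mm) && mm > mismatch_threshold) {
        contaminated <- c(contaminated, ids[k])
        next
      }
    }
    cons[k, ] <- apply(rows, 2, .majority_call)
  }
  keep <- !(ids %in% contaminated)
  out <- list(
    genotypes = cons[keep, , drop = FALSE],
    info = data.frame(individual_id = ids[keep],
                      n_samples = lengths(groups)[keep],
                      stringsAsFactors = FALSE, row.names = NULL),
    panel = gt$panel,
    dropped = contaminated
  )
  class(out) <- "individual_set"
  out
}

# majority call over valid genotypes; ties and all-missing give NA
.majority_call <- function(calls) {
  calls <- calls[geno_valid(calls)]
  if (length(calls) == 0) return(NA_integer_)
  tab <- tabulate(calls + 1L, nbins = 3L)
  top <- which(tab == max(tab))
  if (length(top) > 1) NA_integer_ else top - 1L
}

# mean pairwise mismatch fraction over loci where both calls are valid
.pairwise_mismatch <- function(rows) {
  n <- nrow(rows)
  num <- 0
  den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- geno_valid(rows[i, ]) & geno_valid(rows[j, ])
      num <- num + sum(rows[i, both] != rows[j, both])
      den <- den + sum(both)
    }
  }
  num / den
}

#' @export
print.individual_set <- function(x, ...) {
  cat("<individual_set> ", nrow(x$genotypes), " individuals x ",
      ncol(x$genotypes), " loci", sep = "")
  if (length(x$dropped)) cat(" (", length(x$dropped), " dropped)", sep = "")
  cat("\n")
  invisible(x)
}

#' Estimate genotyping error and allelic dropout from replicates
#'
#' Compares every pair of replicate calls within each replicate group at
#' diploid loci (autosomal and X; the haploid Y and mtDNA loci are
#' excluded). Comparisons in which at least one call is a heterozygote form
#' the denominator. The error rate is the fraction of those comparisons
#' that are discordant; the allelic dropout rate counts
#' heterozygote-versus-homozygote discordances against twice the number of
#' heterozygote comparisons (two alleles at risk per heterozygote), the
#' heterozygote-based convention of Broquet and Petit. With biallelic SNPs
#' every heterozygote discordance involves a homozygote, so the two rates
#' share a numerator and differ in scaling; both are reported.
#'
#' @param gt A `genotype_table` containing at least one replicate group of
#'   size two or more.
#' @return List with `error_rate`, `dropout_rate`, `n_het_comparisons`,
#'   `n_discordant`.
#' @export
estimate_error_rates <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  dip <- panel_cols(gt$panel, c("autosomal", "X"))
  groups <- split(seq_len(nrow(gt$calls)), gt$samples$individual_id)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) {
    stop("no replicate groups of size >= 2: error rates undefined")
  }
  n_het <- 0L
  n_err <- 0L
  n_do <- 0L
  for (rows in groups) {
    calls <- gt$calls[rows, dip, drop = FALSE]
    n <- nrow(calls)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- calls[i, ]
        b <- calls[j, ]
        both <- geno_valid(a) & geno_valid(b)
        het <- both & (a == 1L | b == 1L)
        n_het <- n_het + sum(het)
        diff <- het & a != b
        n_err <- n_err + sum(diff)
        n_do <- n_do + sum(diff & xor(a == 1L, b == 1L))
      }
    }
  }
  list(error_rate = n_err / n_het,
       dropout_rate = n_do / (2 * n_het),
       n_het_comparisons = n_het,
       n_discordant = n_err)
}

#' Call sex from Y-presence and X-heterozygosity
#'
#' A sample is male if it yields a valid call at every Y locus and shows no
#' heterozygous X genotype (males are hemizygous on X); it is female if all
#' Y loci are missing (a female is additionally confirmed by at least one
#' heterozygous X call). Partial Y signal, invalid Y calls, or a Y-positive
#' sample with a heterozygous X are contradictory and give `undetermined`.
#'
#' @param y_calls Integer genotype codes at the Y loci.
#' @param x_calls Integer genotype codes at the X loci.
#' @return `"F"`, `"M"` or `"undetermined"`.
#' @export
determine_sex <- function(y_calls, x_calls) {
  if (length(y_calls) < 1 || length(x_calls) < 1) {
    stop("panel must define at least one Y and one X locus")
  }
  any_invalid_y <- any(!is.na(y_calls) & y_calls < 0)
  present <- geno_valid(y_calls)
  het_x <- any(geno_valid(x_calls) & x_calls == 1L)
  if (any_invalid_y) return("undetermined")
  if (all(present)) {
    if (het_x) "undetermined" else "M"
  } else if (all(is.na(y_calls))) {
    "F"
  } else {
    "undetermined"
  }
}

#' Call sexes for a consolidated individual set
#'
#' @param inds An `individual_set`.
#' @return `inds` with a `sex` column added to `info`.
#' @export
call_sexes <- function(inds) {
  stopifnot(inherits(inds, "individual_set"))
  ycols <- panel_cols(inds$panel, "Y")
  xcols <- panel_cols(inds$panel, "X")
  inds$info$sex <- vapply(seq_len(nrow(inds$genotypes)), function(i) {
    determine_sex(inds$genotypes[i, ycols], inds$genotypes[i, xcols])
  }, character(1))
  inds
}

#' Assign mitochondrial haplotypes
#'
#' Matches each individual's allele states at the diagnostic mtDNA loci
#' against a haplotype key; anything short of an exact match (including a
#' single missing mtDNA call) is `unassigned`.
#'
#' @param inds An `individual_set`.
#' @param key Named list of `"A"`/`"B"` patterns, as [default_mt_key()].
#' @return `inds` with an `mt_hap` column added to `info`.
#' @export
assign_mt_haplotype <- function(inds, key = default_mt_key()) {
  stopifnot(inherits(inds, "individual_set"))
  mtcols <- panel_cols(inds$panel, "mtDNA")
  pat_of <- function(calls) {
    if (!all(geno_valid(calls)) || any(calls == 1L)) return(NA_character_)
    paste(ifelse(calls == 2L, "B", "A"), collapse = "")
  }
  keys <- vapply(key, paste, character(1), collapse = "")
  inds$info$mt_hap <- vapply(seq_len(nrow(inds$genotypes)), function(i) {
    p <- pat_of(inds$genotypes[i, mtcols])
    hit <- names(keys)[!is.na(p) & keys == p]
    if (length(hit) == 1) hit else "unassigned"
  }, character(1))
  inds
}

#' Panel summary statistics
#'
#' Computes the call rate over non-Y loci (valid calls over valid + missing
#' + invalid, at the sample level), per-locus autosomal minor allele
#' frequencies from consolidated genotypes, and the multilocus probability
#' of identity of the autosomal panel (see [pid_identity()]).
#'
#' @param gt A `genotype_table` (sample-level calls, for the call rate).
#' @param inds Optional `individual_set`; if supplied, allele frequencies
#'   come from the consolidated genotypes rather than raw samples.
#' @return List with `call_rate`, `maf` (named vector) and `pid`.
#' @export
panel_summaries <- function(gt, inds = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  nonY <- panel_cols(gt$panel, c("autosomal", "X", "mtDNA"))
  calls <- gt$calls[, nonY, drop = FALSE]
  call_rate <- sum(geno_valid(calls)) / length(calls)

  G <- if (is.null(inds)) gt$calls else inds$genotypes
  auto <- panel_cols(gt$panel, "autosomal")
  freq_b <- apply(G[, auto, drop = FALSE], 2, function(g) {
    g <- g[geno_valid(g)]
    if (length(g) == 0) return(NA_real_)
    mean(g) / 2
  })
  maf <- pmin(freq_b, 1 - freq_b)
  ok <- !is.na(freq_b)
  list(call_rate = call_rate, maf = maf,
       pid = as.numeric(pid_identity(1 - freq_b[ok])))
}
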
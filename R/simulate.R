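# Truth-known population simulator: pedigree, sexes, home ranges, genotypes
# and replicated fecal samples with the statistical structure a noninvasive
# SNP dispersal study assumes.

#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic population. The
#' defaults emulate a noninvasively sampled brown-bear population: a 96-SNP
#' panel (87 autosomal loci at mean MAF 0.37, 3 X, 2 Y, 4 mtDNA), roughly
#' 800 individuals of which slightly over half are genotyped, a per-allele
#' genotyping error around 4e-4, sex-specific exponential dispersal kernels
#' with means 12.9 km (females) and 33.8 km (males), and 1-19 fecal samples
#' per genotyped individual over a 214 km x 214 km study rectangle.
#'
#' @param n_founders_f,n_founders_m Number of female/male founders.
#' @param n_generations Total number of non-overlapping generations
#'   including the founders (>= 2).
#' @param mean_offspring_per_mother Poisson mean litter size per mother and
#'   generation (0 gives a founders-only population).
#' @param L_autosomal Number of autosomal SNPs.
#' @param maf_mean Mean minor allele frequency of the autosomal loci.
#' @param epsilon Per-allele genotyping (miscall) error probability.
#' @param dropout_rate Probability that a true heterozygote is observed as a
#'   homozygote (one-allele dropout model).
#' @param invalid_rate Probability that a call is invalidated (ambiguous
#'   cluster), independent of the error model.
#' @param disp_mean_f_km,disp_mean_m_km Mean natal dispersal distance of the
#'   female/male kernel, km.
#' @param dispersal_kernel `"exponential"` (default) or `"halfnormal"`
#'   magnitude distribution; direction is always isotropic.
#' @param samples_per_ind_dist Probability vector over 1..19 fecal samples
#'   per genotyped individual; defaults to [default_samples_dist()].
#' @param sample_scatter_km Isotropic (Gaussian per axis) scatter of fecal
#'   sites around the home-range center, km.
#' @param prop_sampled Fraction of the population that is genotyped.
#' @param cub_prob Probability that a final-generation litter of two or more
#'   is still accompanying its mother (pre-dispersal cubs).
#' @param cub_scatter_km Fecal scatter for cubs (and used to keep their
#'   sites near the mother), km.
#' @param study_size_km Side of the square study area, km.
#' @param mt_hap_probs Named probabilities of founder-matriline mitochondrial
#'   haplotypes; names must match the haplotype key.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   simulation exactly.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_founders_f = 10, n_founders_m = 8, seed = 1)
#' @export
sim_config <- function(n_founders_f = 120,
                       n_founders_m = 95,
                       n_generations = 3,
                       mean_offspring_per_mother = 2.4,
                       L_autosomal = 87,
                       maf_mean = 0.37,
                       epsilon = 3.8e-4,
                       dropout_rate = 1e-4,
                       invalid_rate = 0.0036,
                       disp_mean_f_km = 12.9,
                       disp_mean_m_km = 33.8,
                       dispersal_kernel = c("exponential", "halfnormal"),
                       samples_per_ind_dist = default_samples_dist(),
                       sample_scatter_km = 8.8,
                       prop_sampled = 433 / 810,
                       cub_prob = 0.11,
                       cub_scatter_km = 0.3,
                       study_size_km = 214,
                       mt_hap_probs = c(south = 0.97, middle = 0.02,
                                        north = 0.01),
                       seed = 1L) {
  dispersal_kernel <- match.arg(dispersal_kernel)
  cfg <- list(
    n_founders_f = n_founders_f, n_founders_m = n_founders_m,
    n_generations = n_generations,
    mean_offspring_per_mother = mean_offspring_per_mother,
    L_autosomal = L_autosomal, maf_mean = maf_mean,
    epsilon = epsilon, dropout_rate = dropout_rate,
    invalid_rate = invalid_rate,
    disp_mean_f_km = disp_mean_f_km, disp_mean_m_km = disp_mean_m_km,
    dispersal_kernel = dispersal_kernel,
    samples_per_ind_dist = samples_per_ind_dist,
    sample_scatter_km = sample_scatter_km,
    prop_sampled = prop_sampled,
    cub_prob = cub_prob, cub_scatter_km = cub_scatter_km,
    study_size_km = study_size_km,
    mt_hap_probs = mt_hap_probs,
    seed = as.integer(seed)
  )
  rates <- c(epsilon = epsilon, dropout_rate = dropout_rate,
             invalid_rate = invalid_rate, prop_sampled = prop_sampled,
             cub_prob = cub_prob)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(c(disp_mean_f_km, disp_mean_m_km, sample_scatter_km,
            cub_scatter_km) < 0)) stop("lengths must be >= 0")
  if (n_founders_f < 1 || n_founders_m < 1 || L_autosomal < 1 ||
      study_size_km <= 0) stop("counts must be >= 1")
  if (n_generations < 2) stop("n_generations must be >= 2")
  if (mean_offspring_per_mother < 0) stop("offspring rate must be >= 0")
  if (abs(sum(samples_per_ind_dist) - 1) > 1e-8 ||
      any(samples_per_ind_dist < 0)) {
    stop("samples_per_ind_dist must be a probability vector")
  }
  if (maf_mean <= 0 || maf_mean > 0.5) stop("maf_mean must lie in (0, 0.5]")
  class(cfg) <- "sim_config"
  cfg
}

#' Default distribution of fecal samples per individual
#'
#' Probability vector over 1..19 samples per genotyped individual, shaped
#' like an opportunistic citizen-collection design: two thirds of
#' individuals yield a single sample, with a long tail up to 19 (mean about
#' 2.2 samples per individual).
#'
#' @return Numeric probability vector of length 19.
#' @export
default_samples_dist <- function() {
  counts <- c(275, 45, 25, 24, 10, rep(5, 5), rep(1.4, 5), rep(0.75, 4))
  counts / sum(counts)
}

#' Simulate a multigeneration pedigree with sexes and mtDNA matrilines
#'
#' Builds a truth-known population of non-overlapping generations. Founders
#' are unrelated; in each later generation every female of the previous
#' generation draws one mate uniformly from the previous generation's males
#' (so litters are full siblings and polygamous males father half-sib
#' litters) and a Poisson number of offspring with independent 50:50 sexes.
#' Final-generation litters of two or more are marked as pre-dispersal cubs
#' with probability `cub_prob`. Mitochondrial haplotypes are drawn per
#' founder matriline and copied maternally.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed (defaults to the RNG state already in effect).
#' @return An object of class `truth_population`: a list whose `individuals`
#'   element is a data frame with columns `id`, `sex`, `mother`, `father`,
#'   `generation`, `is_cub`, `sampled`, `mt_hap`, `x_m`, `y_m` (coordinates
#'   NA until [assign_home_ranges()] is run).
#' @export
simulate_pedigree_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  haps <- names(config$mt_hap_probs)

  nf <- config$n_founders_f
  nm <- config$n_founders_m
  ind <- data.frame(
    id = sprintf("B%04d", seq_len(nf + nm)),
    sex = c(rep("F", nf), rep("M", nm)),
    mother = NA_character_, father = NA_character_,
    generation = 1L, is_cub = FALSE,
    mt_hap = sample(haps, nf + nm, replace = TRUE,
                    prob = config$mt_hap_probs),
    stringsAsFactors = FALSE
  )

  for (g in seq_len(config$n_generations - 1) + 1L) {
    mothers <- ind$id[ind$sex == "F" & ind$generation == g - 1L]
    males <- ind$id[ind$sex == "M" & ind$generation == g - 1L]
    if (length(mothers) == 0 || length(males) == 0) break
    for (m in mothers) {
      k <- stats::rpois(1, config$mean_offspring_per_mother)
      if (k == 0) next
      f <- if (length(males) == 1) males else sample(males, 1)
      off <- data.frame(
        id = sprintf("B%04d", nrow(ind) + seq_len(k)),
        sex = ifelse(stats::runif(k) < 0.5, "F", "M"),
        mother = m, father = f, generation = g,
        is_cub = FALSE,
        mt_hap = ind$mt_hap[ind$id == m],
        stringsAsFactors = FALSE
      )
      ind <- rbind(ind, off)
    }
  }

  # whole final-generation litters may still be with their mother
  last <- ind$generation == max(ind$generation) & !is.na(ind$mother)
  if (any(last) && config$cub_prob > 0) {
    litters <- split(which(last), ind$mother[last])
    for (rows in litters) {
      if (length(rows) >= 2 && stats::runif(1) < config$cub_prob) {
        ind$is_cub[rows] <- TRUE
      }
    }
  }

  ind$sampled <- stats::runif(nrow(ind)) < config$prop_sampled
  ind$x_m <- NA_real_
  ind$y_m <- NA_real_
  out <- list(individuals = ind, config = config)
  class(out) <- "truth_population"
  out
}

#' @export
print.truth_population <- function(x, ...) {
  ind <- x$individuals
  cat("<truth_population> ", nrow(ind), " individuals (",
      sum(ind$sex == "F"), " F / ", sum(ind$sex == "M"), " M), ",
      max(ind$generation), " generations, ", sum(ind$sampled),
      " sampled, ", sum(ind$is_cub), " cubs\n", sep = "")
  invisible(x)
}

# one isotropic displacement of given magnitude that stays inside [0, S]^2;
# the magnitude is preserved (direction redrawn) so realized mother-offspring
# distances follow the configured kernel; clamped only if no direction fits
.place_offspring <- function(x0, y0, mag, S) {
  for (i in seq_len(200)) {
    theta <- stats::runif(1, 0, 2 * pi)
    x <- x0 + mag * cos(theta)
    y <- y0 + mag * sin(theta)
    if (x >= 0 && x <= S && y >= 0 && y <= S) return(c(x, y))
  }
  c(min(max(x, 0), S), min(max(y, 0), S))
}

#' Assign home-range centers by sex-specific dispersal kernels
#'
#' Founders receive centers uniform over the study rectangle. Every non-cub
#' offspring is placed at its mother's center plus a displacement with
#' isotropic direction and a sex-specific kernel magnitude (exponential by
#' default, mean `disp_mean_f_km`/`disp_mean_m_km`; optionally half-normal
#' with the same mean). Cubs stay at their mother's center. Displacements
#' keep their drawn magnitude: directions are redrawn until the endpoint
#' lies inside the study rectangle.
#'
#' @param truth A [simulate_pedigree_population()] result.
#' @param config The same [sim_config()].
#' @param seed Optional seed.
#' @return `truth` with `x_m`, `y_m` filled in (meters).
#' @export
assign_home_ranges <- function(truth, config = truth$config, seed = NULL) {
  stopifnot(inherits(truth, "truth_population"))
  if (!is.null(seed)) set.seed(seed)
  ind <- truth$individuals
  S <- config$study_size_km * 1000
  founders <- is.na(ind$mother)
  ind$x_m[founders] <- stats::runif(sum(founders), 0, S)
  ind$y_m[founders] <- stats::runif(sum(founders), 0, S)

  for (g in sort(unique(ind$generation[!founders]))) {
    for (i in which(ind$generation == g & !founders)) {
      mi <- match(ind$mother[i], ind$id)
      if (ind$is_cub[i]) {
        ind$x_m[i] <- ind$x_m[mi]
        ind$y_m[i] <- ind$y_m[mi]
        next
      }
      mu <- if (ind$sex[i] == "F") config$disp_mean_f_km else
        config$disp_mean_m_km
      mag <- 1000 * draw_kernel_magnitude(1, mu, config$dispersal_kernel)
      xy <- .place_offspring(ind$x_m[mi], ind$y_m[mi], mag, S)
      ind$x_m[i] <- xy[1]
      ind$y_m[i] <- xy[2]
    }
  }
  truth$individuals <- ind
  truth
}

#' Draw dispersal-kernel magnitudes
#'
#' @param n Number of draws.
#' @param mean_km Kernel mean, km.
#' @param kernel `"exponential"` or `"halfnormal"`.
#' @return Non-negative magnitudes, km.
#' @export
draw_kernel_magnitude <- function(n, mean_km,
                                  kernel = c("exponential", "halfnormal")) {
  kernel <- match.arg(kernel)
  if (mean_km == 0) return(rep(0, n))
  if (kernel == "exponential") {
    stats::rexp(n, rate = 1 / mean_km)
  } else {
    abs(stats::rnorm(n, 0, mean_km * sqrt(pi / 2)))
  }
}

#' Simulate replicated fecal samples
#'
#' Each genotyped (sampled) individual yields a number of fecal samples
#' drawn from `samples_per_ind_dist` (support 1..19); sample coordinates are
#' the individual's center plus isotropic Gaussian scatter
#' (`sample_scatter_km` per axis; `cub_scatter_km` for cubs).
#'
#' @param truth A truth population with centers assigned.
#' @param config The [sim_config()].
#' @param seed Optional seed.
#' @return Data frame with columns `sample_id`, `individual_id`, `x_m`,
#'   `y_m`.
#' @export
simulate_fecal_samples <- function(truth, config = truth$config,
                                   seed = NULL) {
  stopifnot(inherits(truth, "truth_population"))
  if (!is.null(seed)) set.seed(seed)
  ind <- truth$individuals[truth$individuals$sampled, , drop = FALSE]
  if (anyNA(ind$x_m)) stop("assign_home_ranges() must be run first")
  support <- seq_along(config$samples_per_ind_dist)
  n_per <- sample(support, nrow(ind), replace = TRUE,
                  prob = config$samples_per_ind_dist)
  rows <- rep(seq_len(nrow(ind)), n_per)
  scatter_m <- 1000 * ifelse(ind$is_cub[rows], config$cub_scatter_km,
                             config$sample_scatter_km)
  data.frame(
    sample_id = paste0(ind$id[rows], "_s",
                       unlist(lapply(n_per, seq_len))),
    individual_id = ind$id[rows],
    x_m = ind$x_m[rows] + stats::rnorm(length(rows), 0, scatter_m),
    y_m = ind$y_m[rows] + stats::rnorm(length(rows), 0, scatter_m),
    stringsAsFactors = FALSE
  )
}

# inherit one allele (B count 0/1) from a diploid genotype code 0/1/2
.transmit <- function(g) stats::rbinom(length(g), 1, g / 2)

#' Simulate true and observed genotypes
#'
#' True genotypes follow Hardy-Weinberg equilibrium in the founders and
#' Mendelian transmission in their descendants: autosomal loci pass one
#' allele from each parent; X loci are diploid in females and hemizygous in
#' males (maternal allele, reported as a homozygote); Y loci pass from
#' father to son and are missing in females; the mitochondrial pattern is
#' the matriline haplotype. Observed calls are generated per fecal sample:
#' a true heterozygote drops to a random homozygote with probability
#' `dropout_rate`, then each reported allele is miscalled with probability
#' `epsilon`, and finally a call is invalidated with probability
#' `invalid_rate`.
#'
#' @param truth A truth population.
#' @param panel A [make_marker_panel()] whose autosomal loci match the
#'   configuration.
#' @param samples Sample table from [simulate_fecal_samples()]; if `NULL`,
#'   one sample per individual (all individuals) is genotyped.
#' @param epsilon Per-allele miscall probability.
#' @param dropout_rate Heterozygote-to-homozygote dropout probability.
#' @param invalid_rate Per-call invalidation probability.
#' @param mt_key Haplotype key mapping labels to mtDNA allele patterns.
#' @param seed Optional seed.
#' @return An object of class `genotype_table`: list with `calls` (integer
#'   matrix, samples x loci; 0/1/2 = B-allele count, NA = missing, -1 =
#'   invalid), `samples` (sample_id, individual_id), `panel`, and the
#'   error-free `true_genotypes` matrix (individuals x loci).
#' @export
simulate_genotypes <- function(truth, panel, samples = NULL,
                               epsilon = truth$config$epsilon,
                               dropout_rate = truth$config$dropout_rate,
                               invalid_rate = truth$config$invalid_rate,
                               mt_key = default_mt_key(),
                               seed = NULL) {
  stopifnot(inherits(truth, "truth_population"),
            inherits(panel, "marker_panel"))
  if (!is.null(seed)) set.seed(seed)
  ind <- truth$individuals
  n <- nrow(ind)
  L <- nrow(panel)
  G <- matrix(NA_integer_, n, L, dimnames = list(ind$id, panel$locus_id))
  male <- ind$sex == "M"
  ord <- order(ind$generation)

  for (l in seq_len(L)) {
    qb <- 1 - panel$freq_a[l]
    cls <- panel$class[l]
    if (cls == "mtDNA") {
      mt_idx <- sum(panel$class[seq_len(l)] == "mtDNA")
      for (h in names(mt_key)) {
        G[ind$mt_hap == h, l] <- if (mt_key[[h]][mt_idx] == "B") 2L else 0L
      }
      next
    }
    for (i in ord) {
      founder <- is.na(ind$mother[i])
      mi <- if (!founder) match(ind$mother[i], ind$id) else NA
      fi <- if (!founder) match(ind$father[i], ind$id) else NA
      G[i, l] <- switch(cls,
        autosomal = if (founder) stats::rbinom(1, 2, qb) else
          .transmit(G[mi, l]) + .transmit(G[fi, l]),
        X = if (male[i]) {
          if (founder) 2L * stats::rbinom(1, 1, qb) else
            2L * .transmit(G[mi, l])
        } else {
          if (founder) stats::rbinom(1, 2, qb) else
            .transmit(G[mi, l]) + G[fi, l] / 2L
        },
        Y = if (!male[i]) NA_integer_ else
          if (founder) 2L * stats::rbinom(1, 1, qb) else G[fi, l]
      )
    }
  }
  storage.mode(G) <- "integer"

  if (is.null(samples)) {
    samples <- data.frame(sample_id = paste0(ind$id, "_s1"),
                          individual_id = ind$id, stringsAsFactors = FALSE)
  }
  si <- match(samples$individual_id, ind$id)
  obs <- G[si, , drop = FALSE]
  rownames(obs) <- samples$sample_id
  haploid <- matrix(panel$class %in% c("Y", "mtDNA"), nrow(obs), L,
                    byrow = TRUE)
  haploid[male[si], panel$class == "X"] <- TRUE

  # dropout: true heterozygote observed as a random homozygote
  het <- !haploid & !is.na(obs) & obs == 1L
  drop_hit <- het & stats::runif(length(obs)) < dropout_rate
  obs[drop_hit] <- 2L * stats::rbinom(sum(drop_hit), 1, 0.5)

  # per-allele symmetric miscall
  valid <- !is.na(obs)
  flip1 <- stats::runif(length(obs)) < epsilon
  flip2 <- stats::runif(length(obs)) < epsilon
  nb <- obs / 2          # per-allele B indicator scale
  a1 <- ifelse(obs >= 1L, 1L, 0L)   # allele 1 is B iff code >= 1
  a2 <- ifelse(obs == 2L, 1L, 0L)   # allele 2 is B iff code == 2
  new1 <- ifelse(flip1, 1L - a1, a1)
  new2 <- ifelse(flip2, 1L - a2, a2)
  miscalled <- new1 + new2
  miscalled[haploid] <- 2L * new1[haploid]   # single reported allele
  obs[valid] <- miscalled[valid]

  if (invalid_rate > 0) {
    inv <- valid & stats::runif(length(obs)) < invalid_rate
    obs[inv] <- -1L
  }
  storage.mode(obs) <- "integer"

  out <- list(calls = obs,
              samples = samples[, c("sample_id", "individual_id")],
              panel = panel, true_genotypes = G)
  class(out) <- "genotype_table"
  out
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table> ", nrow(x$calls), " samples x ", ncol(x$calls),
      " loci (", length(unique(x$samples$individual_id)),
      " individuals)\n", sep = "")
  invisible(x)
}

#' Simulate a complete study
#'
#' Chains allele-frequency, pedigree, home-range, fecal-sample and genotype
#' simulation under a single seed.
#'
#' @param config A [sim_config()].
#' @param genotypes Set `FALSE` to skip genotype simulation (pedigree and
#'   spatial structure only).
#' @return List of class `kindisp_sim` with elements `config`, `panel`,
#'   `truth`, `samples` and (unless disabled) `genotypes`.
#' @examples
#' sim <- simulate_population(sim_config(n_founders_f = 8, n_founders_m = 6,
#'                                       seed = 42))
#' sim$truth
#' @export
simulate_population <- function(config, genotypes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  maf <- simulate_allele_frequencies(config$L_autosomal, config$maf_mean)
  panel <- make_marker_panel(auto_freq_a = 1 - maf)
  truth <- simulate_pedigree_population(config)
  truth <- assign_home_ranges(truth, config)
  samples <- simulate_fecal_samples(truth, config)
  out <- list(config = config, panel = panel, truth = truth,
              samples = samples)
  if (genotypes) {
    out$genotypes <- simulate_genotypes(truth, panel, samples)
  }
  class(out) <- "kindisp_sim"
  out
}

#' True pedigree as a parent table
#'
#' Converts a truth population to the parent-table layout used by the
#' dispersal functions ([identify_cubs()], [natal_distances()]), with all
#' mother links marked oriented (the truth is known).
#'
#' @param truth A `truth_population`.
#' @return Data frame with columns `id`, `mother`, `father`, `sex`,
#'   `mother_oriented`.
#' @export
truth_parent_table <- function(truth) {
  ind <- truth$individuals
  data.frame(id = ind$id, mother = ind$mother, father = ind$father,
             sex = ind$sex, mother_oriented = !is.na(ind$mother),
             stringsAsFactors = FALSE)
}
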
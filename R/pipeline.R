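#' Run the full dispersal-estimation pipeline
#'
#' Chains the analysis stages on a simulated (or equivalently structured)
#' data set: replicate consolidation, sex calling, mitochondrial haplotype
#' assignment, Lynch-Ritland relatedness, posterior-filtered parentage,
#' pedigree assembly and dyad orientation, median-center estimation,
#' isolation-by-distance tests on the putative parents, cub exclusion and
#' sex-stratified dispersal summaries with a rank-sum test.
#'
#' @param sim A `kindisp_sim` from [simulate_population()], or a list with
#'   elements `genotypes` (a `genotype_table`) and `samples` (coordinates).
#' @param pconfig A [parentage_config()].
#' @param n_perm Mantel permutations for the IBD stage.
#' @return List with elements `individuals`, `qc`, `relatedness`,
#'   `parentage`, `pedigree`, `centers`, `ibd`, `records`, `summary`,
#'   `rank_sum`.
#' @export
run_dispersal_pipeline <- function(sim, pconfig = parentage_config(),
                                   n_perm = 999) {
  gt <- sim$genotypes
  inds <- consolidate_replicates(gt)
  inds <- call_sexes(inds)
  inds <- assign_mt_haplotype(inds)
  qc <- c(list(error = tryCatch(estimate_error_rates(gt),
                                error = function(e) NULL)),
          panel_summaries(gt, inds))

  rel <- relatedness_matrix(inds)
  rec <- reconstruct_pedigree(inds, pconfig)
  par_res <- rec$parentage
  ped <- rec$pedigree

  centers <- compute_centers(sim$samples)
  sexes <- stats::setNames(inds$info$sex, inds$info$individual_id)
  putative_parents <- unique(stats::na.omit(
    c(ped$parents$mother, ped$parents$father)))
  ibd <- if (length(putative_parents) >= 3) {
    ibd_by_sex(centers, rel, sexes, putative_parents, n_perm = n_perm)
  } else NULL

  ptab <- ped$parents
  ptab$sex <- sexes[ptab$id]
  cubs <- identify_cubs(ptab, centers)
  records <- natal_distances(ptab, centers, cubs)
  active <- records[!records$is_cub, , drop = FALSE]
  summary <- if (nrow(active)) summarize_by_sex(records) else NULL
  rs <- if (all(c("F", "M") %in% active$offspring_sex)) {
    rank_sum_test(active$distance_km[active$offspring_sex == "F"],
                  active$distance_km[active$offspring_sex == "M"])
  } else NULL

  list(individuals = inds, qc = qc, relatedness = rel,
       parentage = par_res, pedigree = ped, centers = centers, ibd = ibd,
       records = records, summary = summary, rank_sum = rs)
}
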
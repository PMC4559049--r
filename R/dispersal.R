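# Natal dispersal: cub exclusion, mother-offspring distances, sex-stratified
# summaries and the rank-sum test for sex-biased dispersal.

#' Flag pre-dispersal cubs
#'
#' An offspring still accompanying its mother is identified by three
#' criteria: it has at least one full sibling; that sibling is at the same
#' geographic location (mutual distance at most `delta_sib_km`); and both
#' lie within `delta_mother_km` of their mother's center. Only offspring
#' with a known mother, a known father (full siblings require both parents)
#' and available centers can be flagged.
#'
#' @param parents Parent table: data frame with `id`, `mother`, `father`.
#' @param centers Data frame `individual_id`, `x_m`, `y_m`.
#' @param delta_sib_km Maximum sibling-sibling distance, km.
#' @param delta_mother_km Maximum offspring-mother distance, km.
#' @return Named logical vector over `parents$id`.
#' @export
identify_cubs <- function(parents, centers, delta_sib_km = 1,
                          delta_mother_km = 1) {
  ctr <- function(id) {
    i <- match(id, centers$individual_id)
    if (is.na(i)) return(NULL)
    c(centers$x_m[i], centers$y_m[i])
  }
  cub <- stats::setNames(rep(FALSE, nrow(parents)), parents$id)
  linked <- !is.na(parents$mother) & !is.na(parents$father)
  fams <- split(parents$id[linked],
                paste(parents$mother[linked], parents$father[linked]))
  for (sibs in fams) {
    if (length(sibs) < 2) next
    m <- parents$mother[match(sibs[1], parents$id)]
    cm <- ctr(m)
    if (is.null(cm)) {
      warning("mother ", m, " has no center; litter skipped")
      next
    }
    cs <- lapply(sibs, ctr)
    has_ctr <- !vapply(cs, is.null, logical(1))
    for (i in which(has_ctr)) {
      near_mother_i <- euclidean_km(cs[[i]], cm) <= delta_mother_km
      if (!near_mother_i) next
      for (j in which(has_ctr)) {
        if (j == i) next
        if (euclidean_km(cs[[i]], cs[[j]]) <= delta_sib_km &&
            euclidean_km(cs[[j]], cm) <= delta_mother_km) {
          cub[sibs[i]] <- TRUE
          break
        }
      }
    }
  }
  cub
}

#' Mother-offspring natal dispersal distances
#'
#' One record per non-cub offspring with an oriented mother link: the
#' Euclidean distance between the mother's and the offspring's home-range
#' centers. Zero distances are retained (short-distance dispersal is part
#' of the estimate); offspring whose mother link exists only as an
#' unoriented dyad, or whose centers are unavailable, are skipped.
#'
#' @param parents Parent table with `id`, `mother`, `sex`, and (optional)
#'   `mother_oriented`; rows without an oriented mother are skipped.
#' @param centers Data frame `individual_id`, `x_m`, `y_m`.
#' @param cubs Optional logical vector from [identify_cubs()]; flagged
#'   offspring are excluded but kept in the output with `is_cub = TRUE`.
#' @return Data frame of class `dispersal_records`: `offspring_id`,
#'   `mother_id`, `offspring_sex`, `distance_km`, `is_cub`.
#' @export
natal_distances <- function(parents, centers, cubs = NULL) {
  oriented <- if ("mother_oriented" %in% names(parents)) {
    !is.na(parents$mother_oriented) & parents$mother_oriented
  } else {
    rep(TRUE, nrow(parents))
  }
  keep <- !is.na(parents$mother) & oriented
  idx <- match(parents$id, centers$individual_id)
  midx <- match(parents$mother, centers$individual_id)
  keep <- keep & !is.na(idx) & !is.na(midx)
  rows <- which(keep)
  out <- data.frame(
    offspring_id = parents$id[rows],
    mother_id = parents$mother[rows],
    offspring_sex = if ("sex" %in% names(parents)) parents$sex[rows]
                    else NA_character_,
    distance_km = sqrt((centers$x_m[idx[rows]] -
                          centers$x_m[midx[rows]])^2 +
                       (centers$y_m[idx[rows]] -
                          centers$y_m[midx[rows]])^2) / 1000,
    is_cub = if (is.null(cubs)) FALSE else unname(cubs[parents$id[rows]]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dispersal_records", "data.frame")
  out
}

#' Summarize dispersal distances by offspring sex
#'
#' For all offspring together and for each sex: the number of records, the
#' median, mean, standard error (sample SD over the square root of n; NA
#' for a single record) and maximum distance in km. Cubs are excluded.
#'
#' @param records A `dispersal_records` data frame.
#' @return Data frame with rows `all`, `F`, `M` (empty groups omitted with
#'   a warning) and columns `group`, `n`, `median_km`, `mean_km`, `se_km`,
#'   `max_km`.
#' @export
summarize_by_sex <- function(records) {
  records <- records[!records$is_cub, , drop = FALSE]
  one <- function(name, d) {
    if (length(d) == 0) {
      warning("group ", name, " is empty; omitted")
      return(NULL)
    }
    data.frame(group = name, n = length(d),
               median_km = stats::median(d), mean_km = mean(d),
               se_km = if (length(d) > 1) {
                 stats::sd(d) / sqrt(length(d))
               } else NA_real_,
               max_km = max(d), stringsAsFactors = FALSE)
  }
  out <- rbind(
    one("all", records$distance_km),
    one("F", records$distance_km[records$offspring_sex == "F"]),
    one("M", records$distance_km[records$offspring_sex == "M"])
  )
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum test for sex-biased dispersal
#'
#' Two-sided rank-sum (Mann-Whitney) test under the first-sample W
#' convention: exact for small untied samples, normal approximation with
#' tie and continuity correction otherwise. Two identical groups give
#' p = 1.
#'
#' @param x,y Numeric distance vectors (e.g. female and male distances).
#' @return List with `W` and `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # all observations tied across both groups
  list(W = unname(wt$statistic), p_value = min(p, 1))
}
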
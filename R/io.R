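# Plain-text interchange: genotype, coordinate and pedigree CSV files.

.code_to_call <- c(`0` = "A/A", `1` = "A/B", `2` = "B/B")

#' Write a genotype table to CSV
#'
#' Calls are coded `A/A`, `A/B`, `B/B`, with `./.` for missing and `-/-`
#' for invalidated calls. The first two columns are `sample_id` and
#' `individual_id` (the replicate grouping); the remaining columns are loci.
#'
#' @param gt A `genotype_table`.
#' @param path Output file.
#' @export
write_genotypes <- function(gt, path) {
  calls <- gt$calls
  chr <- matrix("./.", nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  chr[geno_valid(calls)] <- .code_to_call[
    as.character(calls[geno_valid(calls)])]
  chr[!is.na(calls) & calls < 0] <- "-/-"
  df <- data.frame(sample_id = gt$samples$sample_id,
                   individual_id = gt$samples$individual_id,
                   chr, stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a genotype table from CSV
#'
#' @param path File written by [write_genotypes()] (or following its
#'   dialect).
#' @param panel The `marker_panel` describing the locus columns.
#' @return A `genotype_table`.
#' @export
read_genotypes <- function(path, panel) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  loci <- setdiff(names(df), c("sample_id", "individual_id"))
  stopifnot(all(panel$locus_id %in% loci))
  chr <- as.matrix(df[, panel$locus_id, drop = FALSE])
  calls <- matrix(NA_integer_, nrow(chr), ncol(chr),
                  dimnames = list(df$sample_id, panel$locus_id))
  calls[chr == "A/A"] <- 0L
  calls[chr == "A/B" | chr == "B/A"] <- 1L
  calls[chr == "B/B"] <- 2L
  calls[chr == "-/-"] <- -1L
  out <- list(calls = calls,
              samples = data.frame(sample_id = df$sample_id,
                                   individual_id = df$individual_id,
                                   stringsAsFactors = FALSE),
              panel = panel)
  class(out) <- "genotype_table"
  out
}

#' Write sample coordinates to CSV
#'
#' @param samples Data frame with `sample_id`, `individual_id`, `x_m`,
#'   `y_m`.
#' @param path Output file.
#' @export
write_coordinates <- function(samples, path) {
  utils::write.csv(samples[, c("sample_id", "individual_id", "x_m", "y_m")],
                   path, row.names = FALSE, quote = FALSE)
}

#' Read sample coordinates from CSV
#'
#' @param path File with columns `sample_id`, `individual_id`, `x_m`,
#'   `y_m`.
#' @return Data frame.
#' @export
read_coordinates <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a truth pedigree to CSV
#'
#' @param truth A `truth_population`.
#' @param path Output file (columns `id`, `sex`, `mother`, `father`,
#'   `generation`, `x_m`, `y_m`).
#' @export
write_pedigree <- function(truth, path) {
  utils::write.csv(truth$individuals[, c("id", "sex", "mother", "father",
                                         "generation", "x_m", "y_m")],
                   path, row.names = FALSE, quote = FALSE)
}
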
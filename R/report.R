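#' Pipeline configuration defaults
#'
#' Central record of every numeric threshold the pipeline applies: the DE
#' p-value cutoff, the similarity-graph e-value threshold and MCL inflation,
#' the RBBH identity/coverage thresholds, the core-cluster membership rule
#' and the pioneer database e-value.
#'
#' @param alpha Raw DE p-value threshold. Default 0.001.
#' @param evalue_threshold Similarity-graph e-value cutoff. Default 1e-35.
#' @param inflation MCL inflation. Default 6.
#' @param rbbh_identity,rbbh_coverage RBBH thresholds. Defaults 70 and 50.
#' @param core_min_datasets,core_total_datasets Core rule: effector cluster
#'   in at least 5 of the 8 focal datasets.
#' @param pioneer_db_evalue Database-hit e-value for pioneer screening.
#'   Default 1e-5.
#' @param seed Integer seed for any stochastic step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.001, evalue_threshold = 1e-35,
                            inflation = 6, rbbh_identity = 70,
                            rbbh_coverage = 50, core_min_datasets = 5L,
                            core_total_datasets = 8L,
                            pioneer_db_evalue = 1e-5, seed = 1L) {
  structure(list(alpha = alpha, evalue_threshold = evalue_threshold,
                 inflation = inflation, rbbh_identity = rbbh_identity,
                 rbbh_coverage = rbbh_coverage,
                 core_min_datasets = as.integer(core_min_datasets),
                 core_total_datasets = as.integer(core_total_datasets),
                 pioneer_db_evalue = pioneer_db_evalue,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Round half away from zero, the convention consistent with every printed
# percentage this package reports.
round_half_away <- function(x, digits = 0L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Percentage report row
#'
#' @param numerator,denominator Counts; `denominator` must be positive.
#' @param decimals Decimal places of the percentage (rounded half away from
#'   zero). Default 1.
#' @param label Optional row label.
#' @return `data.frame` row with `label`, `numerator`, `denominator`,
#'   `percent`.
#' @examples
#' percent_report(49, 430)   # 11.4
#' percent_report(3, 390)    # 0.8
#' @export
percent_report <- function(numerator, denominator, decimals = 1L,
                           label = NA_character_) {
  if (length(denominator) != 1L || is.na(denominator) || denominator <= 0) {
    stop("denominator must be a single positive count")
  }
  data.frame(label = label, numerator = numerator, denominator = denominator,
             percent = round_half_away(100 * numerator / denominator,
                                       decimals),
             stringsAsFactors = FALSE)
}

#' Per-dataset repertoire summary
#'
#' Counts per dataset: head-upregulated transcripts, those that are
#' secreted (putative effectors), secreted with an NLS, and the same three
#' rows for body-upregulated transcripts.
#'
#' @param effector_calls Row-bound [call_effectors()] output (with
#'   `dataset` filled in).
#' @return `data.frame` with one row per dataset and columns
#'   `upregulated_head`, `secreted_head`, `secreted_head_nls`,
#'   `upregulated_body`, `secreted_body`, `secreted_body_nls`.
#' @export
repertoire_summary <- function(effector_calls) {
  by_ds <- split(effector_calls, effector_calls$dataset)
  rows <- lapply(names(by_ds), function(ds) {
    x <- by_ds[[ds]]
    data.frame(
      dataset = ds,
      upregulated_head = sum(x$direction == "head_up"),
      secreted_head = sum(x$category == "putative_effector"),
      secreted_head_nls = sum(x$category == "putative_effector" & x$nls_flag),
      upregulated_body = sum(x$direction == "body_up"),
      secreted_body = sum(x$category == "other_secreted"),
      secreted_body_nls = sum(x$category == "other_secreted" & x$nls_flag),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ORF completeness report
#'
#' @param classes Character vector of completeness classes
#'   ([classify_orf_completeness()]).
#' @return `data.frame` with `class`, `count` and nearest-integer `percent`
#'   (rounded half away from zero) of the total.
#' @export
completeness_report <- function(classes) {
  if (!length(classes)) stop("no ORFs to report on")
  lev <- c("complete", "five_prime_partial", "three_prime_partial",
           "internal")
  counts <- table(factor(classes, levels = lev))
  data.frame(class = lev, count = as.integer(counts),
             percent = round_half_away(100 * as.integer(counts) /
                                         length(classes)),
             stringsAsFactors = FALSE)
}

#' Expression stability of reference (housekeeping-style) transcripts
#'
#' @param de_calls Output of [exact_test_de()] (or row-bound across
#'   datasets).
#' @param reference_ids Transcript ids of the reference set.
#' @return A list with `n_reference`, `n_de` (flagged in either direction)
#'   and `n_stable`.
#' @export
housekeeping_stability <- function(de_calls, reference_ids) {
  x <- de_calls[de_calls$id %in% reference_ids, , drop = FALSE]
  n_de <- sum(x$direction != "ns")
  list(n_reference = length(unique(reference_ids)), n_de = n_de,
       n_stable = length(unique(reference_ids)) - n_de)
}

#' Selection-screen summary
#'
#' @param screen [screen_groups()] output.
#' @param decimals Decimal places of the percentage. Default 1.
#' @return A list with `n_screened` (groups with a defined aggregate omega),
#'   `n_excluded`, `n_positive` and a [percent_report()] row.
#' @export
selection_summary <- function(screen, decimals = 1L) {
  defined <- !is.na(screen$omega)
  n_pos <- sum(screen$positive_selection[defined])
  list(n_screened = sum(defined), n_excluded = sum(!defined),
       n_positive = n_pos,
       report = if (sum(defined) > 0) {
         percent_report(n_pos, sum(defined), decimals,
                        label = "groups with dN/dS > 1")
       } else {
         NULL
       })
}
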
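#' Call candidate effectors from DE results and secretion annotations
#'
#' A transcript upregulated in head tissue that carries a predicted signal
#' peptide and no transmembrane domain is called a putative effector; a
#' body-upregulated secreted transcript is called "other secreted".
#' Everything else (including secreted-but-TM transcripts) is `none`.
#' No fold-change floor is applied beyond the DE call itself.
#'
#' @param de_calls Output of [exact_test_de()].
#' @param annotations Annotation table ([read_annotation_table()] /
#'   [annotation_table()]). Ids missing from it are treated as all-flags-no,
#'   with a warning.
#' @param dataset Optional dataset label attached to every call.
#' @return `data.frame` with `id`, `category`
#'   (`putative_effector` / `other_secreted` / `none`), `nls_flag`
#'   (copied for secreted calls, `FALSE` otherwise), `direction`, `dataset`.
#' @export
call_effectors <- function(de_calls, annotations, dataset = NA_character_) {
  m <- match(de_calls$id, annotations$id)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " DE id(s) missing from annotations; ",
            "treated as unannotated (all flags no)")
  }
  sp <- ifelse(is.na(m), FALSE, annotations$has_signal_peptide[m])
  tm <- ifelse(is.na(m), FALSE, annotations$has_tm_domain[m])
  nls <- ifelse(is.na(m), FALSE, annotations$has_nls[m])
  secreted <- sp & !tm
  category <- rep("none", nrow(de_calls))
  category[de_calls$direction == "head_up" & secreted] <- "putative_effector"
  category[de_calls$direction == "body_up" & secreted] <- "other_secreted"
  data.frame(id = de_calls$id, category = category,
             nls_flag = ifelse(category == "none", FALSE, nls),
             direction = de_calls$direction, dataset = dataset,
             stringsAsFactors = FALSE)
}

#' Classify ORF completeness
#'
#' @param has_start_codon,has_stop_codon Logical vectors: presence of a
#'   leading start codon and a trailing stop codon.
#' @return Character vector: `complete`, `five_prime_partial`,
#'   `three_prime_partial` or `internal`.
#' @export
classify_orf_completeness <- function(has_start_codon, has_stop_codon) {
  stopifnot(length(has_start_codon) == length(has_stop_codon))
  ifelse(has_start_codon & has_stop_codon, "complete",
         ifelse(!has_start_codon & has_stop_codon, "five_prime_partial",
                ifelse(has_start_codon, "three_prime_partial", "internal")))
}

#' Derive ORF completeness flags from CDS strings
#'
#' @param cds Character vector of coding sequences.
#' @return `data.frame` with `has_start_codon` (leading ATG),
#'   `has_stop_codon` (trailing TAA/TAG/TGA) and `class`.
#' @export
orf_completeness_from_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  start <- substr(cds, 1L, 3L) == "ATG"
  stopc <- substr(cds, n - 2L, n) %in% c("TAA", "TAG", "TGA")
  data.frame(has_start_codon = start, has_stop_codon = stopc,
             class = classify_orf_completeness(start, stopc),
             stringsAsFactors = FALSE)
}

#' Overlap of proteomics-identified saliva proteins with effector calls
#'
#' @param saliva_ids Ids of proteins identified in saliva.
#' @param effector_calls Output of [call_effectors()].
#' @param annotations Annotation table.
#' @return A list: `total`, `unmatched` (ids absent from the annotations),
#'   `secreted` (signal peptide and no TM), `effector_overlap` (saliva ids
#'   in the putative-effector set), and per-id `detail` table.
#' @export
proteomics_overlap <- function(saliva_ids, effector_calls, annotations) {
  saliva_ids <- unique(as.character(saliva_ids))
  m <- match(saliva_ids, annotations$id)
  matched <- !is.na(m)
  secreted <- matched & annotations$has_signal_peptide[m] &
    !annotations$has_tm_domain[m]
  eff_set <- effector_calls$id[effector_calls$category == "putative_effector"]
  overlap <- secreted & saliva_ids %in% eff_set
  detail <- data.frame(id = saliva_ids, matched = matched,
                       secreted = secreted, putative_effector = overlap,
                       stringsAsFactors = FALSE)
  list(total = length(saliva_ids), unmatched = saliva_ids[!matched],
       secreted = sum(secreted), effector_overlap = sum(overlap),
       detail = detail)
}

#' Count repeat motifs in a protein sequence
#'
#' Greedy non-overlapping left-to-right matching of a short amino-acid
#' motif, allowing up to `max_mismatch` substitutions per match. Reports the
#' number of matches, their spans, and the longest tandem run of adjacent
#' matches.
#'
#' @param protein Amino-acid string.
#' @param motif Motif string (length >= 3).
#' @param max_mismatch Maximum substitutions per match (< motif length).
#' @param overlapping Also consider matches starting inside a previous
#'   match (off by default; repeat units are discrete).
#' @return A list with `count`, `spans` (matrix of start/end positions) and
#'   `max_tandem_run`.
#' @export
count_repeat_motifs <- function(protein, motif, max_mismatch = 0,
                                overlapping = FALSE) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  k <- nchar(motif)
  if (k < 3L) stop("motif length must be >= 3")
  if (max_mismatch >= k) stop("max_mismatch must be < motif length")
  pv <- strsplit(protein, "")[[1L]]
  mv <- strsplit(motif, "")[[1L]]
  n <- length(pv)
  starts <- integer(0)
  i <- 1L
  while (i + k - 1L <= n) {
    mism <- sum(pv[i:(i + k - 1L)] != mv)
    if (mism <= max_mismatch) {
      starts <- c(starts, i)
      i <- i + (if (overlapping) 1L else k)
    } else {
      i <- i + 1L
    }
  }
  if (!length(starts)) {
    return(list(count = 0L, spans = cbind(start = integer(0),
                                          end = integer(0)),
                max_tandem_run = 0L))
  }
  spans <- cbind(start = starts, end = starts + k - 1L)
  adjacent <- c(FALSE, starts[-1L] == starts[-length(starts)] + k)
  run <- 1L; best <- 1L
  for (j in seq_along(adjacent)[-1L]) {
    run <- if (adjacent[j]) run + 1L else 1L
    best <- max(best, run)
  }
  list(count = length(starts), spans = spans, max_tandem_run = best)
}
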
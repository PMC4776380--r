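# Codon machinery shared by the selection screen and the sequence simulator.
# Standard genetic code throughout (Biostrings::GENETIC_CODE).

codon_env <- new.env(parent = emptyenv())

genetic_code <- function() {
  if (is.null(codon_env$code)) {
    codon_env$code <- Biostrings::GENETIC_CODE
    codon_env$codons <- names(codon_env$code)
    codon_env$sense <- codon_env$codons[codon_env$code != "*"]
  }
  codon_env$code
}

sense_codons <- function() {
  genetic_code()
  codon_env$sense
}

translate_codons <- function(codons) {
  unname(genetic_code()[codons])
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("sequence length is not a multiple of 3")
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# Nei-Gojobori synonymous site count of one codon: at each position, each of
# the three possible changes contributes 1/3 of a synonymous site if it
# preserves the amino acid; changes creating stop codons count as
# nonsynonymous so that synonymous + nonsynonymous sites always sum to 3.
codon_syn_sites <- function() {
  if (!is.null(codon_env$syn_sites)) return(codon_env$syn_sites)
  code <- genetic_code()
  nts <- c("A", "C", "G", "T")
  s <- numeric(length(code))
  names(s) <- names(code)
  for (codon in names(code)) {
    aa <- code[[codon]]
    frac <- 0
    for (pos in 1:3) {
      for (nt in setdiff(nts, substr(codon, pos, pos))) {
        mut <- codon
        substr(mut, pos, pos) <- nt
        if (code[[mut]] == aa && aa != "*") frac <- frac + 1 / 3
      }
    }
    s[[codon]] <- frac
  }
  codon_env$syn_sites <- s
  s
}

# Average (synonymous, nonsynonymous) difference counts between two codons
# over all minimal mutational pathways, equal weights. Pathways passing
# through a stop codon are excluded; if every pathway is blocked the average
# falls back to all pathways with stop transitions counted as nonsynonymous.
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste0(c1, c2)
  cached <- codon_env$pair_cache[[key]]
  if (!is.null(cached)) return(cached)
  res <- path_average(c1, c2, allow_stop = FALSE)
  if (res[["paths"]] == 0) res <- path_average(c1, c2, allow_stop = TRUE)
  out <- c(sd = res[["sd"]] / res[["paths"]], nd = res[["nd"]] / res[["paths"]])
  if (is.null(codon_env$pair_cache)) codon_env$pair_cache <- list()
  codon_env$pair_cache[[key]] <- out
  out
}

path_average <- function(from, to, allow_stop) {
  code <- genetic_code()
  if (from == to) return(c(paths = 1, sd = 0, nd = 0))
  acc <- c(paths = 0, sd = 0, nd = 0)
  for (pos in 1:3) {
    if (substr(from, pos, pos) == substr(to, pos, pos)) next
    nxt <- from
    substr(nxt, pos, pos) <- substr(to, pos, pos)
    if (!allow_stop && code[[nxt]] == "*" && nxt != to) next
    sub <- path_average(nxt, to, allow_stop)
    if (sub[["paths"]] == 0) next
    syn <- code[[from]] == code[[nxt]] && code[[from]] != "*"
    acc[["paths"]] <- acc[["paths"]] + sub[["paths"]]
    acc[["sd"]] <- acc[["sd"]] + sub[["sd"]] + (if (syn) sub[["paths"]] else 0)
    acc[["nd"]] <- acc[["nd"]] + sub[["nd"]] + (if (syn) 0 else sub[["paths"]])
  }
  acc
}

#' Pairwise Nei-Gojobori (1986) dN/dS
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the two
#' sequences) and resolves multi-position codon differences by averaging over
#' all minimal mutational pathways with equal weights, excluding pathways
#' through stop codons. Proportions are corrected with the Jukes-Cantor
#' formula `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param cds_a,cds_b Ungapped coding sequences of equal length (multiple of
#'   3, no stop codons; run after [trim_codon_alignment()]).
#' @return A list with `dN`, `dS`, `omega` (`NA` when `dS == 0`), the raw
#'   proportions `pN`, `pS`, difference counts `Nd`, `Sd`, site counts `N`,
#'   `S`, and `n_codons`.
#' @examples
#' ng86("ATGGCT", "ATGGCC")  # one synonymous difference
#' @export
ng86 <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b)) {
    stop("sequences differ in length (", nchar(cds_a), " vs ", nchar(cds_b), ")")
  }
  if (grepl("-", cds_a, fixed = TRUE) || grepl("-", cds_b, fixed = TRUE)) {
    stop("gapped sequences: trim the codon alignment first")
  }
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  aa <- translate_codons(ca)
  ab <- translate_codons(cb)
  if (any(aa == "*") || any(ab == "*")) {
    stop("stop codon inside coding sequence")
  }
  sites <- codon_syn_sites()
  S <- (sum(sites[ca]) + sum(sites[cb])) / 2
  N <- 3 * length(ca) - S
  sd_tot <- 0; nd_tot <- 0
  for (i in which(ca != cb)) {
    d <- codon_pair_diffs(ca[i], cb[i])
    sd_tot <- sd_tot + d[["sd"]]
    nd_tot <- nd_tot + d[["nd"]]
  }
  pS <- if (S > 0) sd_tot / S else 0
  pN <- if (N > 0) nd_tot / N else 0
  dN <- jukes_cantor(pN)
  dS <- jukes_cantor(pS)
  omega <- if (is.infinite(dN)) {
    NA_real_                      # nonsynonymous distance saturated
  } else if (is.infinite(dS)) {
    0                             # synonymous saturation: omega forced to 0
  } else if (dS > 0) {
    dN / dS
  } else {
    NA_real_
  }
  list(dN = dN, dS = dS, omega = omega, pN = pN, pS = pS,
       Nd = nd_tot, Sd = sd_tot, N = N, S = S, n_codons = length(ca),
       saturated = pN >= 0.75 || pS >= 0.75)
}

# Jukes-Cantor multiple-hit correction; proportions at or beyond the 3/4
# saturation point map to an infinite distance.
jukes_cantor <- function(p) {
  if (p >= 0.75) return(Inf)
  -0.75 * log(1 - 4 * p / 3)
}

#' Back-translate a protein alignment onto coding sequences
#'
#' Projects each aligned protein row codon-by-codon onto its CDS: every
#' amino-acid column becomes one codon column, protein gaps become `---`.
#' A trailing stop codon on the CDS is dropped. The CDS must translate
#' exactly to the ungapped protein under the standard code.
#'
#' @param protein_alignment Named character vector of aligned amino-acid
#'   sequences (gap `-`), all the same length.
#' @param cds_by_id Named character vector of unaligned CDS covering every
#'   alignment row.
#' @return Named character vector of aligned CDS (class `codon_alignment`).
#' @export
back_translate <- function(protein_alignment, cds_by_id) {
  ids <- names(protein_alignment)
  if (is.null(ids)) stop("protein alignment rows must be named")
  if (length(unique(nchar(protein_alignment))) != 1L) {
    stop("protein alignment rows differ in length")
  }
  out <- character(length(ids))
  names(out) <- ids
  for (id in ids) {
    if (!id %in% names(cds_by_id)) stop("no CDS for aligned id: ", id)
    cds <- cds_by_id[[id]]
    if (is.null(cds) || is.na(cds)) stop("no CDS for aligned id: ", id)
    cds <- drop_trailing_stop(toupper(cds))
    aln <- toupper(protein_alignment[[id]])
    prot <- gsub("-", "", aln, fixed = TRUE)
    if (nchar(cds) != 3L * nchar(prot)) {
      stop("CDS/protein length mismatch for ", id, ": ", nchar(cds),
           " nt vs ", nchar(prot), " aa")
    }
    codons <- split_codons(cds)
    trans <- translate_codons(codons)
    mism <- which(trans != strsplit(prot, "")[[1L]])
    if (length(mism)) {
      stop("CDS does not translate to protein for ", id,
           " at position ", mism[1L])
    }
    cols <- strsplit(aln, "")[[1L]]
    row <- character(length(cols))
    row[cols == "-"] <- "---"
    row[cols != "-"] <- codons
    out[[id]] <- paste(row, collapse = "")
  }
  structure(out, class = "codon_alignment")
}

#' Trim a codon alignment
#'
#' Removes user-specified codon regions (e.g. a variable repeat-motif region)
#' and then every codon column containing a gap in any row, leaving a
#' gap-free alignment suitable for [ng86()].
#'
#' @param aln Codon alignment (named character vector, columns = codons).
#' @param drop_gap_columns Drop codon columns containing a gap in any row.
#' @param mask_regions List of `c(start, end)` codon ranges (1-based,
#'   inclusive) removed before gap trimming.
#' @return Trimmed codon alignment.
#' @export
trim_codon_alignment <- function(aln, drop_gap_columns = TRUE,
                                 mask_regions = list()) {
  ncod <- nchar(aln[[1L]]) / 3L
  if (any(nchar(aln) != ncod * 3L)) {
    stop("alignment rows differ in length or are not codon-sized")
  }
  rows <- lapply(aln, split_codons)
  keep <- rep(TRUE, ncod)
  for (r in mask_regions) {
    if (length(r) != 2L || r[1L] < 1L || r[2L] > ncod || r[1L] > r[2L]) {
      stop("mask region out of bounds: [", paste(r, collapse = ", "),
           "] for ", ncod, " codon columns")
    }
    keep[r[1L]:r[2L]] <- FALSE
  }
  if (drop_gap_columns) {
    gapped <- Reduce(`|`, lapply(rows, function(x) grepl("-", x, fixed = TRUE)))
    keep <- keep & !gapped
  }
  out <- vapply(rows, function(x) paste(x[keep], collapse = ""), character(1L))
  structure(out, class = "codon_alignment")
}

#' Screen orthologue groups for positive selection
#'
#' Runs [ng86()] on every unordered pair within each group's (trimmed,
#' gap-free) codon alignment and aggregates the defined pairwise omega
#' values by their median. A group is flagged as under positive selection
#' when the aggregate exceeds 1.
#'
#' @param alignments Named list of codon alignments, one per group (each a
#'   named character vector of equal-length ungapped CDS rows).
#' @param flag_ds_zero Count pairs with `dS == 0` and `dN > 0` ("unbounded"
#'   omega) as positive evidence. Off by default since omega is undefined.
#' @return A `data.frame` with one row per group: `group`, `n_members`,
#'   `n_pairs`, `n_defined` (pairs with defined omega), `omega` (median of
#'   defined pairwise omegas, `NA` if none), `positive_selection`, `note`.
#'   Per-pair results are attached as `attr(, "pairs")`.
#' @export
screen_groups <- function(alignments, flag_ds_zero = FALSE) {
  groups <- names(alignments)
  if (is.null(groups)) stop("alignments must be a named list keyed by group")
  rows <- vector("list", length(groups))
  pair_rows <- list()
  for (g in seq_along(groups)) {
    aln <- alignments[[g]]
    ids <- names(aln)
    n <- length(ids)
    if (n < 2L) {
      rows[[g]] <- data.frame(group = groups[g], n_members = n, n_pairs = 0L,
                              n_defined = 0L, omega = NA_real_,
                              positive_selection = NA,
                              note = "skipped: fewer than 2 members",
                              stringsAsFactors = FALSE)
      next
    }
    pairs <- utils::combn(n, 2L)
    om <- numeric(0)
    unbounded <- 0L
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      r <- ng86(aln[[i]], aln[[j]])
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(group = groups[g], id_a = ids[i], id_b = ids[j],
                   dN = r$dN, dS = r$dS, omega = r$omega,
                   stringsAsFactors = FALSE)
      if (!is.na(r$omega)) om <- c(om, r$omega)
      else if (r$dN > 0) unbounded <- unbounded + 1L
    }
    agg <- if (length(om)) stats::median(om) else NA_real_
    pos <- if (length(om)) agg > 1 else NA
    note <- ""
    if (!length(om)) note <- "excluded: no pair with defined omega"
    if (unbounded > 0L) {
      note <- paste0(note, if (nzchar(note)) "; ",
                     unbounded, " pair(s) with dS=0, unbounded")
      if (flag_ds_zero && is.na(pos)) pos <- TRUE
    }
    rows[[g]] <- data.frame(group = groups[g], n_members = n,
                            n_pairs = ncol(pairs), n_defined = length(om),
                            omega = agg, positive_selection = pos,
                            note = note, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "pairs") <- if (length(pair_rows)) {
    do.call(rbind, pair_rows)
  } else {
    data.frame(group = character(), id_a = character(), id_b = character(),
               dN = numeric(), dS = numeric(), omega = numeric())
  }
  res
}
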
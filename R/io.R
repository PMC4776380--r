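#' Read a FASTA file into a sequence table
#'
#' Reads protein or CDS FASTA and returns one row per entry. Identifiers are
#' truncated at the first whitespace of the header so that they join directly
#' to the query/subject ids of tabular BLAST output.
#'
#' @param path Path to a FASTA file.
#' @param dataset_label Label of the dataset (species/genotype) of origin,
#'   attached to every record.
#' @return A `data.frame` with columns `id`, `dataset`, `seq`, in file order.
#'   An empty file yields a zero-row table.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a descr", "MKV", ">b", "MA"), fa)
#' read_fasta(fa, "sp1")
#' @export
read_fasta <- function(path, dataset_label) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(id = character(), dataset = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    stop("empty sequence for id(s): ", paste(ids[empty], collapse = ", "))
  }
  data.frame(id = ids, dataset = dataset_label, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param ids Character vector of identifiers.
#' @param seqs Character vector of sequences (same length as `ids`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Pair protein and CDS tables into validated sequence records
#'
#' Joins a protein table and an optional CDS table (both as returned by
#' [read_fasta()]) on `id` and validates the coding relationship: after
#' dropping a trailing stop codon the CDS must be exactly three times the
#' protein length, and the protein must contain no internal stop symbol.
#'
#' @param proteins `data.frame` from [read_fasta()] (protein sequences).
#' @param cds Optional `data.frame` from [read_fasta()] (nucleotide CDS).
#' @return A `data.frame` with columns `id`, `dataset`, `protein`, `cds`
#'   (`NA` where no CDS was supplied).
#' @export
sequence_records <- function(proteins, cds = NULL) {
  if (any(grepl("\\*.", proteins$seq))) {
    bad <- proteins$id[grepl("\\*.", proteins$seq)]
    stop("internal stop symbol in protein(s): ", paste(bad, collapse = ", "))
  }
  prot <- sub("\\*$", "", proteins$seq)
  rec <- data.frame(id = proteins$id, dataset = proteins$dataset,
                    protein = prot, cds = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(cds)) {
    m <- match(rec$id, cds$id)
    cseq <- toupper(cds$seq[m])
    has <- !is.na(m)
    cseq[has] <- drop_trailing_stop(cseq[has])
    bad <- has & nchar(cseq) != 3L * nchar(rec$protein)
    if (any(bad)) {
      stop("CDS length is not 3 x protein length for: ",
           paste(rec$id[bad], collapse = ", "))
    }
    rec$cds <- cseq
  }
  rec
}

drop_trailing_stop <- function(cds) {
  n <- nchar(cds)
  last <- substr(cds, pmax(n - 2L, 1L), n)
  trailing <- n %% 3L == 0L & last %in% c("TAA", "TAG", "TGA")
  cds[trailing] <- substr(cds[trailing], 1L, n[trailing] - 3L)
  cds
}

#' Read tabular BLAST results (outfmt 6)
#'
#' Parses the 12-column tab-separated BLAST dialect
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`, with an optional 13th `qlen` column. When `qlen` is
#' absent, query lengths are taken from `query_lengths`.
#'
#' @param path Path to the TSV file (no header).
#' @param query_lengths Optional named numeric vector mapping query id to
#'   query length; required for coverage computations when the file has no
#'   `qlen` column.
#' @return A `data.frame` of similarity edges with columns `query`,
#'   `subject`, `identity`, `aln_length`, `evalue`, `bitscore`,
#'   `query_length` (`NA` when unavailable).
#' @export
read_blast_tab <- function(path, query_lengths = NULL) {
  if (!file.exists(path)) stop("BLAST table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_edges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- which(!(ncol %in% c(12L, 13L)))
  if (length(bad)) {
    stop("malformed BLAST row (expected 12 or 13 columns) at line ", bad[1L],
         " of ", path)
  }
  m <- do.call(rbind, fields)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      stop("non-numeric ", what, " at line ", which(is.na(v))[1L], " of ", path)
    }
    v
  }
  evalue <- num(11L, "e-value")
  if (any(evalue < 0)) {
    stop("negative e-value at line ", which(evalue < 0)[1L], " of ", path)
  }
  bitscore <- num(12L, "bitscore")
  if (any(bitscore < 0)) {
    warning("negative bitscore(s) in ", path, "; kept as given")
  }
  qlen <- if (all(ncol == 13L)) num(13L, "qlen") else rep(NA_real_, nrow(m))
  edges <- data.frame(
    query = m[, 1L], subject = m[, 2L],
    identity = num(3L, "percent identity"),
    aln_length = num(4L, "alignment length"),
    evalue = evalue, bitscore = bitscore,
    query_length = qlen, stringsAsFactors = FALSE)
  if (!is.null(query_lengths)) {
    miss <- is.na(edges$query_length)
    edges$query_length[miss] <- unname(query_lengths[edges$query[miss]])
  }
  if (any(edges$identity < 0 | edges$identity > 100)) {
    stop("percent identity outside [0, 100] in ", path)
  }
  edges
}

empty_edges <- function() {
  data.frame(query = character(), subject = character(), identity = numeric(),
             aln_length = numeric(), evalue = numeric(), bitscore = numeric(),
             query_length = numeric(), stringsAsFactors = FALSE)
}

#' Write similarity edges as a tabular BLAST file
#'
#' Emits the 13-column dialect read by [read_blast_tab()] (qlen included).
#' Positional columns not represented in the edge table (mismatch, gapopen,
#' start/end coordinates) are filled with consistent placeholders.
#'
#' @param edges Edge `data.frame` (see [read_blast_tab()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(edges, path) {
  n <- nrow(edges)
  out <- data.frame(
    edges$query, edges$subject,
    format(edges$identity, trim = TRUE, scientific = FALSE),
    edges$aln_length,
    rep(0L, n), rep(0L, n), rep(1L, n), edges$aln_length,
    rep(1L, n), edges$aln_length,
    format(edges$evalue, trim = TRUE),
    format(edges$bitscore, trim = TRUE, scientific = FALSE),
    edges$query_length)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a count table plus design into a CountMatrix
#'
#' @param path TSV of raw counts: first column transcript id, remaining
#'   columns one per library; header row holds library ids. Counts must be
#'   non-negative integers (normalisation happens downstream).
#' @param design_path TSV with header `library`, `tissue`, `replicate`;
#'   `tissue` must be `head` or `body`.
#' @param transcript_lengths Optional named vector of transcript lengths in
#'   bp (needed for FPKM).
#' @return A `count_matrix` object: list with `counts` (integer matrix),
#'   `design` (data.frame) and `lengths`.
#' @export
read_counts_table <- function(path, design_path, transcript_lengths = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(counts) <- ids
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  count_matrix(counts, design, transcript_lengths)
}

#' Construct and validate a CountMatrix
#'
#' @param counts Matrix of raw counts, transcripts x libraries, with
#'   dimnames.
#' @param design `data.frame` with columns `library`, `tissue`, `replicate`.
#' @param lengths Optional named vector of transcript lengths (bp).
#' @return A validated `count_matrix` object.
#' @export
count_matrix <- function(counts, design, lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have transcript rownames and library colnames")
  }
  storage <- suppressWarnings(as.numeric(counts))
  if (anyNA(storage)) stop("non-numeric count values")
  counts <- matrix(storage, nrow = nrow(counts), dimnames = dimnames(counts))
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be raw integers")
  req <- c("library", "tissue", "replicate")
  if (!all(req %in% names(design))) {
    stop("design must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(design$tissue %in% c("head", "body"))) {
    stop("tissue labels must be 'head' or 'body'")
  }
  missing <- setdiff(design$library, colnames(counts))
  if (length(missing)) {
    stop("design references libraries absent from the count table: ",
         paste(missing, collapse = ", "))
  }
  counts <- counts[, as.character(design$library), drop = FALSE]
  mode(counts) <- "integer"
  if (!is.null(lengths)) {
    lengths <- lengths[rownames(counts)]
    if (anyNA(lengths) || any(lengths < 1)) {
      stop("transcript lengths must cover all transcripts and be >= 1 bp")
    }
  }
  structure(list(counts = counts, design = design, lengths = lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "transcripts x",
      ncol(x$counts), "libraries\n")
  cat("  tissues:", paste(sprintf("%s=%d", names(table(x$design$tissue)),
                                  table(x$design$tissue)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a per-sequence annotation table
#'
#' The table carries upstream predictor output consumed as plain columns:
#' signal peptide, transmembrane domain, nuclear localisation signal,
#' best database hit e-value (empty field = no hit) and Pfam-A presence.
#'
#' @param path TSV with header
#'   `id  signal_peptide  tm_domain  nls  best_db_hit_evalue  pfamA`;
#'   flag columns take `yes`/`no`.
#' @return A `data.frame` keyed by `id` with logical columns
#'   `has_signal_peptide`, `has_tm_domain`, `has_nls`, `has_pfamA` and
#'   numeric `best_db_hit_evalue` (`NA` = no hit).
#' @export
read_annotation_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  req <- c("id", "signal_peptide", "tm_domain", "nls",
           "best_db_hit_evalue", "pfamA")
  if (!all(req %in% names(tab))) {
    stop("annotation table must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate annotation id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  flag <- function(col) {
    v <- trimws(tab[[col]])
    bad <- !(v %in% c("yes", "no"))
    if (any(bad)) {
      stop("unknown flag token '", v[bad][1L], "' in column ", col)
    }
    v == "yes"
  }
  ev <- trimws(tab$best_db_hit_evalue)
  evalue <- suppressWarnings(as.numeric(ev))
  bad <- nzchar(ev) & is.na(evalue)
  if (any(bad)) stop("non-numeric best_db_hit_evalue: ", ev[bad][1L])
  annotation_table(tab$id, flag("signal_peptide"), flag("tm_domain"),
                   flag("nls"), evalue, flag("pfamA"))
}

#' Build an annotation table in memory
#'
#' @param id Sequence identifiers (unique).
#' @param has_signal_peptide,has_tm_domain,has_nls,has_pfamA Logical flags.
#' @param best_db_hit_evalue Numeric e-value of the best database hit,
#'   `NA` for "no hit".
#' @return Annotation `data.frame` as from [read_annotation_table()].
#' @export
annotation_table <- function(id, has_signal_peptide, has_tm_domain, has_nls,
                             best_db_hit_evalue, has_pfamA) {
  if (anyDuplicated(id)) stop("duplicate annotation id(s)")
  data.frame(id = as.character(id),
             has_signal_peptide = as.logical(has_signal_peptide),
             has_tm_domain = as.logical(has_tm_domain),
             has_nls = as.logical(has_nls),
             best_db_hit_evalue = as.numeric(best_db_hit_evalue),
             has_pfamA = as.logical(has_pfamA),
             stringsAsFactors = FALSE)
}

#' Write an annotation table as TSV
#'
#' @param ann Annotation `data.frame` (see [annotation_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(ann, path) {
  yn <- function(x) ifelse(x, "yes", "no")
  out <- data.frame(id = ann$id,
                    signal_peptide = yn(ann$has_signal_peptide),
                    tm_domain = yn(ann$has_tm_domain),
                    nls = yn(ann$has_nls),
                    best_db_hit_evalue = ifelse(is.na(ann$best_db_hit_evalue),
                                                "",
                                                format(ann$best_db_hit_evalue,
                                                       trim = TRUE)),
                    pfamA = yn(ann$has_pfamA))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write graph edges in MCL "abc" format
#'
#' Three tab-separated columns: query, hit, e-value.
#'
#' @param edges Edge `data.frame` with `query`, `subject`, `evalue`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abc <- function(edges, path) {
  out <- data.frame(edges$query, edges$subject,
                    format(edges$evalue, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a counts matrix and design as TSV files
#'
#' @param cm A `count_matrix`.
#' @param counts_path,design_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts_table <- function(cm, counts_path, design_path) {
  tab <- data.frame(transcript = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cm$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}
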
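best_hits <- function(edges, min_identity, min_coverage) {
  if (!nrow(edges)) {
    return(data.frame(query = character(), subject = character(),
                      identity = numeric(), coverage = numeric(),
                      bitscore = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (anyNA(edges$query_length)) {
    stop("query_length required for coverage filtering ",
         "(13-column BLAST table or a length map)")
  }
  cov <- 100 * edges$aln_length / edges$query_length
  e <- edges[edges$identity >= min_identity & cov >= min_coverage, ,
             drop = FALSE]
  cov <- cov[edges$identity >= min_identity & cov >= min_coverage]
  if (!nrow(e)) {
    return(best_hits(empty_edges(), min_identity, min_coverage))
  }
  # Rank hits by bitscore rounded to one decimal (BLAST reporting
  # granularity); a query whose top score is shared by two or more subjects
  # is dropped entirely (tie rejection).
  bs <- round(e$bitscore, 1L)
  rows <- lapply(split(seq_len(nrow(e)), e$query), function(i) {
    top <- i[bs[i] == max(bs[i])]
    top <- top[!duplicated(e$subject[top])]
    if (length(top) != 1L) return(NULL)
    data.frame(query = e$query[top], subject = e$subject[top],
               identity = e$identity[top], coverage = cov[top],
               bitscore = e$bitscore[top], evalue = e$evalue[top],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) best_hits(empty_edges(), min_identity, min_coverage)
  else out
}

#' Reciprocal best BLAST hit (RBBH) 1:1 orthologue pairs
#'
#' For each query in either direction the best hit is the highest-bitscore
#' edge among those passing the identity and query-coverage thresholds;
#' queries whose top bitscore is tied between two or more subjects yield no
#' best hit (as expected for recent gene duplications). A pair is emitted
#' only when the two sequences are each other's unique best hit.
#'
#' @param edges_ab Directional edges, dataset A queries against dataset B.
#' @param edges_ba Directional edges, dataset B queries against dataset A.
#' @param min_identity Minimum percent identity. Default 70.
#' @param min_coverage Minimum percent query coverage
#'   (`100 * aln_length / query_length`), applied to each direction's own
#'   query, so a pair satisfies coverage on both sequences. Default 50.
#' @param known_ids Optional character vector: the valid id universe; edges
#'   mentioning other ids raise an error.
#' @return `data.frame` with `id_a`, `id_b`, `identity`, `coverage`,
#'   `bitscore` (from the a-to-b hit) and `evalue` (minimum of the two
#'   directions).
#' @export
rbbh_pairs <- function(edges_ab, edges_ba, min_identity = 70,
                       min_coverage = 50, known_ids = NULL) {
  if (!is.null(known_ids)) {
    seen <- unique(c(edges_ab$query, edges_ab$subject,
                     edges_ba$query, edges_ba$subject))
    unknown <- setdiff(seen, known_ids)
    if (length(unknown)) {
      stop("edges reference unknown ids: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
  }
  ab <- best_hits(edges_ab, min_identity, min_coverage)
  ba <- best_hits(edges_ba, min_identity, min_coverage)
  if (!nrow(ab) || !nrow(ba)) {
    return(data.frame(id_a = character(), id_b = character(),
                      identity = numeric(), coverage = numeric(),
                      bitscore = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  back <- stats::setNames(ba$subject, ba$query)
  mutual <- !is.na(back[ab$subject]) & back[ab$subject] == ab$query
  ab <- ab[mutual, , drop = FALSE]
  ev_ba <- stats::setNames(ba$evalue, ba$query)
  out <- data.frame(id_a = ab$query, id_b = ab$subject,
                    identity = ab$identity, coverage = ab$coverage,
                    bitscore = ab$bitscore,
                    evalue = pmin(ab$evalue, ev_ba[ab$subject]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$id_a), , drop = FALSE]
}

#' Group RBBH pairs into 1:1 orthologue groups
#'
#' Pairs from all dataset combinations are written as abc-style edges
#' (query, hit, e-value; the smaller of the two directional e-values) and
#' grouped with the same Markov clustering engine used for the whole-graph
#' analysis, at the same inflation.
#'
#' @param pairs Row-bound [rbbh_pairs()] output across all dataset pairs.
#' @param effector_ids Candidate effector ids used to flag groups.
#' @param params [mcl_params()] for the grouping step.
#' @return `data.frame` with `group`, `member`; per-group summary (size,
#'   `contains_effector`) in `attr(, "groups")`.
#' @export
rbbh_groups <- function(pairs, effector_ids = character(),
                        params = mcl_params()) {
  if (!nrow(pairs)) {
    res <- data.frame(group = integer(), member = character())
    attr(res, "groups") <- data.frame(group = integer(), n_members = integer(),
                                      contains_effector = logical())
    return(res)
  }
  edges <- data.frame(query = pairs$id_a, subject = pairs$id_b,
                      evalue = pairs$evalue, stringsAsFactors = FALSE)
  graph <- build_graph(edges, evalue_threshold = Inf)
  cl <- mcl_cluster(graph, params)
  res <- data.frame(group = cl$cluster, member = cl$member,
                    stringsAsFactors = FALSE)
  ids <- split(res$member, res$group)
  attr(res, "groups") <- data.frame(
    group = as.integer(names(ids)),
    n_members = lengths(ids),
    contains_effector = vapply(ids, function(m) any(m %in% effector_ids),
                               logical(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  res
}
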
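#' Build an undirected similarity graph from pairwise hits
#'
#' Keeps edges at or below the e-value threshold (self hits discarded),
#' transforms e-values to weights `-log10(evalue)` with e-value 0 mapped to
#' weight 200, and merges reciprocal edges keeping the larger weight. Nodes
#' without any surviving edge remain in the graph as isolated nodes so that
#' hit-less sequences become singleton clusters.
#'
#' @param edges Edge `data.frame` (see [read_blast_tab()]).
#' @param nodes Character vector: the full node universe. Defaults to the
#'   ids appearing in `edges`.
#' @param evalue_threshold Keep edges with `evalue <= threshold`.
#'   Default 1e-35.
#' @return A `similarity_graph`: list with `nodes` and an edge table
#'   (`from`, `to`, `weight`).
#' @export
build_graph <- function(edges, nodes = NULL, evalue_threshold = 1e-35) {
  if (is.null(nodes)) nodes <- unique(c(edges$query, edges$subject))
  keep <- edges$evalue <= evalue_threshold & edges$query != edges$subject
  e <- edges[keep, , drop = FALSE]
  unknown <- setdiff(unique(c(e$query, e$subject)), nodes)
  if (length(unknown)) {
    stop("edges reference ids outside the node universe: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  w <- ifelse(e$evalue == 0, 200, -log10(e$evalue))
  a <- pmin(e$query, e$subject)
  b <- pmax(e$query, e$subject)
  key <- paste(a, b, sep = "\r")
  w <- tapply(w, key, max)
  et <- if (length(w)) {
    ab <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    data.frame(from = ab[, 1L], to = ab[, 2L], weight = as.numeric(w),
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), weight = numeric())
  }
  rownames(et) <- NULL
  structure(list(nodes = nodes, edges = et), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("SimilarityGraph:", length(x$nodes), "nodes,", nrow(x$edges),
      "undirected edges\n")
  invisible(x)
}

#' Markov Cluster (MCL) parameters
#'
#' @param inflation Inflation exponent (> 1). Default 6.
#' @param prune_threshold Matrix entries below this are pruned each
#'   iteration. Default 1e-5.
#' @param max_iterations Iteration cap. Default 200.
#' @param convergence_tol Convergence when the largest entry change falls
#'   below this. Default 1e-8.
#' @return List of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 6, prune_threshold = 1e-5,
                       max_iterations = 200L, convergence_tol = 1e-8) {
  if (inflation <= 1) stop("inflation must be > 1")
  structure(list(inflation = inflation, prune_threshold = prune_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol), class = "mcl_params")
}

#' Markov clustering of a similarity graph
#'
#' Dense-matrix MCL: self-loops are added with each node's maximum incident
#' edge weight (1 for isolated nodes), columns are normalised to stochastic,
#' and the process alternates expansion (matrix squaring) with inflation
#' (entrywise power, renormalise) and pruning until the matrix stops
#' changing. Clusters are read off the attractor structure of the limit
#' matrix: rows with a nonzero diagonal are attractors, attractors sharing
#' nodes are merged, and every node joins the cluster of an attractor
#' supporting it (ties resolved towards the lexicographically smallest
#' attractor id, so output is deterministic).
#'
#' @param graph A `similarity_graph` from [build_graph()].
#' @param params An [mcl_params()].
#' @return A `data.frame` with `cluster` (integer id, 1-based, ordered by
#'   smallest member id) and `member`. `attr(, "converged")` reports
#'   convergence.
#' @export
mcl_cluster <- function(graph, params = mcl_params()) {
  nodes <- sort(graph$nodes)
  n <- length(nodes)
  if (n == 0L) {
    return(structure(data.frame(cluster = integer(), member = character()),
                     converged = TRUE))
  }
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, nodes)
    j <- match(graph$edges$to, nodes)
    A[cbind(i, j)] <- graph$edges$weight
    A[cbind(j, i)] <- graph$edges$weight
  }
  loop <- apply(A, 1L, max)
  diag(A) <- ifelse(loop > 0, loop, 1)
  M <- normalise_columns(A)
  converged <- FALSE
  for (it in seq_len(params$max_iterations)) {
    M_new <- M %*% M
    M_new <- normalise_columns(M_new^params$inflation)
    M_new[M_new < params$prune_threshold] <- 0
    M_new <- normalise_columns(M_new)
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", params$max_iterations,
            " iterations; interpreting the current matrix")
  }
  res <- interpret_mcl_matrix(M, nodes)
  attr(res, "converged") <- converged
  res
}

normalise_columns <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1
  sweep(M, 2L, cs, "/")
}

# Read clusters off a (near-)idempotent MCL matrix. M[i, j] > 0 means node j
# is attracted to attractor i.
interpret_mcl_matrix <- function(M, nodes) {
  eps <- 1e-12
  attractors <- which(diag(M) > eps)
  if (!length(attractors)) attractors <- seq_along(nodes)
  # Merge attractors that support any common node (weak connectivity of the
  # attractor system).
  g <- igraph::make_empty_graph(n = length(attractors), directed = FALSE)
  support <- lapply(attractors, function(a) which(M[a, ] > eps))
  for (j in seq_along(nodes)) {
    within <- which(vapply(support, function(s) j %in% s, logical(1L)))
    if (length(within) > 1L) {
      g <- igraph::add_edges(g, rbind(within[-length(within)], within[-1L]))
    }
  }
  comp <- igraph::components(g)$membership
  assignment <- integer(length(nodes))
  for (j in seq_along(nodes)) {
    owners <- attractors[vapply(support, function(s) j %in% s, logical(1L))]
    if (!length(owners)) owners <- attractors[which.max(M[attractors, j])]
    # A node supported by several components joins the component holding the
    # smallest attractor id; nodes[] is sorted so index order is
    # lexicographic order.
    assignment[j] <- comp[match(min(owners), attractors)]
  }
  # Number clusters by their lexicographically smallest member.
  relabel <- match(assignment, unique(assignment))
  out <- data.frame(cluster = relabel, member = nodes,
                    stringsAsFactors = FALSE)
  out[order(out$cluster, out$member), , drop = FALSE]
}

#' Cluster membership summaries with effector and core labels
#'
#' Flags clusters containing at least one candidate effector and, among
#' those, the "core" clusters represented by at least `min_datasets` of the
#' focal (aphid) datasets; outgroup datasets never count towards the core
#' membership tally.
#'
#' @param clusters `data.frame` from [mcl_cluster()].
#' @param effector_ids Candidate effector ids (this study's calls plus any
#'   published candidate lists).
#' @param dataset_of Named character vector mapping member id to dataset.
#' @param aphid_datasets Datasets counting towards core membership; defaults
#'   to every dataset seen.
#' @param min_datasets Core threshold. Default 5 (of 8).
#' @return `data.frame` with one row per cluster: `cluster`, `n_members`,
#'   `n_datasets` (focal datasets represented), `contains_effector`, `core`.
#' @export
label_and_find_core <- function(clusters, effector_ids, dataset_of,
                                aphid_datasets = NULL, min_datasets = 5L) {
  unmapped <- setdiff(clusters$member, names(dataset_of))
  if (length(unmapped)) {
    stop("members without a dataset mapping: ",
         paste(utils::head(unmapped, 5L), collapse = ", "))
  }
  ds <- dataset_of[clusters$member]
  if (is.null(aphid_datasets)) aphid_datasets <- unique(ds)
  ids <- split(clusters$member, clusters$cluster)
  dss <- split(unname(ds), clusters$cluster)
  out <- data.frame(
    cluster = as.integer(names(ids)),
    n_members = lengths(ids),
    n_datasets = vapply(dss, function(d) {
      length(unique(d[d %in% aphid_datasets]))
    }, integer(1L)),
    contains_effector = vapply(ids, function(m) {
      any(m %in% effector_ids)
    }, logical(1L)),
    stringsAsFactors = FALSE)
  out$core <- out$contains_effector & out$n_datasets >= min_datasets
  rownames(out) <- NULL
  out[order(out$cluster), , drop = FALSE]
}

#' Find pioneer effector clusters
#'
#' A pioneer cluster contains a candidate effector, every member lacks both
#' a database hit (at or below `db_evalue`) and a Pfam-A domain, and its
#' members are confined to a single species or a single genus.
#'
#' @param clusters `data.frame` from [mcl_cluster()].
#' @param annotations Annotation table with `best_db_hit_evalue`, `has_pfamA`.
#' @param effector_ids Candidate effector ids.
#' @param dataset_of Named map member id -> dataset.
#' @param genus_of Named map dataset -> genus; `species_of` likewise.
#' @param species_of Named map dataset -> species.
#' @param db_evalue Hits at e-values above this do not count as database
#'   hits. Default 1e-5.
#' @return `data.frame` per cluster with `cluster`, `contains_effector`,
#'   `all_unannotated`, `single_species`, `single_genus`, `pioneer`.
#' @export
find_pioneers <- function(clusters, annotations, effector_ids, dataset_of,
                          species_of, genus_of, db_evalue = 1e-5) {
  if (is.null(names(genus_of)) || is.null(names(species_of))) {
    stop("species_of and genus_of must be named by dataset")
  }
  ds <- dataset_of[clusters$member]
  if (anyNA(ds)) stop("members without a dataset mapping")
  if (anyNA(genus_of[unique(ds)])) {
    stop("missing genus mapping for dataset(s): ",
         paste(unique(ds)[is.na(genus_of[unique(ds)])], collapse = ", "))
  }
  m <- match(clusters$member, annotations$id)
  has_hit <- !is.na(annotations$best_db_hit_evalue[m]) &
    annotations$best_db_hit_evalue[m] <= db_evalue
  has_pfam <- annotations$has_pfamA[m]
  unann <- ifelse(is.na(m), TRUE, !has_hit & !has_pfam)
  by_cluster <- split(seq_len(nrow(clusters)), clusters$cluster)
  out <- data.frame(
    cluster = as.integer(names(by_cluster)),
    contains_effector = vapply(by_cluster, function(i) {
      any(clusters$member[i] %in% effector_ids)
    }, logical(1L)),
    all_unannotated = vapply(by_cluster, function(i) all(unann[i]),
                             logical(1L)),
    single_species = vapply(by_cluster, function(i) {
      length(unique(species_of[ds[i]])) == 1L
    }, logical(1L)),
    single_genus = vapply(by_cluster, function(i) {
      length(unique(genus_of[ds[i]])) == 1L
    }, logical(1L)),
    stringsAsFactors = FALSE)
  out$pioneer <- out$contains_effector & out$all_unannotated &
    (out$single_species | out$single_genus)
  rownames(out) <- NULL
  out[order(out$cluster), , drop = FALSE]
}
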
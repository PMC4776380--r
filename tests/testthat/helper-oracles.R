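# Independent oracles, coded separately from the package internals.

GC <- Biostrings::GENETIC_CODE
SENSE <- names(GC)[GC != "*"]

# --- Nei-Gojobori by exhaustive pathway enumeration -------------------------

# Synonymous site fraction of one codon, counting changes to stop codons as
# nonsynonymous.
oracle_syn_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (nt in nts) {
      if (nt == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (GC[[mut]] != "*" && GC[[mut]] == GC[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

PERMS <- list(matrix(1L, 1, 1),
              rbind(c(1L, 2L), c(2L, 1L)),
              rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# Enumerate every ordering of the differing positions explicitly; average the
# per-step synonymous/nonsynonymous counts over pathways whose intermediate
# codons are not stops, falling back to all pathways (stop steps counted
# nonsynonymous) when every pathway is blocked.
oracle_codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  walk <- function(order, strict) {
    cur <- c1
    sd <- 0; nd <- 0
    for (step in seq_along(order)) {
      p <- pos[order[step]]
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (strict && GC[[nxt]] == "*" && nxt != c2) return(NULL)
      if (GC[[cur]] != "*" && GC[[cur]] == GC[[nxt]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  perms <- PERMS[[k]]
  res <- lapply(seq_len(nrow(perms)), function(r) walk(perms[r, ], TRUE))
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    res <- lapply(seq_len(nrow(perms)), function(r) walk(perms[r, ], FALSE))
  }
  colMeans(do.call(rbind, res))
}

oracle_ng86 <- function(cds_a, cds_b) {
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  S <- (sum(vapply(ca, oracle_syn_sites, numeric(1))) +
          sum(vapply(cb, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca), function(i) {
    oracle_codon_diffs(ca[i], cb[i])
  }, numeric(2)))
  jc <- function(p) if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  list(Sd = d[["sd"]], Nd = d[["nd"]], S = S, N = N,
       dS = jc(d[["sd"]] / S), dN = jc(d[["nd"]] / N))
}

random_sense_cds <- function(n_codons) {
  paste(sample(SENSE, n_codons, replace = TRUE), collapse = "")
}

# --- Reference MCL ----------------------------------------------------------

# Naive loop-based MCL on a weighted adjacency matrix; returns the partition
# as a list of sorted member vectors (sorted by first member).
oracle_mcl <- function(adj, inflation = 6, prune = 1e-5, tol = 1e-8,
                       max_iter = 200) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  for (i in seq_len(n)) {
    mx <- max(adj[i, ])
    adj[i, i] <- if (mx > 0) mx else 1
  }
  colnorm <- function(m) {
    for (j in seq_len(ncol(m))) {
      s <- sum(m[, j])
      if (s > 0) m[, j] <- m[, j] / s
    }
    m
  }
  M <- colnorm(adj)
  for (it in seq_len(max_iter)) {
    nxt <- colnorm((M %*% M)^inflation)
    nxt[nxt < prune] <- 0
    nxt <- colnorm(nxt)
    if (max(abs(nxt - M)) < tol) {
      M <- nxt
      break
    }
    M <- nxt
  }
  attractors <- which(diag(M) > 1e-12)
  if (!length(attractors)) attractors <- seq_len(n)
  # union-find over attractors sharing supported nodes
  parent <- seq_along(attractors)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  support <- lapply(attractors, function(a) which(M[a, ] > 1e-12))
  for (j in seq_len(n)) {
    holders <- which(vapply(support, function(s) j %in% s, logical(1)))
    if (length(holders) > 1) {
      for (h in holders[-1]) parent[find(h)] <- find(holders[1])
    }
  }
  roots <- vapply(seq_along(attractors), find, integer(1))
  assign <- integer(n)
  for (j in seq_len(n)) {
    holders <- which(vapply(support, function(s) j %in% s, logical(1)))
    if (!length(holders)) holders <- which.max(M[attractors, j])
    best <- holders[which.min(attractors[holders])]
    assign[j] <- roots[best]
  }
  parts <- split(nodes, assign)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1))])
}

# Convert a package cluster data.frame to the same canonical form.
partition_of <- function(clusters) {
  parts <- split(clusters$member, clusters$cluster)
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[`, character(1), 1))])
}

adj_from_edges <- function(edges, nodes) {
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    w <- if (edges$evalue[r] == 0) 200 else -log10(edges$evalue[r])
    i <- edges$query[r]; j <- edges$subject[r]
    A[i, j] <- max(A[i, j], w)
    A[j, i] <- max(A[j, i], w)
  }
  A
}

make_edges <- function(query, subject, evalue, identity = 90,
                       aln_length = 100, bitscore = 200, query_length = 100) {
  data.frame(query = query, subject = subject, identity = identity,
             aln_length = aln_length, evalue = evalue, bitscore = bitscore,
             query_length = query_length, stringsAsFactors = FALSE)
}

# --- Step-by-step TMM arithmetic --------------------------------------------

# Literal transcription of the trimmed-mean-of-M-values definition: reference
# column by upper quartile closest to the mean upper quartile, 30 % trim on
# M, 5 % on A, precision weights, factors scaled to geometric mean 1.
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, stats::quantile, p = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    obs <- counts[, j] / lib[j]
    rf <- counts[, ref] / lib[ref]
    keep <- obs > 0 & rf > 0
    M <- log2(obs[keep] / rf[keep])
    A <- (log2(obs[keep]) + log2(rf[keep])) / 2
    w <- (lib[j] - counts[keep, j]) / (lib[j] * counts[keep, j]) +
      (lib[ref] - counts[keep, ref]) / (lib[ref] * counts[keep, ref])
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[j] <- 2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  }
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# --- Small builders ---------------------------------------------------------

make_cm <- function(counts, reps = ncol(counts) / 2, lengths = NULL) {
  libs <- colnames(counts)
  if (is.null(libs)) {
    libs <- paste0("L", seq_len(ncol(counts)))
    colnames(counts) <- libs
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("t", seq_len(nrow(counts)))
  }
  design <- data.frame(library = libs,
                       tissue = rep(c("head", "body"), each = reps),
                       replicate = rep(seq_len(reps), 2),
                       stringsAsFactors = FALSE)
  count_matrix(counts, design, lengths)
}

make_de <- function(ids, direction) {
  data.frame(id = ids, logFC = ifelse(direction == "head_up", 2,
                                      ifelse(direction == "body_up", -2, 0)),
             p_value = ifelse(direction == "ns", 0.5, 1e-6),
             direction = direction, stringsAsFactors = FALSE)
}
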
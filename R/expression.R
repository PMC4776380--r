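#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-library normalisation factors computed against a reference
#' library (the one whose 75th count percentile is closest to the mean 75th
#' percentile), trimming 30 percent of genes on log-ratio (M) and 5 percent
#' on average log-abundance (A), with precision weighting; genes with a zero
#' count in either library of a comparison are excluded pairwise. Factors
#' are rescaled to have geometric mean 1. Computation is delegated to
#' edgeR's TMM implementation, the method's reference codebase.
#'
#' @param counts Count matrix (transcripts x libraries) or a
#'   [count_matrix()].
#' @return Named numeric vector of scaling factors, one per library.
#' @export
tmm_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 libraries")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop("all-zero library: ", paste(colnames(counts)[zero], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = 0.3, sumTrim = 0.05,
                              doWeighting = TRUE)
  stats::setNames(f, colnames(counts))
}

#' TMM-normalised FPKM
#'
#' `FPKM = count * 1e9 / (effective library size * transcript length)`,
#' where the effective library size is the column sum times its TMM factor.
#'
#' @param counts Count matrix or [count_matrix()] (the latter must carry
#'   transcript lengths).
#' @param factors Scaling factors from [tmm_factors()].
#' @param lengths Transcript lengths in bp (ignored when `counts` is a
#'   `count_matrix` with lengths).
#' @return Matrix of TMM-FPKM values.
#' @export
tmm_fpkm <- function(counts, factors = tmm_factors(counts), lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(lengths)) lengths <- counts$lengths
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (is.null(lengths)) stop("transcript lengths are required for FPKM")
  lengths <- if (!is.null(names(lengths))) lengths[rownames(counts)] else lengths
  if (anyNA(lengths) || any(lengths <= 0)) {
    stop("transcript lengths must be positive for all transcripts")
  }
  eff <- colSums(counts) * factors[colnames(counts)]
  sweep(counts, 2L, eff, "/") * 1e9 / lengths
}

# Method-of-moments common NB dispersion on counts scaled to equal effective
# library sizes. Within each tissue group, E[s^2 - m] = phi * mu^2 and
# E[m^2 - s^2/n] = mu^2, so a ratio-of-sums estimator over all
# transcript-by-group cells is used, floored at 0.
estimate_common_dispersion <- function(scaled, tissue) {
  num <- 0; den <- 0
  for (tis in unique(tissue)) {
    y <- scaled[, tissue == tis, drop = FALSE]
    n <- ncol(y)
    if (n < 2L) next
    m <- rowMeans(y)
    v <- apply(y, 1L, stats::var)
    use <- m > 0
    num <- num + sum(v[use] - m[use])
    den <- den + sum(m[use]^2 - v[use] / n)
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

# Two-sided exact test for a head/body split of a total count t at
# equalised library sizes: the conditional distribution of the head total is
# proportional to dnbinom(k; n_h/phi, n_h*mu) * dnbinom(t-k; n_b/phi, n_b*mu)
# with mu = t/(n_h+n_b); dispersion 0 degenerates to Binomial(t, n_h/(n_h+n_b)).
# The p-value sums the probabilities of all outcomes no more likely than the
# observed one.
exact_nb_pvalue <- function(y_head, y_body, n_head, n_body, phi) {
  t <- y_head + y_body
  if (t == 0) return(1)
  k <- 0:t
  if (phi <= 0) {
    logp <- stats::dbinom(k, t, n_head / (n_head + n_body), log = TRUE)
  } else {
    mu <- t / (n_head + n_body)
    logp <- stats::dnbinom(k, size = n_head / phi, mu = n_head * mu,
                           log = TRUE) +
      stats::dnbinom(t - k, size = n_body / phi, mu = n_body * mu, log = TRUE)
  }
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[y_head + 1L]
  min(1, sum(p[p <= obs * (1 + 1e-8)]))
}

#' Exact negative-binomial head-vs-body differential expression test
#'
#' A documented simplification of the exact-test strategy used for small
#' count experiments: TMM-scaled counts are brought to equal effective
#' library sizes, a single common NB dispersion is estimated by the method
#' of moments (floored at 0, in which case the test degenerates to an exact
#' binomial test), and tissue totals are compared with a two-sided exact
#' test. Calls use the raw p-value at `p < alpha`; ties at `alpha` are not
#' called. Transcripts with zero counts everywhere are reported `ns` with
#' `p = 1`.
#'
#' @param cm A [count_matrix()] with head and body libraries.
#' @param alpha Raw p-value threshold. Default 0.001.
#' @param dispersion Optional fixed common dispersion (overrides
#'   estimation); 0 gives the exact binomial test.
#' @return A `data.frame` with `id`, `logFC` (log2 head over body, based on
#'   scaled tissue means with a 0.5-count prior), `p_value`, `direction`
#'   (`head_up` / `body_up` / `ns`). The dispersion used is attached as
#'   `attr(, "dispersion")`.
#' @export
exact_test_de <- function(cm, alpha = 0.001, dispersion = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  tissue <- cm$design$tissue
  if (!all(c("head", "body") %in% tissue)) {
    stop("both head and body libraries are required")
  }
  if (min(table(tissue)) < 2L) stop("need >= 2 replicates per tissue")
  counts <- cm$counts
  f <- tmm_factors(counts)
  eff <- colSums(counts) * f
  target <- exp(mean(log(eff)))
  scaled <- sweep(counts, 2L, target / eff, "*")
  phi <- if (is.null(dispersion)) {
    estimate_common_dispersion(scaled, tissue)
  } else {
    if (dispersion < 0) stop("dispersion must be >= 0")
    dispersion
  }
  head_idx <- tissue == "head"
  n_head <- sum(head_idx)
  n_body <- sum(!head_idx)
  y_head <- round(rowSums(scaled[, head_idx, drop = FALSE]))
  y_body <- round(rowSums(scaled[, !head_idx, drop = FALSE]))
  p <- vapply(seq_len(nrow(counts)), function(i) {
    exact_nb_pvalue(y_head[i], y_body[i], n_head, n_body, phi)
  }, numeric(1L))
  logfc <- log2((y_head / n_head + 0.5) / (y_body / n_body + 0.5))
  direction <- rep("ns", nrow(counts))
  sig <- p < alpha & logfc != 0
  direction[sig & logfc > 0] <- "head_up"
  direction[sig & logfc < 0] <- "body_up"
  res <- data.frame(id = rownames(counts), logFC = logfc, p_value = p,
                    direction = direction, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "dispersion") <- phi
  res
}
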
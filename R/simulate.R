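#' Configuration for the synthetic repertoire generator
#'
#' Defaults emulate the study design the pipeline targets: 8 aphid-like
#' datasets (three genotypes of one species, a congeneric second species,
#' and four further species), gene families shared across datasets with
#' occasional recent duplications, head-biased effector families, and
#' negative-binomial head/body counts with 3 replicates per tissue.
#'
#' @param n_datasets Number of datasets (>= 2). Default 8.
#' @param n_families Number of gene families. Default 40.
#' @param presence_prob Probability that a (non-pioneer) family is present
#'   in any given dataset. Default 0.8.
#' @param codon_length Codons per gene (>= 10; shorter genes make the
#'   Nei-Gojobori counts unstable). Default 100.
#' @param branch_scale Expected proposed nucleotide changes per site on each
#'   root-to-tip branch of the star phylogeny. Default 0.05.
#' @param effector_fraction Fraction of families that are true effectors
#'   (signal peptide, no TM domain, head-biased expression). Default 0.2.
#' @param pioneer_fraction Fraction of effector families seeded as pioneers:
#'   no database hit, no Pfam-A domain, confined to a single dataset.
#'   Default 0.25.
#' @param nls_fraction Fraction of effector families carrying a nuclear
#'   localisation signal. Default 0.3.
#' @param secreted_noneffector_fraction Fraction of non-effector families
#'   that are nonetheless secreted (signal peptide, no TM). Default 0.1.
#' @param tm_fraction Fraction of non-effector families with signal peptide
#'   plus a transmembrane domain (exercises the TM exclusion). Default 0.05.
#' @param duplication_rate Per-family probability of one recent duplication:
#'   an identical within-dataset copy, which produces tied similarity scores.
#'   Default 0.05.
#' @param omega_per_family Optional numeric vector (length `n_families`) of
#'   true dN/dS values; all must be > 0. When `NULL`, non-effector families
#'   get `omega_background`, effector families `omega_effector`, except a
#'   `positive_fraction` of effector families which get `omega_positive`.
#' @param omega_background,omega_effector,omega_positive True omega for
#'   background, ordinary effector, and positively selected effector
#'   families. Defaults 0.2, 0.5, 3.
#' @param positive_fraction Fraction of effector families evolving at
#'   `omega_positive`. Default 0.25.
#' @param fold_change Head/body mean-count ratio for effector transcripts.
#'   Default 8.
#' @param effector_base_mean Body-tissue mean count of effector transcripts.
#'   Default 500.
#' @param base_meanlog,base_sdlog Log-normal parameters for background
#'   transcript means. Defaults log(100) and 1.
#' @param dispersion Negative-binomial dispersion phi (> 0). Default 0.1.
#' @param replicates Libraries per tissue. Default 3.
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_datasets = 8L, n_families = 40L,
                       presence_prob = 0.8, codon_length = 100L,
                       branch_scale = 0.05, effector_fraction = 0.2,
                       pioneer_fraction = 0.25, nls_fraction = 0.3,
                       secreted_noneffector_fraction = 0.1,
                       tm_fraction = 0.05, duplication_rate = 0.05,
                       omega_per_family = NULL, omega_background = 0.2,
                       omega_effector = 0.5, omega_positive = 3,
                       positive_fraction = 0.25, fold_change = 8,
                       effector_base_mean = 500,
                       base_meanlog = log(100), base_sdlog = 1,
                       dispersion = 0.1, replicates = 3L, seed = 1L) {
  cfg <- list(n_datasets = as.integer(n_datasets),
              n_families = as.integer(n_families),
              presence_prob = presence_prob,
              codon_length = as.integer(codon_length),
              branch_scale = branch_scale,
              effector_fraction = effector_fraction,
              pioneer_fraction = pioneer_fraction,
              nls_fraction = nls_fraction,
              secreted_noneffector_fraction = secreted_noneffector_fraction,
              tm_fraction = tm_fraction,
              duplication_rate = duplication_rate,
              omega_per_family = omega_per_family,
              omega_background = omega_background,
              omega_effector = omega_effector,
              omega_positive = omega_positive,
              positive_fraction = positive_fraction,
              fold_change = fold_change,
              effector_base_mean = effector_base_mean,
              base_meanlog = base_meanlog, base_sdlog = base_sdlog,
              dispersion = dispersion,
              replicates = as.integer(replicates),
              seed = as.integer(seed))
  if (cfg$n_datasets < 2L) stop("n_datasets must be >= 2")
  if (cfg$codon_length < 10L) {
    stop("codon_length must be >= 10 (NG86 unstable on shorter genes)")
  }
  fracs <- c(cfg$presence_prob, cfg$effector_fraction, cfg$pioneer_fraction,
             cfg$nls_fraction, cfg$secreted_noneffector_fraction,
             cfg$tm_fraction, cfg$duplication_rate, cfg$positive_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$branch_scale < 0) stop("branch_scale must be >= 0")
  om <- cfg$omega_per_family
  if (!is.null(om)) {
    if (length(om) != cfg$n_families) {
      stop("omega_per_family must have length n_families")
    }
    if (any(om <= 0)) stop("omega values must be > 0")
  }
  if (any(c(cfg$omega_background, cfg$omega_effector, cfg$omega_positive) <= 0)) {
    stop("omega values must be > 0")
  }
  if (cfg$dispersion <= 0) stop("dispersion must be > 0")
  if (cfg$replicates < 2L) stop("at least 2 replicates per tissue")
  structure(cfg, class = "sim_config")
}

random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# Evolve a CDS by acceptance-rejection on proposed single-nucleotide changes.
# Nonsynonymous proposals are accepted with probability min(1, omega) and
# synonymous ones with min(1, 1/omega), so the realised nonsyn:syn fixation
# ratio equals omega on both sides of 1. Proposals creating stop codons are
# always rejected.
evolve_cds <- function(cds, n_proposals, omega) {
  nts <- c("A", "C", "G", "T")
  code <- genetic_code()
  seqv <- strsplit(cds, "")[[1L]]
  p_non <- min(1, omega)
  p_syn <- min(1, 1 / omega)
  for (k in seq_len(n_proposals)) {
    pos <- sample.int(length(seqv), 1L)
    new_nt <- sample(setdiff(nts, seqv[pos]), 1L)
    c0 <- (pos - 1L) %/% 3L
    idx <- (c0 * 3L + 1L):(c0 * 3L + 3L)
    old_codon <- paste(seqv[idx], collapse = "")
    newv <- seqv[idx]
    newv[pos - c0 * 3L] <- new_nt
    new_codon <- paste(newv, collapse = "")
    if (code[[new_codon]] == "*") next
    syn <- code[[new_codon]] == code[[old_codon]]
    p <- if (syn) p_syn else p_non
    if (stats::runif(1L) <= p) seqv[pos] <- new_nt
  }
  paste(seqv, collapse = "")
}

translate_cds <- function(cds) {
  paste(translate_codons(split_codons(cds)), collapse = "")
}

#' Simulate one diverged coding-sequence pair
#'
#' A random stop-free root CDS evolves independently down two branches of
#' length `t/2` each (total divergence time `t`, in expected proposed
#' substitutions per site) under the acceptance-rejection scheme of
#' [simulate_repertoires()].
#'
#' @param length Number of codons (>= 10).
#' @param omega True dN/dS (> 0).
#' @param t Total divergence (expected proposed changes per site, >= 0).
#' @param seed Integer seed.
#' @return A list with `cds_a` and `cds_b`.
#' @export
simulate_codon_pair <- function(length, omega, t, seed) {
  if (length < 10L) stop("length must be >= 10 codons")
  if (omega <= 0) stop("omega must be > 0")
  if (t < 0) stop("t must be >= 0")
  set.seed(seed)
  root <- random_cds(length)
  n_sites <- 3L * length
  na <- stats::rpois(1L, t / 2 * n_sites)
  nb <- stats::rpois(1L, t / 2 * n_sites)
  list(cds_a = evolve_cds(root, na, omega),
       cds_b = evolve_cds(root, nb, omega))
}

#' Simulate multi-dataset effector repertoires with ground truth
#'
#' Generates gene families shared across datasets on a star phylogeny
#' (independent divergence from a random root CDS per family), evolves
#' members by acceptance-rejection codon evolution at the family's true
#' omega, assigns family-level secretion/TM/NLS labels, seeds pioneer
#' families (no database hit, no Pfam-A, single dataset) and occasional
#' recent duplications (identical within-dataset copies).
#'
#' @param config A [sim_config()].
#' @return A list with `records` (data.frame: `id`, `dataset`, `protein`,
#'   `cds`), `annotations` (see [annotation_table()]), `truth` (list with
#'   `sequences`, `families`, `datasets` tables) and `config`.
#' @export
simulate_repertoires <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nd <- config$n_datasets
  datasets <- sprintf("ds%02d", seq_len(nd))
  # Mirror a genotype/species/genus structure: datasets 1-3 are genotypes of
  # species sp01; ds04 is a congeneric species; the rest are separate genera.
  species <- c("sp01", "sp01", "sp01", "sp02",
               sprintf("sp%02d", seq_len(max(nd - 4L, 0L)) + 2L))[seq_len(nd)]
  genus <- ifelse(species %in% c("sp01", "sp02"), "genus01",
                  sub("sp", "genus", species))
  ds_table <- data.frame(dataset = datasets, species = species, genus = genus,
                         stringsAsFactors = FALSE)

  nf <- config$n_families
  n_eff <- round(config$effector_fraction * nf)
  effector <- seq_len(nf) <= n_eff
  pioneer <- rep(FALSE, nf)
  if (n_eff > 0L) {
    pioneer[seq_len(round(config$pioneer_fraction * n_eff))] <- TRUE
  }
  n_pos <- round(config$positive_fraction * n_eff)
  omega <- config$omega_per_family
  if (is.null(omega)) {
    omega <- rep(config$omega_background, nf)
    omega[effector] <- config$omega_effector
    if (n_pos > 0L) {
      pos_idx <- which(effector & !pioneer)
      pos_idx <- pos_idx[seq_len(min(n_pos, length(pos_idx)))]
      omega[pos_idx] <- config$omega_positive
    }
  }
  nls <- effector & stats::runif(nf) < config$nls_fraction
  sp_flag <- effector
  tm_flag <- rep(FALSE, nf)
  u <- stats::runif(nf)
  sp_flag[!effector & u < config$secreted_noneffector_fraction] <- TRUE
  both <- !effector & u >= config$secreted_noneffector_fraction &
    u < config$secreted_noneffector_fraction + config$tm_fraction
  sp_flag[both] <- TRUE
  tm_flag[both] <- TRUE

  seq_rows <- list()
  fam_datasets <- vector("list", nf)
  for (f in seq_len(nf)) {
    root <- random_cds(config$codon_length)
    present <- if (pioneer[f]) {
      datasets[sample.int(nd, 1L)]
    } else {
      hit <- datasets[stats::runif(nd) < config$presence_prob]
      if (!length(hit)) hit <- datasets[sample.int(nd, 1L)]
      hit
    }
    fam_datasets[[f]] <- present
    n_sites <- 3L * config$codon_length
    members <- lapply(present, function(ds) {
      np <- stats::rpois(1L, config$branch_scale * n_sites)
      cds <- evolve_cds(root, np, omega[f])
      data.frame(id = sprintf("%s.f%03d", ds, f), dataset = ds,
                 family = f, cds = cds, stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, members)
    if (stats::runif(1L) < config$duplication_rate) {
      dup <- fam[sample.int(nrow(fam), 1L), ]
      dup$id <- paste0(dup$id, ".d2")
      fam <- rbind(fam, dup)
    }
    seq_rows[[f]] <- fam
  }
  seqs <- do.call(rbind, seq_rows)
  seqs$protein <- vapply(seqs$cds, translate_cds, character(1L),
                         USE.NAMES = FALSE)
  seqs$effector <- effector[seqs$family]
  seqs$pioneer <- pioneer[seqs$family]
  seqs$omega <- omega[seqs$family]
  seqs$fold_change <- ifelse(seqs$effector, config$fold_change, 1)
  rownames(seqs) <- NULL

  ann <- annotation_table(
    id = seqs$id,
    has_signal_peptide = sp_flag[seqs$family],
    has_tm_domain = tm_flag[seqs$family],
    has_nls = nls[seqs$family],
    best_db_hit_evalue = ifelse(pioneer[seqs$family], NA_real_, 1e-40),
    has_pfamA = !pioneer[seqs$family])

  families <- data.frame(family = seq_len(nf), effector = effector,
                         pioneer = pioneer, omega = omega, nls = nls,
                         secreted = sp_flag, tm = tm_flag,
                         n_datasets = lengths(fam_datasets),
                         stringsAsFactors = FALSE)
  families$datasets <- vapply(fam_datasets, paste, character(1L),
                              collapse = ",")

  list(records = seqs[, c("id", "dataset", "protein", "cds")],
       annotations = ann,
       truth = list(sequences = seqs[, c("id", "dataset", "family",
                                         "effector", "pioneer", "omega",
                                         "fold_change")],
                    families = families, datasets = ds_table),
       config = config)
}

#' Simulate head/body count matrices from a repertoire ground truth
#'
#' Counts are negative binomial with dispersion `config$dispersion`. The
#' head mean of an effector transcript is `fold_change` times its body mean;
#' all other transcripts have equal means in both tissues. Library depths
#' vary uniformly within +/- 25 percent.
#'
#' @param truth The `truth` element of [simulate_repertoires()] output.
#' @param config The matching [sim_config()].
#' @param base_means Optional named vector overriding body-tissue mean
#'   counts per transcript (a zero mean yields an all-zero row, retained).
#' @return Named list of [count_matrix()] objects, one per dataset.
#' @export
simulate_expression <- function(truth, config, base_means = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$dispersion <= 0) stop("dispersion must be > 0")
  set.seed(config$seed + 1L)
  size <- 1 / config$dispersion
  reps <- config$replicates
  out <- list()
  for (ds in truth$datasets$dataset) {
    tr <- truth$sequences[truth$sequences$dataset == ds, ]
    if (!nrow(tr)) next
    mu_body <- if (is.null(base_means)) {
      ifelse(tr$effector, config$effector_base_mean,
             stats::rlnorm(nrow(tr), config$base_meanlog, config$base_sdlog))
    } else {
      v <- base_means[tr$id]
      if (anyNA(v)) stop("base_means must cover every transcript")
      unname(v)
    }
    mu_head <- mu_body * tr$fold_change
    libs <- c(sprintf("%s_head_r%d", ds, seq_len(reps)),
              sprintf("%s_body_r%d", ds, seq_len(reps)))
    tissue <- rep(c("head", "body"), each = reps)
    depth <- stats::runif(2L * reps, 0.8, 1.25)
    counts <- matrix(0L, nrow(tr), 2L * reps,
                     dimnames = list(tr$id, libs))
    for (j in seq_len(2L * reps)) {
      mu <- (if (tissue[j] == "head") mu_head else mu_body) * depth[j]
      counts[, j] <- stats::rnbinom(nrow(tr), size = size, mu = mu)
    }
    design <- data.frame(library = libs, tissue = tissue,
                         replicate = rep(seq_len(reps), 2L),
                         stringsAsFactors = FALSE)
    lens <- stats::setNames(rep(3L * config$codon_length, nrow(tr)), tr$id)
    out[[ds]] <- count_matrix(counts, design, lens)
  }
  out
}

#' Emit all-vs-all similarity edges for synthetic repertoires
#'
#' Replaces an all-vs-all BLASTP for synthetic runs: global identity is the
#' fraction of matching positions after equal-length truncation, the
#' bitscore proxy is `identity_percent * aln_length / 10`, and the e-value
#' proxy is `10^(-bitscore / 2)` floored at 1e-180 (strictly monotone in
#' identity, so best-hit and clustering behaviour is well defined). Ordered
#' pairs below 20 percent identity are omitted; both directions are emitted.
#'
#' @param records Sequence `data.frame` with `id` and `protein` columns.
#' @return Edge `data.frame` in the layout of [read_blast_tab()].
#' @export
emit_similarity_edges <- function(records) {
  n <- nrow(records)
  if (n < 2L) return(empty_edges())
  lens <- nchar(records$protein)
  L <- min(lens)
  chars <- t(vapply(substr(records$protein, 1L, L),
                    function(s) strsplit(s, "")[[1L]], character(L)))
  matches <- matrix(0, n, n)
  for (a in unique(as.vector(chars))) {
    ind <- (chars == a) * 1
    matches <- matches + tcrossprod(ind)
  }
  idx <- which(upper.tri(matches), arr.ind = TRUE)
  identity <- 100 * matches[idx] / L
  keep <- identity >= 20
  idx <- idx[keep, , drop = FALSE]
  identity <- identity[keep]
  bitscore <- identity * L / 10
  evalue <- pmax(10^(-bitscore / 2), 1e-180)
  ids <- records$id
  two_way <- data.frame(
    query = c(ids[idx[, 1L]], ids[idx[, 2L]]),
    subject = c(ids[idx[, 2L]], ids[idx[, 1L]]),
    identity = c(identity, identity),
    aln_length = L,
    evalue = c(evalue, evalue),
    bitscore = c(bitscore, bitscore),
    query_length = c(lens[idx[, 1L]], lens[idx[, 2L]]),
    stringsAsFactors = FALSE)
  two_way[order(two_way$query, two_way$subject), , drop = FALSE]
}
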
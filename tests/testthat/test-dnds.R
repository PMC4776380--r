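test_that("back-translation maps residue columns to codon columns", {
  aln <- c(s1 = "M-K", s2 = "MAK")
  cds <- c(s1 = "ATGAAA", s2 = "ATGGCTAAA")
  bt <- back_translate(aln, cds)
  expect_equal(unname(bt["s1"]), "ATG---AAA")
  expect_equal(unname(bt["s2"]), "ATGGCTAAA")

  # trailing stop codon accepted and dropped
  bt2 <- back_translate(c(s1 = "MK"), c(s1 = "ATGAAATAA"))
  expect_equal(unname(bt2["s1"]), "ATGAAA")

  expect_error(back_translate(c(s1 = "MK"), c(s1 = "ATGAAAA")),
               "length mismatch for s1")
  expect_error(back_translate(c(s1 = "MM"), c(s1 = "ATGAAA")),
               "position 2")
  expect_error(back_translate(c(s1 = "MK"), c(other = "ATGAAA")),
               "no CDS")
})

test_that("trimming removes masked regions then gapped codon columns", {
  aln <- structure(c(s1 = "ATG---AAATTT", s2 = "ATGGCTAAATTT"),
                   class = "codon_alignment")
  t1 <- trim_codon_alignment(aln)
  expect_equal(as.character(t1), c("ATGAAATTT", "ATGAAATTT"))

  # mask the first 2 codon columns (e.g. a repeat-motif region)
  t2 <- trim_codon_alignment(aln, mask_regions = list(c(1, 2)))
  expect_equal(as.character(t2), c("AAATTT", "AAATTT"))

  clean <- structure(c(a = "ATGAAA", b = "ATGCCC"), class = "codon_alignment")
  expect_equal(as.character(trim_codon_alignment(clean)),
               as.character(clean))
  expect_error(trim_codon_alignment(aln, mask_regions = list(c(1, 9))),
               "out of bounds")
})

test_that("a 120-residue mask removes 360 nucleotides before analysis", {
  set.seed(42)
  cds <- random_sense_cds(150)
  aln <- structure(c(a = cds, b = cds), class = "codon_alignment")
  trimmed <- trim_codon_alignment(aln, mask_regions = list(c(1, 120)))
  expect_equal(nchar(trimmed[["a"]]), 150 * 3 - 360)
})

test_that("NG86 handles identity, single changes, and symmetry", {
  r0 <- ng86("ATGAAA", "ATGAAA")
  expect_equal(r0$dN, 0)
  expect_equal(r0$dS, 0)
  expect_true(is.na(r0$omega))

  r1 <- ng86("ATGGCT", "ATGGCC")   # synonymous third-position change
  expect_equal(r1$dN, 0)
  expect_gt(r1$dS, 0)
  expect_equal(r1$omega, 0)

  set.seed(10)
  for (i in 1:20) {
    a <- random_sense_cds(30)
    b <- paste(vapply(strsplit(a, "")[[1]], function(nt) {
      if (runif(1) < 0.05) sample(c("A", "C", "G", "T"), 1) else nt
    }, character(1)), collapse = "")
    if (any(Biostrings::GENETIC_CODE[
      substring(b, seq(1, 89, 3), seq(3, 90, 3))] == "*")) next
    ra <- ng86(a, b)
    rb <- ng86(b, a)
    expect_equal(ra[c("dN", "dS", "Nd", "Sd", "N", "S")],
                 rb[c("dN", "dS", "Nd", "Sd", "N", "S")])
  }
})

test_that("site counts always total three per codon", {
  sites <- effectorscan:::codon_syn_sites()
  r <- ng86(random_sense_cds(40), random_sense_cds(40))
  expect_equal(r$N + r$S, 3 * 40)
  expect_true(all(sites >= 0 & sites <= 3))
})

test_that("NG86 validates its input contract", {
  expect_error(ng86("ATGAAA", "ATG"), "length")
  expect_error(ng86("ATG---", "ATGAAA"), "trim")
  expect_error(ng86("ATGTAA", "ATGAAA"), "stop codon")
})

test_that("pathway averaging equals exhaustive enumeration on mixed codons", {
  # every 2- and 3-difference codon pair in a deterministic sample
  set.seed(99)
  for (i in 1:300) {
    c1 <- sample(SENSE, 1)
    c2 <- sample(SENSE, 1)
    d <- effectorscan:::codon_pair_diffs(c1, c2)
    o <- oracle_codon_diffs(c1, c2)
    expect_equal(unname(d), unname(o), tolerance = 1e-12)
  }
  # a 10-codon pair with two mixed-codon differences against the full oracle
  a <- "ATGGCTAAATTTGGGCCCTACGATCAGTGG"
  b <- "ATGGCAAAATTTGGGCCCTTCGGTCAGTGG"
  r <- ng86(a, b)
  o <- oracle_ng86(a, b)
  expect_equal(r$Sd, o$Sd, tolerance = 1e-12)
  expect_equal(r$Nd, o$Nd, tolerance = 1e-12)
  expect_equal(r$dN, o$dN, tolerance = 1e-12)
  expect_equal(r$dS, o$dS, tolerance = 1e-12)
})

test_that("group screening aggregates pairwise omega and flags > 1", {
  same <- structure(c(x = "ATGAAA", y = "ATGAAA"), class = "codon_alignment")
  res <- screen_groups(list(g1 = same))
  expect_true(is.na(res$omega))
  expect_match(res$note, "no pair with defined omega")

  single <- structure(c(x = "ATGAAA"), class = "codon_alignment")
  res1 <- screen_groups(list(g = single))
  expect_match(res1$note, "fewer than 2")

  set.seed(3)
  pos <- simulate_codon_pair(200, 5, 0.3, seed = 81)
  neg <- simulate_codon_pair(200, 0.05, 0.3, seed = 82)
  res2 <- screen_groups(list(up = structure(c(a = pos$cds_a, b = pos$cds_b),
                                            class = "codon_alignment"),
                             down = structure(c(a = neg$cds_a, b = neg$cds_b),
                                              class = "codon_alignment")))
  expect_true(res2$positive_selection[res2$group == "up"])
  expect_false(res2$positive_selection[res2$group == "down"])
  pairs <- attr(res2, "pairs")
  expect_equal(nrow(pairs), 2)
  expect_true(all(pairs$dN >= 0 & pairs$dS >= 0))
})

test_that("dS-zero pairs count as positive only under the explicit option", {
  # one nonsynonymous difference (Lys -> Arg), no synonymous ones
  aln <- structure(c(a = "ATGAAA", b = "ATGAGA"), class = "codon_alignment")
  r <- ng86("ATGAAA", "ATGAGA")
  expect_equal(r$dS, 0)
  expect_gt(r$dN, 0)
  res <- screen_groups(list(g = aln))
  expect_true(is.na(res$positive_selection))
  expect_match(res$note, "unbounded")
  res2 <- screen_groups(list(g = aln), flag_ds_zero = TRUE)
  expect_true(res2$positive_selection)
})
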
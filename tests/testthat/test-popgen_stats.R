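test_that("nucleotide diversity matches the allele-frequency identity", {
  expect_equal(nucleotide_diversity(
    haplotype_alignment(rep("ACGTACGT", 3), paste0("h", 1:3))), 0)
  one_mismatch <- haplotype_alignment(
    c(strrep("A", 100), paste0(strrep("A", 99), "T")), c("x", "y"))
  expect_equal(nucleotide_diversity(one_mismatch), 0.01)

  # independent oracle: pi * L = sum_sites 2 p (1 - p) n / (n - 1)
  for (seed in 1:5) {
    aln <- simulate_coalescent_alignment(8, 6, 100, seed = seed)
    n <- 8
    freq_pi <- sum(apply(aln$matrix, 2, function(col) {
      p <- mean(col == col[1])
      2 * p * (1 - p) * n / (n - 1)
    })) / aln$length
    expect_equal(nucleotide_diversity(aln), freq_pi, tolerance = 1e-12)
  }
  expect_error(nucleotide_diversity(one_mismatch, "x"), "2 chromosomes")
})

test_that("Watterson's theta reproduces printed values from S, n, L", {
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_equal(round(watterson_theta(15, 1194, 1002) * 100, 3), 0.195)
  expect_equal(round(watterson_theta(3, 166, 1002) * 100, 3), 0.053)
  expect_error(watterson_theta(3, 1, 100), "n >= 2")
})

test_that("Tajima's D matches an independently computed value and edge cases", {
  # frozen oracle: 4 x 10 alignment, S = 2, computed by hand from the 1989
  # constants (a1, a2, b1, b2, c1, c2, e1, e2)
  aln <- haplotype_alignment(
    c("AAAAAAAAAA", "AAAAAAAAAT", "TAAAAAAAAA", "TAAAAAAAAT"),
    paste0("h", 1:4))
  pi <- nucleotide_diversity(aln)
  S <- segregating_sites(aln)
  expect_equal(S, 2L)
  expect_equal(tajimas_d(pi, S, 4, 10), 1.8930564476785954, tolerance = 1e-12)

  # numerator zero when pi * L equals S / a1
  n <- 6
  a1 <- sum(1 / (1:5))
  expect_equal(tajimas_d((3 / a1) / 50, 3, n, 50), 0)
  expect_true(is.na(tajimas_d(0, 0, 10, 100)))
})

test_that("coalescent null for D is centred, has heavy-D tails, and is seeded", {
  p0 <- tajima_d_pvalue(0, 20, 0.01, 500, replicates = 400, seed = 3)
  expect_gt(p0, 0.9)
  p_extreme <- tajima_d_pvalue(5, 20, 0.01, 500, replicates = 400, seed = 3)
  expect_lt(p_extreme, 0.01)
  expect_identical(tajima_d_pvalue(1, 12, 0.01, 300, 200, seed = 11),
                   tajima_d_pvalue(1, 12, 0.01, 300, 200, seed = 11))
  expect_true(is.na(tajima_d_pvalue(1, 12, 0, 300, 200)))
})

test_that("moderate observed D values are not significant under the null", {
  # a Table-1-sized case: D = 0.94 with n = 166 chromosomes
  p <- tajima_d_pvalue(0.94, 166, 5e-4, 1002, replicates = 1000, seed = 5)
  expect_gte(p, 0.05)
})

test_that("Hudson F_ST matches brute-force pair enumeration", {
  a <- haplotype_alignment(c("AAA", "AAT", "TAA", "TAT"),
                           c("p1a", "p1b", "p2a", "p2b"))
  m <- population_map(c("p1a", "p1b", "p2a", "p2b"),
                      c("p1", "p1", "p2", "p2"), a)
  r <- pairwise_fst(a, m, "p1", "p2")
  expect_equal(r$fst, 1 / 3)  # Hw = 1, Hb = 1.5
  expect_equal(r$nm, 0.5)

  # fixed, fully diverged populations
  b <- haplotype_alignment(c("AAAA", "AAAA", "TTTT", "TTTT"),
                           c("p1a", "p1b", "p2a", "p2b"))
  expect_equal(pairwise_fst(b, m, "p1", "p2")$fst, 1)

  # identical composition in both populations: no positive differentiation
  # signal (Hudson's Hw slightly exceeds Hb in finite samples, so the
  # estimate is weakly negative and Nm maps to the infinite-migration flag)
  seqs <- rep(c("AAAT", "AATA"), 10)
  ids <- paste0("c", 1:20)
  same <- haplotype_alignment(seqs, ids)
  msame <- population_map(ids, rep(c("p1", "p2"), each = 10), same)
  r0 <- pairwise_fst(same, msame, "p1", "p2")
  expect_lte(r0$fst, 0)
  expect_lt(abs(r0$fst), 0.15)
  expect_identical(r0$nm, Inf)
})

test_that("F_ST <-> Nm conversion is exact and handles the edge cases", {
  expect_equal(nm_from_fst(0.5), 0.25)
  expect_equal(fst_from_nm(0.25), 0.5)
  expect_equal(round(fst_from_nm(12.02), 2), 0.02)
  for (fst in seq(0.01, 1, by = 0.07))
    expect_equal(fst_from_nm(nm_from_fst(fst)), fst, tolerance = 1e-12)
  expect_identical(nm_from_fst(0), Inf)
  expect_identical(nm_from_fst(-0.03), Inf)

  kii_nm <- c(3.27, 2.19, 1.75, 12.02, 15.49, 2.20, 2.09)
  expect_equal(round(mean(kii_nm), 1), 5.6)
})

test_that("haplotype spectrum reports sharing fractions over chromosomes", {
  fx <- kii_like_sample()
  sp <- haplotype_spectrum(fx$alignment, fx$map)
  kii <- sp$sharing[sp$sharing$population == "Kii", ]
  expect_equal(kii$private_fraction, 23 / 80)
  expect_equal(kii$shared_fraction + kii$private_fraction, 1)

  # counts conserve population sizes and frequencies sum to one
  for (p in levels(fx$map$population)) {
    sub <- sp$table[sp$table$population == p, ]
    expect_equal(sum(sub$count), sum(fx$map$population == p))
    expect_equal(sum(sub$frequency), 1, tolerance = 1e-12)
  }

  # single population: everything is private by definition
  solo <- population_map(fx$map$chromosome_id[1:80], "Kii", fx$alignment)
  sp1 <- haplotype_spectrum(fx$alignment, solo)
  expect_equal(sp1$sharing$private_fraction, 1)

  # one haplotype shared by all populations: nothing private
  aln <- haplotype_alignment(rep("ACGT", 6), paste0("c", 1:6))
  m <- population_map(paste0("c", 1:6), rep(c("x", "y", "z"), each = 2), aln)
  expect_true(all(haplotype_spectrum(aln, m)$sharing$private_fraction == 0))
})

test_that("the Kii-like allele spectrum tallies to the design counts", {
  fx <- kii_like_sample()
  sp <- haplotype_spectrum(fx$alignment, fx$map)
  kii_counts <- sort(sp$table$count[sp$table$population == "Kii"])
  expect_equal(kii_counts, sort(unname(fx$counts)))
  # the 23-copy (private) haplotype sits at frequency 29%
  priv <- sp$table[sp$table$population == "Kii" & sp$table$private, ]
  expect_equal(round(priv$frequency * 100), 29)
})

test_that("diversity summary assembles per-population rows", {
  fx <- kii_like_sample()
  ds <- diversity_summary(fx$alignment, fx$map)
  expect_equal(ds$population, c("Kii", "Neighbour", "All"))
  expect_equal(ds$n_chromosomes, c(80L, 10L, 90L))
  expect_equal(ds$n_haplotypes, c(6L, 5L, 6L))
  expect_true(all(ds$pi >= 0 & ds$theta_w >= 0))
})

test_that("Nei-Gojobori site counts follow the per-codon enumeration", {
  gg <- count_syn_nonsyn_sites("GGG")
  expect_equal(gg$syn_sites, 1)
  expect_equal(gg$nonsyn_sites, 2)

  atg <- count_syn_nonsyn_sites("ATGAAA")
  expect_equal(atg$syn_sites, 1 / 3)
  expect_equal(atg$nonsyn_sites, 17 / 3)

  empty <- count_syn_nonsyn_sites("")
  expect_equal(empty$syn_sites, 0)
  expect_equal(empty$nonsyn_sites, 0)

  expect_error(count_syn_nonsyn_sites("ATGA"), "divisible by 3")
  expect_error(count_syn_nonsyn_sites("ATGTAAAAA"), "stop codon")

  # totals always close to 3 sites per codon under this stop convention
  set.seed(2)
  for (i in 1:5) {
    codons <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                             c("TAA", "TAG", "TGA")), 20, replace = TRUE)
    cds <- paste(codons, collapse = "")
    ct <- count_syn_nonsyn_sites(cds)
    expect_equal(ct$syn_sites + ct$nonsyn_sites, 3 * 20)
  }
})

test_that("single-variant consequence calls use the codon table", {
  expect_equal(classify_snv("ATGGGGTGG", 2, "C"), "start-loss")
  expect_equal(classify_snv("ATGGGGTGG", 6, "A"), "synonymous")   # GGG > GGA
  expect_equal(classify_snv("ATGGGGTGG", 8, "A"), "nonsense")     # TGG > TAG
  expect_equal(classify_snv("ATGGGGTGG", 4, "A"), "nonsynonymous")
  expect_error(classify_snv("ATGGGG", 4, "G"), "reference")
  expect_error(classify_snv("ATGGGG", 9, "A"), "outside")
})
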
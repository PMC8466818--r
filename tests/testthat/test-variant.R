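test_that("percent identity reproduces the reported family identities", {
  set.seed(411)
  cds1635 <- random_cds(1635)
  cds1638 <- random_cds(1638)
  # one mismatch on the CBDAS-length cds
  expect_equal(percent_identity(cds1635, mutate_at(cds1635, 100, "N")), 99.94)
  # four mismatches: the most divergent CBDAS clone
  pos4 <- c(100, 400, 800, 1200)
  expect_equal(percent_identity(cds1635, mutate_at(cds1635, pos4, rep("N", 4))),
               99.76)
  # three diagnostic mismatches on the CBCAS/THCAS-length cds
  v3 <- cds1638
  for (p in c(13, 18, 1628)) {
    old <- substr(v3, p, p)
    v3 <- mutate_at(v3, p, setdiff(BASES4, old)[1])
  }
  expect_equal(percent_identity(cds1638, v3), 99.82)
  # two mismatches
  expect_equal(percent_identity(cds1638, mutate_at(cds1638, c(10, 20), c("N", "N"))),
               99.88)
})

test_that("percent identity is symmetric, 100 iff identical, matches a naive oracle", {
  set.seed(412)
  for (i in 1:20) {
    a <- random_dna(200)
    k <- sample(0:30, 1)
    b <- mutate_at(a, sample(200, k), sample(BASES4, k, replace = TRUE))
    # oracle rounded the same way for comparability at 2 dp
    expect_equal(percent_identity(a, b), round(naive_identity(a, b) + 1e-9, 2))
    expect_equal(percent_identity(a, b), percent_identity(b, a))
    expect_identical(percent_identity(a, b) == 100, a == b)
  }
  expect_error(percent_identity("", "ACGT"), "empty")
})

test_that("unequal-length sequences are aligned before identity", {
  a <- paste0("ATG", strrep("GCT", 50), "TAA")
  b <- paste0("ATG", strrep("GCT", 49), "TAA")  # one codon missing
  pid <- percent_identity(a, b)
  expect_true(pid > 97 && pid < 100)
})

test_that("codon mapping follows the floor formula", {
  expect_equal(codon_index(1426), 476L)
  expect_equal(codon_index(1), 1L)
  expect_equal(codon_index(3), 1L)
  expect_equal(codon_index(986), 329L)
  expect_error(codon_index(0), ">= 1")
})

test_that("substitution classification agrees with a whole-cds translation oracle", {
  set.seed(413)
  cds <- random_cds(300)
  for (i in 1:40) {
    pos <- sample(4:297, 1)
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(BASES4, ref), 1)
    got <- classify_substitution(pos, alt, cds)
    want <- naive_effect(pos, alt, cds)
    expect_equal(got$effect, want$effect)
    expect_equal(got$aa_from, want$aa_from)
    expect_equal(got$aa_to, want$aa_to)
  }
  # third-position G>T in an alanine codon is synonymous
  ctx <- paste0("ATG", strrep("AAA", 33), "GCG", strrep("AAA", 40), "TAA")
  got <- classify_substitution(105, "T", ctx)
  expect_equal(got$effect, "synonymous")
  expect_equal(got$aa_from, "A")
  # Pro -> Ser through C>T at the first codon position
  ctx2 <- paste0(strrep("AAA", 475), "CCA", "TAA")
  got2 <- classify_substitution(1426, "T", ctx2)
  expect_equal(got2[c("effect", "aa_from", "aa_to")],
               list(effect = "missense", aa_from = "P", aa_to = "S"))
  # TGG -> TGA is nonsense
  ctx3 <- paste0("ATG", "TGG", strrep("AAA", 30), "TAA")
  expect_equal(classify_substitution(6, "A", ctx3)$effect, "nonsense")
  expect_error(classify_substitution(6, "G", ctx3), "equals the reference")
})

test_that("SNP calling recovers exactly the injected substitution set", {
  set.seed(414)
  ref_seq <- random_cds(1635)
  ref <- seq_record("ref", ref_seq, role = "reference")
  expect_equal(nrow(call_snps(seq_record("q0", ref_seq), ref)$snps), 0)
  expect_equal(call_snps(seq_record("q0", ref_seq), ref)$identity_pct, 100)

  for (i in 1:10) {
    k <- sample(1:20, 1)
    pos <- sort(sample(4:1632, k))
    alt <- vapply(pos, function(p)
      sample(setdiff(BASES4, substr(ref_seq, p, p)), 1), "")
    q <- seq_record("q", mutate_at(ref_seq, pos, alt))
    st <- call_snps(q, ref)
    expect_equal(st$snps$pos_nt, pos)
    expect_equal(st$snps$alt_allele, alt)
    expect_equal(st$identity_pct, round(100 * (1635 - k) / 1635 + 1e-9, 2))
  }
  expect_error(call_snps(seq_record("q", random_dna(100)), ref), "align")
})

test_that("identity from SNP count matches percent_identity on equal lengths", {
  set.seed(415)
  ref_seq <- random_cds(900)
  ref <- seq_record("ref", ref_seq)
  pos <- sample(4:897, 12)
  alt <- vapply(pos, function(p) sample(setdiff(BASES4, substr(ref_seq, p, p)), 1), "")
  q <- seq_record("q", mutate_at(ref_seq, pos, alt))
  st <- call_snps(q, ref)
  expect_equal(st$identity_pct, percent_identity(q, ref))
  expect_equal(100 * (st$aligned_length_nt - nrow(st$snps)) / st$aligned_length_nt,
               st$identity_pct, tolerance = 0.005)
})

test_that("critical-residue checks flag deviations at the catalytic positions", {
  set.seed(416)
  aa <- strsplit(translate_cds(random_cds(1638))$aa, "")[[1]]
  aa[110] <- "R"; aa[114] <- "H"; aa[176] <- "C"
  ref_protein <- paste(aa, collapse = "")
  prof <- critical_residue_set(ref_protein)
  expect_equal(prof$position, c(110:114, 176))
  expect_true(check_critical_residues(ref_protein, prof)$all_intact)

  mut <- ref_protein
  substr(mut, 176, 176) <- "S"
  rep_ <- check_critical_residues(mut, prof)
  expect_false(rep_$all_intact)
  expect_equal(rep_$deviations$position, 176)
  expect_equal(rep_$deviations$observed, "S")

  expect_error(check_critical_residues(substr(ref_protein, 1, 100), prof),
               "shorter")
})
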
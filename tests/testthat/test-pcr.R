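test_that("binding-site search equals a brute-force all-offsets scan", {
  set.seed(421)
  for (i in 1:25) {
    tmpl <- random_dna(sample(200:800, 1))
    # half the time plant a degraded copy of a real subsequence
    start <- sample(50:150, 1)
    primer <- substr(tmpl, start, start + 19)
    if (i %% 2 == 0) {
      p <- sample(1:17, 1)  # keep the 3' clamp clean
      primer <- mutate_at(primer, p, sample(setdiff(BASES4, substr(primer, p, p)), 1))
    }
    mm <- sample(0:2, 1)
    got <- find_binding_sites(primer, tmpl, max_mismatch = mm, clamp_3prime = 3)
    want <- naive_sites(primer, tmpl, mm, 3)
    got <- got[order(got$strand, got$pos5), ]
    expect_equal(got$pos5, want$pos5)
    expect_equal(got$strand, want$strand)
    expect_equal(got$mismatches, want$mm)
  }
})

test_that("the 3'-clamp rule rejects terminal mismatches regardless of budget", {
  tmpl <- paste0(strrep("C", 40), "ATTGACCGTAGGCTAAGTCA", strrep("C", 40))
  site <- "ATTGACCGTAGGCTAAGTCA"
  expect_equal(nrow(find_binding_sites(site, tmpl)), 1)
  # one internal mismatch: found with budget 2, absent with budget 0
  internal <- mutate_at(site, 5, "T")
  expect_equal(nrow(find_binding_sites(internal, tmpl, max_mismatch = 2)), 1)
  expect_equal(find_binding_sites(internal, tmpl, max_mismatch = 2)$mismatches, 1)
  expect_equal(nrow(find_binding_sites(internal, tmpl, max_mismatch = 0)), 0)
  # 3'-terminal mismatch: never accepted
  tm3 <- mutate_at(site, 20, "G")
  expect_equal(nrow(find_binding_sites(tm3, tmpl, max_mismatch = 5)), 0)
})

test_that("IUPAC ambiguity in the template matches compatible primer bases", {
  tmpl <- paste0(strrep("G", 30), "ACGTACGTACGTACGTACRT", strrep("G", 30))
  primer <- "ACGTACGTACGTACGTACAT"  # A compatible with R = A/G
  hit <- find_binding_sites(primer, tmpl)
  expect_equal(nrow(hit[hit$strand == "+", ]), 1)
  expect_equal(hit$mismatches[hit$strand == "+"], 0)
  primer_c <- "ACGTACGTACGTACGTACCT"  # C incompatible with R, and in the clamp
  expect_equal(nrow(find_binding_sites(primer_c, tmpl)), 0)
})

test_that("product prediction reproduces the full-length cds amplicon", {
  set.seed(422)
  cb <- cds_primer_table()
  cb <- cb[cb$gene == "CBDAS-cds", ]
  filler <- random_dna(1635 - nchar(cb$fw) - nchar(cb$rv))
  tmpl <- seq_record("cbdas_like", paste0(cb$fw, filler, rc_oracle(cb$rv)))
  pp <- primer_pair("CBDAS-cds", cb$fw, cb$rv, expected_len_bp = 1635)
  prod <- predict_products(pp, tmpl)
  expect_equal(nrow(prod), 1)
  expect_equal(prod$length_bp, 1635)
  expect_equal(prod$start, 1)
  expect_equal(prod$end, 1635)
})

test_that("product prediction is strand-consistent and enumerates multiple sites", {
  set.seed(423)
  fw <- random_dna(20); rv <- random_dna(20)
  mid <- random_dna(300)
  tmpl <- seq_record("t", paste0(random_dna(40), fw, mid, rc_oracle(rv),
                                 random_dna(40)))
  pp <- primer_pair("p", fw, rv)
  prod <- predict_products(pp, tmpl)
  expect_equal(prod$length_bp, 340)

  # reverse-complement template: same product length
  prod_rc <- predict_products(pp, seq_record("t_rc", rc_oracle(tmpl$seq)))
  expect_equal(prod_rc$length_bp, prod$length_bp)

  # template lacking the reverse site yields nothing
  no_rv <- seq_record("n", paste0(random_dna(40), fw, mid))
  expect_equal(nrow(predict_products(pp, no_rv)), 0)

  # two forward sites upstream of one reverse site give two products
  tmpl2 <- seq_record("t2", paste0(fw, random_dna(100), fw, mid, rc_oracle(rv)))
  prod2 <- predict_products(pp, tmpl2)
  expect_equal(nrow(prod2), 2)
  expect_equal(diff(sort(prod2$length_bp)), 120)
})

test_that("B-locus band patterns map to genotype and chemotype calls", {
  expect_equal(interpret_b_locus(1192)$b_locus, "BT/BT")
  expect_equal(interpret_b_locus(1192)$chemotype_class, "I")
  both <- interpret_b_locus(c(1080, 1192))
  expect_equal(both$b_locus, "BT/BD")
  expect_equal(both$chemotype_class, "II")
  d <- interpret_b_locus(1081)
  expect_equal(d$b_locus, "BD/BD")
  expect_equal(d$chemotype_class, "III-IV-V")
  none <- interpret_b_locus(integer(0))
  expect_equal(none$b_locus, "no-call")
  off <- interpret_b_locus(c(900, 1192))
  expect_equal(off$b_locus, "no-call")
  expect_match(off$reason, "900")
})

test_that("specificity validation passes clade-specific pairs and names offenders", {
  sim <- simulate_gene_family(family_config(clades = cansynth:::default_clades(3),
                                            seed = 47))
  # anchor the forward primer 3' end on the clade-diagnostic positions 13/18
  fw_on <- function(ref) substr(ref$seq, 1, 18)
  rv_on <- function(ref) rc_oracle(substr(ref$seq, nchar(ref$seq) - 19,
                                          nchar(ref$seq)))
  cb_ref <- sim$references$CBCAS
  th_ref <- sim$references$THCAS
  pair_cb <- primer_pair("CBCAS-like", fw_on(cb_ref), rv_on(cb_ref))
  pos <- sim$records[sim$truth$clade == "CBCAS"]
  neg <- sim$records[sim$truth$clade == "THCAS"]
  rep_ <- validate_primer_specificity(pair_cb, pos, neg)
  expect_true(rep_$pass)
  expect_true(all(rep_$per_template$n_products[rep_$per_template$panel == "positive"] >= 1))
  expect_true(all(rep_$per_template$n_products[rep_$per_template$panel == "negative"] == 0))

  # a pair built on the THCAS reference fails when THCAS clones are negatives
  pair_th <- primer_pair("THCAS-like", fw_on(th_ref), rv_on(th_ref))
  rep2 <- validate_primer_specificity(pair_th, pos, neg)
  expect_false(rep2$pass)
  expect_true(any(grepl("negative", rep2$failures)) ||
              any(grepl("positive", rep2$failures)))
})

test_that("Tm estimate follows the two published approximations", {
  expect_equal(primer_tm("ACGTACGTACGT"), 2 * 6 + 4 * 6)  # 12-mer Wallace rule
  p <- "ACGTACGTACGTACGTACGT"  # 20-mer, GC = 10
  expect_equal(primer_tm(p), 64.9 + 41 * (10 - 16.4) / 20)
})
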
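test_that("self-alignment gives full identity and coverage", {
  h <- align_local("MKVLHEACDE", "MKVLHEACDE")
  expect_equal(h$identity_pct, 100)
  expect_equal(h$similarity_pct, 100)
  expect_equal(h$coverage_longer_pct, 100)
  expect_error(align_local("", "MKV"), "empty")
})

test_that("an internal substitution gives 75% identity over 4 columns", {
  # internal change: a local aligner would trim a mismatched terminus,
  # so the substituted residue sits inside the alignment
  h <- align_local("ACDE", "ACFE")
  expect_equal(h$aln_len, 4L)
  expect_equal(h$identity_pct, 75)
})

test_that("local alignment scores match a brute-force Gotoh oracle", {
  set.seed(101)
  aas <- names(genefamr:::AA_MASS)
  for (i in 1:40) {
    a <- paste(sample(aas, sample(5:20, 1L), TRUE), collapse = "")
    b <- paste(sample(aas, sample(5:20, 1L), TRUE), collapse = "")
    expect_equal(align_local(a, b)$score, oracle_local_score(a, b),
                 tolerance = 1e-9)
  }
})

test_that("alignment score is symmetric", {
  set.seed(102)
  aas <- names(genefamr:::AA_MASS)
  for (i in 1:10) {
    a <- paste(sample(aas, 15, TRUE), collapse = "")
    b <- paste(sample(aas, 12, TRUE), collapse = "")
    expect_equal(align_local(a, b)$score, align_local(b, a)$score)
  }
})

test_that("family filters are strict and collapse redundant sequences", {
  refs <- c("NPF1;1|NPF1" = "MKVLHEACDEFGHIK")
  hits <- data.frame(
    query_id = c("gA", "gB", "gC"),
    subject_id = "NPF1;1",
    score = c(50, 50, 50),
    identity_pct = c(70, 70, 70),
    similarity_pct = c(80, 75, 75.1),
    aln_len = 15L,
    coverage_longer_pct = c(90, 90, 76)
  )
  cands <- c(gA = "MKVA", gB = "MKVB", gC = "MKVC")
  out <- identify_family(cands, refs, hits = hits)
  expect_identical(out$gene_id, c("gA", "gC"))  # exactly 75 is rejected
  expect_identical(out$subfamily, c("NPF1", "NPF1"))

  # identical proteins collapse to the lexicographically smallest id
  dup <- c(gZ = "MKVA", gA = "MKVA")
  out2 <- identify_family(dup, refs,
                          hits = hits[hits$query_id == "gA", ])
  expect_identical(out2$gene_id, "gA")
  expect_error(identify_family(cands, character(0)), "empty reference")
})

test_that("identification is monotone in its thresholds", {
  corpus <- default_corpus()
  refs <- corpus_labelled_refs()
  hits <- corpus_ref_hits()
  strict <- identify_family(corpus$sim$proteins, refs, hits = hits)
  loose <- identify_family(corpus$sim$proteins, refs, hits = hits,
                           min_coverage = 60, min_similarity = 60)
  expect_true(all(strict$gene_id %in% loose$gene_id))
})

test_that("family identification recovers the planted truth exactly", {
  corpus <- default_corpus()
  members <- corpus_family()
  truth <- corpus$truth$family_members
  expect_setequal(members$gene_id, truth$gene_id)
  m <- merge(members, truth, by = "gene_id")
  expect_identical(m$subfamily.x, m$subfamily.y)
  expect_identical(m$best_reference, m$reference)
})

test_that("systematic names follow coordinate order within groups", {
  models <- list(
    g2 = gene_model("g2", "A03", "+", 5000, 6000,
                    exons = rbind(c(5000, 6000)), cds = rbind(c(5000, 6000))),
    g1 = gene_model("g1", "A03", "+", 1000, 2000,
                    exons = rbind(c(1000, 2000)), cds = rbind(c(1000, 2000))),
    g3 = gene_model("g3", "C05", "-", 100, 900,
                    exons = rbind(c(100, 900)), cds = rbind(c(100, 900)))
  )
  members <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    subfamily = c("NPF4", "NPF4", "NPF2"),
    best_reference = c("NPF4;1", "NPF4;1", "NPF2;3"),
    stringsAsFactors = FALSE
  )
  named <- assign_names(members, models, species_prefix = "Bna")
  expect_identical(named$name[named$gene_id == "g1"], "BnaA03.NPF4;1a")
  expect_identical(named$name[named$gene_id == "g2"], "BnaA03.NPF4;1b")
  expect_identical(named$name[named$gene_id == "g3"], "BnaC05.NPF2;3")

  # invariant to input order
  named2 <- assign_names(members[c(3, 1, 2), ], models, species_prefix = "Bna")
  expect_identical(named$name[order(named$gene_id)],
                   named2$name[order(named2$gene_id)])
})

test_that("copy-number tables reproduce the printed family arithmetic", {
  counts <- list(
    arabidopsis = c(NPF1 = 3, NPF2 = 14, NPF3 = 1, NPF4 = 7, NPF5 = 16,
                    NPF6 = 4, NPF7 = 3, NPF8 = 5),
    b_rapa = c(NPF1 = 4, NPF2 = 22, NPF3 = 3, NPF4 = 8, NPF5 = 36,
               NPF6 = 7, NPF7 = 6, NPF8 = 9),
    b_oleracea = c(NPF1 = 6, NPF2 = 21, NPF3 = 3, NPF4 = 8, NPF5 = 32,
                   NPF6 = 7, NPF7 = 6, NPF8 = 10),
    b_napus = c(NPF1 = 10, NPF2 = 42, NPF3 = 6, NPF4 = 19, NPF5 = 73,
                NPF6 = 13, NPF7 = 10, NPF8 = 20)
  )
  tab <- count_by_subfamily(counts, reference = "arabidopsis")
  expect_equal(unname(tab$table["Total", ]), c(53L, 95L, 93L, 193L))
  expect_equal(unname(tab$ratio_to_reference), c(1.0, 1.8, 1.8, 3.6))
  expect_equal(unname(tab$mean_per_subfamily[["b_napus"]]), 24.125)
  expect_equal(unname(tab$min[["b_napus"]]), 6L)
  expect_equal(unname(tab$max[["b_napus"]]), 73L)

  empty <- count_by_subfamily(list(sp = character(0)))
  expect_equal(unname(empty$table["Total", ]), 0L)
})

test_that("intron statistics sum to one and count exon gaps", {
  models <- list(
    g1 = gene_model("g1", "A01", "+", 1, 400,
                    exons = rbind(c(1, 50), c(100, 150), c(200, 250),
                                  c(300, 400)),
                    cds = rbind(c(1, 50), c(100, 150), c(200, 250),
                                c(300, 400)))
  )
  expect_equal(intron_count(models$g1), 3L)
  members <- data.frame(gene_id = "g1", subfamily = "NPF1",
                        best_reference = "NPF1;1")
  st <- intron_statistics(members, models)
  expect_equal(st$distribution$fraction, 1)

  # {3,3,3,2} -> fraction(3) = 0.75
  counts <- c(3, 3, 3, 2)
  expect_equal(mean(counts == 3), 0.75)
})
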
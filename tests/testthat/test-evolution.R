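test_that("back-translation expands residues to codons and masks gaps", {
  aln <- c(a = "MKF", b = "MKF")
  cds_a <- "ATGAAATTTTAA"
  cds_b <- "ATGAAGTTCTGA"
  ca <- backtranslate_alignment(aln, cds_a, cds_b)
  expect_equal(nchar(ca$a), 9L)
  expect_equal(nchar(ca$b), 9L)
  expect_length(ca$mask, 0L)

  aln_gap <- c(a = "MKF", b = "M-F")
  cds_b2 <- "ATGTTCTGA"
  ca2 <- backtranslate_alignment(aln_gap, cds_a, cds_b2)
  expect_equal(nchar(ca2$a), 6L)
  expect_identical(ca2$mask, 2L)

  # round trip: translating the output recovers the gap-stripped proteins
  code <- Biostrings::GENETIC_CODE
  tr <- function(nt) paste(code[substring(nt, seq(1, nchar(nt), 3),
                                          seq(3, nchar(nt), 3))],
                           collapse = "")
  expect_identical(tr(ca$a), "MKF")
  expect_identical(tr(ca2$b), "MF")

  expect_error(backtranslate_alignment(aln, "ATGAAAGGGTAA", cds_b),
               "residue 3")
})

test_that("NG86 handles identical and synonymous-only pairs", {
  same <- ng86_kaks(list(ids = c("x", "y"), a = "ATGAAA", b = "ATGAAA"))
  expect_equal(same$ka, 0)
  expect_equal(same$ks, 0)
  expect_true(is.na(same$ratio))
  expect_identical(same$selection, "undefined")

  # one synonymous Phe change next to a leucine codon rich in silent sites
  syn <- ng86_kaks(list(ids = c("x", "y"), a = "CTATTT", b = "CTATTC"))
  expect_equal(syn$ka, 0)
  expect_gt(syn$ks, 0)
  expect_equal(syn$ratio, 0)
  expect_identical(syn$selection, "purifying")
})

test_that("NG86 matches the pathway-enumeration oracle on random pairs", {
  set.seed(201)
  for (i in 1:120) {
    k <- sample(1:2, 1L)
    a <- random_stopfree_cds(k)
    b <- random_stopfree_cds(k)
    mine <- ng86_kaks(list(ids = c("a", "b"), a = a, b = b))
    orac <- oracle_ng86(a, b)
    expect_equal(mine$S, orac$S, tolerance = 1e-9)
    expect_equal(mine$Sd, orac$Sd, tolerance = 1e-9)
    expect_equal(mine$Nd, orac$Nd, tolerance = 1e-9)
    expect_equal(mine$ks, orac$ks, tolerance = 1e-9)
    expect_equal(mine$ka, orac$ka, tolerance = 1e-9)
    # symmetry
    rev <- ng86_kaks(list(ids = c("b", "a"), a = b, b = a))
    expect_identical(mine$ka, rev$ka)
    expect_identical(mine$ks, rev$ks)
  }
})

test_that("selection classes map from the ratio", {
  expect_identical(classify_selection(0.5), "purifying")
  expect_identical(classify_selection(1), "neutral")
  expect_identical(classify_selection(1.7), "positive")
  expect_identical(classify_selection(NA_real_), "undefined")
})

test_that("NJ solves the three-taxon closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(bl[["a"]], 1)  # (3 + 4 - 5) / 2
  expect_equal(bl[["b"]], 2)
  expect_equal(bl[["c"]], 3)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ reconstructs additive matrices exactly", {
  set.seed(202)
  for (i in 1:30) {
    case <- random_additive_case(sample(5:8, 1L))
    tr <- nj_tree(case$d)
    expect_equal(as.numeric(ape::dist.topo(tr, case$tree)), 0)
    # branch lengths: cophenetic distances of the reconstruction match
    dd <- ape::cophenetic.phylo(tr)[rownames(case$d), colnames(case$d)]
    expect_equal(dd, case$d, tolerance = 1e-6)
  }
})

test_that("ultrametric clusters come out as sister clades", {
  labs <- c("a1", "a2", "a3", "b1", "b2", "b3")
  d <- matrix(10, 6, 6, dimnames = list(labs, labs))
  d[1:3, 1:3] <- 2
  d[4:6, 4:6] <- 2
  diag(d) <- 0
  tr <- nj_tree(d)
  part <- ape::prop.part(tr)
  sets <- lapply(part, function(p) sort(attr(part, "labels")[p]))
  has <- function(x) any(vapply(sets, identical, TRUE, x))
  expect_true(has(c("a1", "a2", "a3")) || has(c("b1", "b2", "b3")))
})

test_that("bootstrap supports a planted deep split and is deterministic", {
  set.seed(203)
  aas <- names(genefamr:::AA_MASS)
  core1 <- sample(aas, 60, TRUE)
  core2 <- sample(aas, 60, TRUE)  # deeply divergent second clan
  jitter <- function(core, rate = 0.05) {
    idx <- runif(length(core)) < rate
    core[idx] <- sample(aas, sum(idx), TRUE)
    paste(core, collapse = "")
  }
  aln <- c(x1 = jitter(core1), x2 = jitter(core1), x3 = jitter(core1),
           y1 = jitter(core2), y2 = jitter(core2), y3 = jitter(core2))
  tr <- bootstrap_support(aln, n_reps = 100L, seed = 9L)
  supp <- suppressWarnings(as.numeric(tr$node.label))
  supp <- supp[!is.na(supp)]
  expect_true(all(supp >= 0 & supp <= 100))
  expect_gte(max(supp), 95)  # the central split is near-certain

  tr2 <- bootstrap_support(aln, n_reps = 100L, seed = 9L)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("member-vs-reference Ka/Ks on the corpus shows purifying selection", {
  corpus <- default_corpus()
  members <- head(corpus_family(), 10L)
  kk <- kaks_table(members, corpus$sim$proteins, corpus$sim$cds,
                   corpus$sim$ref_proteins, corpus$sim$ref_cds)
  expect_true(all(is.finite(kk$ratio)))
  expect_true(all(kk$ratio < 1))
  expect_true(all(kk$selection == "purifying"))
})

test_that("the center-star aligner preserves sequences up to gaps", {
  seqs <- c(s1 = "MKVLHEACDEFGHIK", s2 = "MKVLHEACDEFGHIK",
            s3 = "MKVLHACDEFGHIK", s4 = "MKVLHEACDEFGWHIK")
  aln <- align_proteins(seqs)
  expect_length(unique(nchar(aln)), 1L)
  expect_identical(gsub("-", "", aln), seqs)
})
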
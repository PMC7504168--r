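mk_gene <- function(id, chrom, start, end, strand = "+") {
  gene_model(id, chrom, strand, start, end,
             exons = rbind(c(start, end)), cds = rbind(c(start, end)))
}

test_that("homolog-pair filtering is strict and symmetric", {
  hits <- data.frame(
    query_id = c("g1", "g2", "g3", "g4", "g5"),
    subject_id = c("g2", "g1", "g4", "g3", "g5"),
    score = 10, identity_pct = 70,
    similarity_pct = c(80, 80, 75, 75, 99),
    aln_len = 100L,
    coverage_longer_pct = c(80, 80, 90, 90, 100)
  )
  pairs <- filter_homolog_pairs(hits)
  # the 80/80 pair is kept once despite two hit directions; exactly-75 is
  # dropped; self-pairs are dropped
  expect_equal(nrow(pairs), 1L)
  expect_identical(pairs$gene_a, "g1")
  expect_identical(pairs$gene_b, "g2")
})

test_that("tandem detection applies the separation window on one chromosome", {
  models <- list(
    a = mk_gene("a", "A01", 1000, 2000),
    b = mk_gene("b", "A01", 8500, 9500),
    c = mk_gene("c", "A01", 260000, 261000),
    d = mk_gene("d", "C01", 3000, 4000)
  )
  pairs <- data.frame(gene_a = c("a", "a", "a"), gene_b = c("b", "c", "d"),
                      similarity_pct = 90, coverage_longer_pct = 90)
  ev <- detect_tandem(pairs, models)
  expect_equal(nrow(ev), 1L)
  expect_identical(ev$gene_b, "b")
  expect_equal(ev$separation_bp, 6500L)

  far <- data.frame(gene_a = "b", gene_b = "c",
                    similarity_pct = 90, coverage_longer_pct = 90)
  expect_equal(nrow(detect_tandem(far, models)), 0L)  # 250500 bp apart
})

test_that("consecutive homologous pairs chain into one block", {
  n <- 6L
  a_models <- lapply(seq_len(n), function(i) {
    mk_gene(paste0("a", i), "A01", i * 10000, i * 10000 + 1000)
  })
  names(a_models) <- paste0("a", seq_len(n))
  b_same <- lapply(seq_len(n), function(i) {
    mk_gene(paste0("b", i), "B01", i * 10000, i * 10000 + 1000)
  })
  names(b_same) <- paste0("b", seq_len(n))
  pairs <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                      similarity_pct = 90, coverage_longer_pct = 90)
  blocks <- chain_collinear_blocks(pairs, a_models, b_same)
  expect_length(blocks, 1L)
  expect_equal(blocks[[1L]]$size, 6L)
  expect_identical(blocks[[1L]]$orientation, "same")

  # reversing the b-side order gives one inverted block
  b_rev <- lapply(seq_len(n), function(i) {
    mk_gene(paste0("b", i), "B01", (n - i + 1L) * 10000,
            (n - i + 1L) * 10000 + 1000)
  })
  names(b_rev) <- paste0("b", seq_len(n))
  blocks2 <- chain_collinear_blocks(pairs, a_models, b_rev)
  expect_length(blocks2, 1L)
  expect_identical(blocks2[[1L]]$orientation, "inverted")
  expect_equal(blocks2[[1L]]$size, 6L)
})

test_that("chaining matches an exhaustive longest-chain oracle", {
  set.seed(301)
  for (rep in 1:15) {
    n <- sample(6:12, 1L)
    ra <- sample(1:15, n)
    rb <- sample(1:15, n)
    a_models <- lapply(seq_len(n), function(i) {
      mk_gene(paste0("a", i), "A01", ra[i] * 1000, ra[i] * 1000 + 100)
    })
    names(a_models) <- paste0("a", seq_len(n))
    b_models <- lapply(seq_len(n), function(i) {
      mk_gene(paste0("b", i), "B01", rb[i] * 1000, rb[i] * 1000 + 100)
    })
    names(b_models) <- paste0("b", seq_len(n))
    pairs <- data.frame(gene_a = paste0("a", 1:n), gene_b = paste0("b", 1:n),
                        similarity_pct = 90, coverage_longer_pct = 90)
    max_gap <- sample(2:5, 1L)
    blocks <- chain_collinear_blocks(pairs, a_models, b_models,
                                     min_block = 2L, max_gap = max_gap)
    best_mine <- if (length(blocks) == 0L) 1L else max(vapply(blocks, `[[`,
                                                              0L, "size"))
    # ranks are the order statistics of the positions
    best_oracle <- oracle_longest_chain(rank(ra), rank(rb), max_gap)
    expect_equal(best_mine, max(best_oracle, 1L))
  }
})

test_that("event classification resolves overlaps to tandem and summarizes", {
  tand <- data.frame(gene_a = "a1", gene_b = "b1", type = "tandem",
                     separation_bp = 6500L)
  blocks <- list(list(pairs = data.frame(gene_a = paste0("a", 1:5),
                                         gene_b = paste0("b", 1:5)),
                      chrom_a = "A01", chrom_b = "B01",
                      orientation = "same", size = 5L))
  res <- classify_duplications(tand, blocks, total_genes = 10L)
  expect_false(any(duplicated(res$events[c("gene_a", "gene_b")])))
  expect_equal(res$summary$n_tandem_pairs, 1L)
  expect_equal(res$summary$n_segmental_pairs, 4L)  # a1-b1 resolved to tandem
  types <- split(res$events$type, paste(res$events$gene_a, res$events$gene_b))
  expect_true(all(lengths(types) == 1L))

  zero <- classify_duplications(tand[0, ], list(), total_genes = 0L)
  expect_equal(zero$summary$n_segmental_pairs, 0L)
  expect_equal(zero$summary$n_tandem_pairs, 0L)
  expect_equal(zero$summary$fraction_segmental_genes_pct, 0)

  # the printed worked example: 137 genes of 193 is 71%
  expect_equal(percent_of(137, 193), 71)
})

test_that("block finding is symmetric in the two genomes", {
  corpus <- default_corpus()
  pairs <- corpus_member_pairs()
  blocks_ab <- chain_collinear_blocks(pairs, corpus$sim$genes,
                                      corpus$sim$genes)
  swapped <- data.frame(gene_a = pairs$gene_b, gene_b = pairs$gene_a,
                        similarity_pct = pairs$similarity_pct,
                        coverage_longer_pct = pairs$coverage_longer_pct)
  blocks_ba <- chain_collinear_blocks(swapped, corpus$sim$genes,
                                      corpus$sim$genes)
  expect_equal(sort(vapply(blocks_ab, `[[`, 0L, "size")),
               sort(vapply(blocks_ba, `[[`, 0L, "size")))
})

test_that("planted duplications are recovered exactly on the corpus", {
  corpus <- default_corpus()
  pairs <- corpus_member_pairs()
  tand <- detect_tandem(pairs, corpus$sim$genes)
  tp <- corpus$truth$planted_tandem_pairs
  expect_equal(nrow(tand), 1L)
  expect_setequal(c(tand$gene_a, tand$gene_b), c(tp$gene_a, tp$gene_b))
  expect_equal(tand$separation_bp, tp$separation_bp)

  blocks <- chain_collinear_blocks(pairs, corpus$sim$genes, corpus$sim$genes)
  truth_blocks <- corpus$truth$planted_collinear_blocks
  expect_length(blocks, length(truth_blocks))
  key <- function(b) paste(b$chrom_a, b$chrom_b)
  blocks <- blocks[order(vapply(blocks, key, ""))]
  truth_blocks <- truth_blocks[order(vapply(truth_blocks, key, ""))]
  for (i in seq_along(blocks)) {
    expect_identical(blocks[[i]]$orientation, truth_blocks[[i]]$orientation)
    expect_identical(blocks[[i]]$pairs$gene_a, truth_blocks[[i]]$gene_a)
    expect_identical(blocks[[i]]$pairs$gene_b, truth_blocks[[i]]$gene_b)
  }
})

test_that("cross-species synteny partitions pairs by subgenome", {
  corpus <- default_corpus()
  fam <- corpus$truth$family_members$gene_id
  # synthetic ancestor: the A-subgenome genes under new ids/chromosomes
  a_genes <- Filter(function(g) startsWith(g$chromosome, "A"),
                    corpus$sim$genes)
  anc_models <- lapply(a_genes, function(g) {
    gene_model(paste0("anc_", g$gene_id), sub("^A", "X", g$chromosome),
               g$strand, g$start, g$end, g$exons, g$cds)
  })
  names(anc_models) <- paste0("anc_", names(a_genes))
  pairs <- data.frame(gene_a = names(a_genes),
                      gene_b = names(anc_models),
                      similarity_pct = 100, coverage_longer_pct = 100)
  anc_members <- data.frame(gene_id = paste0(
    "anc_", intersect(fam, names(a_genes))))
  tgt_members <- data.frame(gene_id = fam)
  syn <- cross_species_synteny(tgt_members, anc_members, pairs,
                               corpus$sim$genes, anc_models,
                               min_block = 5L, max_gap = 10L)
  found <- unlist(lapply(syn$pairs_by_subgenome, function(df) df$gene_a))
  a_fam <- intersect(fam, names(a_genes))
  expect_setequal(found, a_fam)  # every A-side member has a syntenic partner
  expect_identical(names(syn$pairs_by_subgenome), "A")

  # invariance to order-preserving chromosome relabeling
  anc_models2 <- lapply(anc_models, function(g) {
    gene_model(g$gene_id, sub("^X", "Z", g$chromosome), g$strand,
               g$start, g$end, g$exons, g$cds)
  })
  syn2 <- cross_species_synteny(tgt_members, anc_members, pairs,
                                corpus$sim$genes, anc_models2,
                                min_block = 5L, max_gap = 10L)
  expect_equal(vapply(syn$pairs_by_subgenome, nrow, 0L),
               vapply(syn2$pairs_by_subgenome, nrow, 0L))

  empty <- cross_species_synteny(tgt_members, anc_members, pairs[0, ],
                                 corpus$sim$genes, anc_models)
  expect_length(empty$pairs_by_subgenome, 0L)
})
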
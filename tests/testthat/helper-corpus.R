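# Shared fixtures: the default synthetic corpus (generated once per session)
# and the derived family identification / homolog-pair tables.

corpus_cache <- new.env(parent = emptyenv())

default_corpus <- function() {
  if (is.null(corpus_cache$corpus)) {
    dir <- file.path(tempdir(), "genefamr-default-corpus")
    corpus_cache$corpus <- suppressWarnings(
      simulate_corpus(dir, default_config())
    )
  }
  corpus_cache$corpus
}

corpus_labelled_refs <- function() {
  corpus <- default_corpus()
  setNames(corpus$sim$ref_proteins,
           paste0(names(corpus$sim$ref_proteins), "|",
                  corpus$sim$ref_subfamily))
}

corpus_ref_hits <- function() {
  if (is.null(corpus_cache$ref_hits)) {
    corpus <- default_corpus()
    corpus_cache$ref_hits <- homology_hits(corpus$sim$proteins,
                                           corpus$sim$ref_proteins)
  }
  corpus_cache$ref_hits
}

corpus_family <- function() {
  if (is.null(corpus_cache$family)) {
    corpus <- default_corpus()
    corpus_cache$family <- identify_family(corpus$sim$proteins,
                                           corpus_labelled_refs(),
                                           hits = corpus_ref_hits())
  }
  corpus_cache$family
}

corpus_member_pairs <- function() {
  if (is.null(corpus_cache$pairs)) {
    corpus <- default_corpus()
    fam <- corpus$truth$family_members$gene_id
    hits <- pairwise_hits(corpus$sim$proteins[fam])
    corpus_cache$pairs <- filter_homolog_pairs(hits)
  }
  corpus_cache$pairs
}

read_cre_catalog_quiet <- function(...) {
  suppressWarnings(read_cre_catalog(...))
}

# a small fast generator configuration for determinism/error-path tests
small_config <- function(seed = 11L) {
  run_config(
    seed = seed,
    genome = list(
      n_family = 16L, n_decoys = 8L, block_size = 3L,
      ref_length_range = c(120L, 150L), decoy_length_range = c(100L, 160L),
      spacer_range = c(200L, 500L)
    ),
    promoter = list(length = 500L)
  )
}
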
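# Local protein alignment used for homology search at desk scale.
# Affine-gap Smith-Waterman via Biostrings; a gap of length L costs
# gap_open + gap_extend * L.

blosum62_x0 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      # unknown residue X is scored 0 against everything
      m["X", ] <- 0L
      m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps under BLOSUM62 (X scored 0). Reports the
#' alignment statistics used by the family homology filter: percent identity,
#' percent similarity (aligned columns with a positive substitution score) and
#' coverage of the longer sequence by the aligned region.
#'
#' @param a,b Protein sequences (single strings, 20-letter alphabet plus X).
#' @param gap_open,gap_extend Affine gap penalties (positive).
#' @param query_id,subject_id Ids recorded in the hit.
#' @return A one-row data.frame (class `homolog_hit`): query_id, subject_id,
#'   score, identity_pct, similarity_pct, aln_len, coverage_longer_pct.
#' @export
align_local <- function(a, b, gap_open = 10, gap_extend = 0.5,
                        query_id = "query", subject_id = "subject") {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  hits <- align_local_many(setNames(a, query_id), b,
                           subject_id = subject_id,
                           gap_open = gap_open, gap_extend = gap_extend)
  hits[1L, , drop = FALSE]
}

# Vectorized form: many queries against one subject.
align_local_many <- function(queries, subject, subject_id = "subject",
                             gap_open = 10, gap_extend = 0.5) {
  mat <- blosum62_x0()
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(queries),
    subject = Biostrings::AAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  pat <- as.character(Biostrings::alignedPattern(pa))
  sub <- as.character(Biostrings::alignedSubject(pa))
  longer <- pmax(nchar(queries), nchar(subject))
  stats <- mapply(function(p, s) {
    cp <- strsplit(p, "", fixed = TRUE)[[1L]]
    cs <- strsplit(s, "", fixed = TRUE)[[1L]]
    ncol <- length(cp)
    nongap <- cp != "-" & cs != "-"
    ident <- sum(cp == cs & nongap)
    pos <- sum(mat[cbind(cp[nongap], cs[nongap])] > 0)
    c(ncol = ncol, ident = ident, pos = pos)
  }, pat, sub)
  data.frame(
    query_id = names(queries),
    subject_id = subject_id,
    score = Biostrings::score(pa),
    identity_pct = 100 * stats["ident", ] / stats["ncol", ],
    similarity_pct = 100 * stats["pos", ] / stats["ncol", ],
    aln_len = as.integer(stats["ncol", ]),
    coverage_longer_pct = 100 * stats["ncol", ] / longer,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' All-vs-reference homology hits
#'
#' Aligns every candidate protein against every reference protein and returns
#' the full hit table.
#'
#' @param candidates Named character vector of candidate proteins.
#' @param references Named character vector of reference proteins.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return data.frame of `homolog_hit` rows.
#' @export
homology_hits <- function(candidates, references,
                          gap_open = 10, gap_extend = 0.5) {
  if (length(references) == 0L) stop("empty reference set")
  if (length(candidates) == 0L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      score = numeric(0), identity_pct = numeric(0),
                      similarity_pct = numeric(0), aln_len = integer(0),
                      coverage_longer_pct = numeric(0)))
  }
  do.call(rbind, lapply(names(references), function(rid) {
    align_local_many(candidates, references[[rid]], subject_id = rid,
                     gap_open = gap_open, gap_extend = gap_extend)
  }))
}

#' All-vs-all homology hits among one gene set
#'
#' Unordered unique pairs only (each pair aligned once).
#'
#' @param proteins Named character vector.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return data.frame of `homolog_hit` rows with query_id < subject_id.
#' @export
pairwise_hits <- function(proteins, gap_open = 10, gap_extend = 0.5) {
  ids <- sort(names(proteins))
  out <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    sid <- ids[[i]]
    rest <- ids[(i + 1L):length(ids)]
    out[[sid]] <- align_local_many(proteins[rest], proteins[[sid]],
                                   subject_id = sid,
                                   gap_open = gap_open,
                                   gap_extend = gap_extend)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # orient so gene_a < gene_b lexicographically
  a <- pmin(res$query_id, res$subject_id)
  b <- pmax(res$query_id, res$subject_id)
  res$query_id <- a
  res$subject_id <- b
  res
}
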
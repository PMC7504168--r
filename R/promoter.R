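# Promoter extraction and IUPAC cis-regulatory element scanning.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read a cis-regulatory element catalog
#'
#' TSV with columns name, consensus (IUPAC), category. Invalid IUPAC letters
#' are an error; catalog entries that are reverse complements of each other
#' (or self-reverse-complementary) trigger a warning because scanning both
#' strands will double-count such motifs.
#'
#' @param path TSV path (default: the catalog shipped with the package,
#'   literature consensus sequences).
#' @return data.frame: name, consensus, category.
#' @export
read_cre_catalog <- function(path = system.file("extdata", "cre_catalog.tsv",
                                                package = "genefamr")) {
  cat <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "consensus", "category")
  if (!all(need %in% names(cat))) {
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  }
  for (i in seq_len(nrow(cat))) {
    letters_i <- seq_chars(cat$consensus[[i]])
    bad <- setdiff(letters_i, IUPAC_LETTERS)
    if (length(bad) > 0L) {
      stop("invalid IUPAC letter(s) in motif ", cat$name[[i]], ": ",
           paste(bad, collapse = ", "))
    }
  }
  rc <- vapply(cat$consensus, revcomp, "")
  twin <- which(rc %in% cat$consensus)
  if (length(twin) > 0L) {
    warning("motif(s) whose reverse complement is also in the catalog ",
            "(palindromes double-count on two-strand scans): ",
            paste(unique(cat$name[twin]), collapse = ", "))
  }
  cat
}

#' Extract the promoter of a gene
#'
#' The `length` bases immediately 5' of the CDS start on the coding strand;
#' minus-strand promoters are reverse-complemented. Truncated with a warning
#' at the chromosome edge.
#'
#' @param gene A `gene_model` (must have CDS).
#' @param genome Named character vector of chromosome sequences.
#' @param length Promoter length in bp (default 2,000).
#' @return Promoter sequence (coding-strand orientation).
#' @export
extract_promoter <- function(gene, genome, length = 2000L) {
  if (nrow(gene$cds) == 0L) stop("gene ", gene$gene_id, " has no CDS")
  chrom <- genome[[gene$chromosome]]
  if (is.null(chrom)) stop("chromosome ", gene$chromosome, " not in genome")
  if (gene$strand == "+") {
    cds_start <- min(gene$cds[, 1L])
    from <- cds_start - length
    if (from < 1L) {
      warning("promoter of ", gene$gene_id, " truncated at chromosome start")
      from <- 1L
    }
    if (cds_start == 1L) return("")
    substr(chrom, from, cds_start - 1L)
  } else {
    cds_end <- max(gene$cds[, 2L])
    to <- cds_end + length
    if (to > nchar(chrom)) {
      warning("promoter of ", gene$gene_id, " truncated at chromosome end")
      to <- nchar(chrom)
    }
    if (cds_end == nchar(chrom)) return("")
    revcomp(substr(chrom, cds_end + 1L, to))
  }
}

#' Scan a promoter for cis-regulatory elements
#'
#' Reports every position where a catalog consensus matches, honoring IUPAC
#' degeneracy; overlapping matches are all reported. Minus-strand matches
#' (the reverse complement of the consensus on the forward strand) are
#' reported at forward-strand coordinates.
#'
#' @param promoter Promoter sequence.
#' @param catalog Catalog data.frame from [read_cre_catalog()].
#' @param both_strands Scan the minus strand too (default TRUE).
#' @param promoter_id Id recorded in the hits.
#' @return data.frame: promoter_id, motif, position (1-based), strand,
#'   matched.
#' @export
scan_cres <- function(promoter, catalog, both_strands = TRUE,
                      promoter_id = "promoter") {
  subject <- Biostrings::DNAString(promoter)
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    motif <- catalog$name[[i]]
    cons <- catalog$consensus[[i]]
    if (nchar(cons) > nchar(promoter)) next
    fwd <- Biostrings::matchPattern(cons, subject, fixed = FALSE)
    if (length(fwd) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        promoter_id = promoter_id, motif = motif,
        position = Biostrings::start(fwd), strand = "+",
        matched = as.character(fwd), stringsAsFactors = FALSE)
    }
    if (both_strands) {
      rc <- revcomp(cons)
      rev <- Biostrings::matchPattern(rc, subject, fixed = FALSE)
      if (length(rev) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          promoter_id = promoter_id, motif = motif,
          position = Biostrings::start(rev), strand = "-",
          matched = as.character(rev), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(promoter_id = character(0), motif = character(0),
                      position = integer(0), strand = character(0),
                      matched = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$motif, out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan many promoters
#'
#' @param promoters Named character vector of promoter sequences.
#' @param catalog Catalog data.frame.
#' @param both_strands Scan both strands.
#' @return Combined hits data.frame.
#' @export
scan_all_cres <- function(promoters, catalog, both_strands = TRUE) {
  out <- lapply(names(promoters), function(id) {
    scan_cres(promoters[[id]], catalog, both_strands = both_strands,
              promoter_id = id)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize CRE hits per gene and per category
#'
#' TATA-box and CAAT-box (or a configured exclusion list) are flagged as
#' excluded from display but retained in the counts.
#'
#' @param hits Hits data.frame from [scan_all_cres()].
#' @param catalog Catalog data.frame.
#' @param exclude Motifs excluded from display (default TATA-box, CAAT-box).
#' @return List with `counts` (promoter x motif matrix), `category_counts`
#'   (promoter x category matrix) and `excluded` (logical per motif,
#'   TRUE for motifs excluded from display but retained in the data).
#' @export
cre_summary <- function(hits, catalog,
                        exclude = c("TATA-box", "CAAT-box")) {
  motifs <- catalog$name
  proms <- sort(unique(hits$promoter_id))
  counts <- matrix(0L, nrow = length(proms), ncol = length(motifs),
                   dimnames = list(proms, motifs))
  if (nrow(hits) > 0L) {
    tab <- table(hits$promoter_id, hits$motif)
    counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  cats <- unique(catalog$category)
  category_counts <- vapply(cats, function(cc) {
    cols <- catalog$name[catalog$category == cc]
    if (length(proms) == 0L) return(integer(0))
    as.integer(rowSums(counts[, cols, drop = FALSE]))
  }, integer(length(proms)))
  if (length(proms) > 0L) {
    category_counts <- matrix(category_counts, nrow = length(proms),
                              dimnames = list(proms, cats))
  }
  list(counts = counts,
       category_counts = category_counts,
       excluded = setNames(motifs %in% exclude, motifs))
}
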
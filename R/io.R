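# Readers/writers for the on-disk formats used by the pipeline.
# Coordinates are 1-based inclusive throughout (GFF3 convention).

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive gene span.
#' @param exons Two-column matrix of exon (start, end), sorted by start,
#'   non-overlapping.
#' @param cds Two-column matrix of CDS (start, end) within the exon span.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, start, end, exons, cds) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (start > end) stop("gene ", gene_id, ": start > end")
  exons <- as_coord_matrix(exons)
  cds <- as_coord_matrix(cds)
  if (nrow(exons) == 0L) stop("gene ", gene_id, ": no exons")
  if (is.unsorted(exons[, 1L], strictly = TRUE) && nrow(exons) > 1L) {
    stop("gene ", gene_id, ": exons not sorted by start")
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("gene ", gene_id, ": exons overlap")
  }
  if (any(exons[, 1L] < start) || any(exons[, 2L] > end)) {
    stop("gene ", gene_id, ": exons outside gene span")
  }
  if (nrow(cds) > 0L &&
      (min(cds[, 1L]) < min(exons[, 1L]) || max(cds[, 2L]) > max(exons[, 2L]))) {
    stop("gene ", gene_id, ": CDS outside exon span")
  }
  structure(
    list(gene_id = gene_id, chromosome = chromosome, strand = strand,
         start = as.integer(start), end = as.integer(end),
         exons = exons, cds = cds),
    class = "gene_model"
  )
}

as_coord_matrix <- function(x) {
  m <- matrix(as.integer(x), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  if (nrow(m) > 0L && any(m[, 1L] > m[, 2L])) stop("interval start > end")
  m
}

#' Number of introns of a gene model
#' @param gene A `gene_model`.
#' @return Integer: number of exons minus one.
#' @export
intron_count <- function(gene) nrow(gene$exons) - 1L

#' Summarize a list of gene models as a data frame
#' @param genes Named list of `gene_model` objects.
#' @return data.frame with one row per gene.
#' @export
gene_table <- function(genes) {
  data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    chromosome = vapply(genes, `[[`, "", "chromosome"),
    strand = vapply(genes, `[[`, "", "strand"),
    start = vapply(genes, `[[`, 0L, "start"),
    end = vapply(genes, `[[`, 0L, "end"),
    intron_count = vapply(genes, intron_count, 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Read a FASTA file
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  setNames(as.character(set), ids)
}

#' Write a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names")
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Expects gene/mRNA/exon/CDS features. When a gene has several mRNAs the
#' transcript with the longest total CDS is kept.
#'
#' @param path GFF3 file path.
#' @return Named list of `gene_model` objects, ordered by (chromosome, start).
#' @export
read_gff3 <- function(path) {
  validate_gff3_lines(path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else p[[1L]]
  }, "")

  gene_idx <- which(type == "gene")
  if (length(gene_idx) == 0L) return(list())
  mrna_idx <- which(type == "mRNA")
  models <- list()
  for (gi in gene_idx) {
    gid <- ids[gi]
    g_start <- GenomicRanges::start(gr)[gi]
    g_end <- GenomicRanges::end(gr)[gi]
    children <- mrna_idx[parents[mrna_idx] == gid]
    if (length(children) == 0L) {
      stop("gene ", gid, " has no mRNA feature")
    }
    cds_len <- vapply(children, function(mi) {
      sel <- type == "CDS" & parents == ids[mi]
      sum(GenomicRanges::width(gr)[sel])
    }, 0)
    mi <- children[which.max(cds_len)]
    exon_sel <- which(type == "exon" & parents == ids[mi])
    cds_sel <- which(type == "CDS" & parents == ids[mi])
    exons <- cbind(GenomicRanges::start(gr)[exon_sel],
                   GenomicRanges::end(gr)[exon_sel])
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
    cds <- cbind(GenomicRanges::start(gr)[cds_sel],
                 GenomicRanges::end(gr)[cds_sel])
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
    if (nrow(cds) > 0L && (min(cds[, 1L]) < g_start || max(cds[, 2L]) > g_end)) {
      stop("gene ", gid, ": CDS outside gene span")
    }
    models[[gid]] <- gene_model(
      gene_id = gid,
      chromosome = as.character(GenomicRanges::seqnames(gr))[gi],
      strand = as.character(GenomicRanges::strand(gr))[gi],
      start = g_start, end = g_end, exons = exons, cds = cds
    )
  }
  tab <- gene_table(models)
  models[order(tab$chromosome, tab$start)]
}

validate_gff3_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L) {
      stop("malformed GFF3 line ", i, ": expected 9 tab-separated fields")
    }
    s <- suppressWarnings(as.integer(fields[4L]))
    e <- suppressWarnings(as.integer(fields[5L]))
    if (is.na(s) || is.na(e) || s > e) {
      stop("malformed GFF3 line ", i, ": bad coordinates")
    }
  }
  invisible(TRUE)
}

#' Write gene models to a GFF3 file
#' @param genes Named list of `gene_model` objects.
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  tab <- gene_table(genes)
  genes <- genes[order(tab$chromosome, tab$start)]
  for (g in genes) {
    mid <- paste0(g$gene_id, ".t1")
    rows <- c(
      gff3_line(g$chromosome, "gene", g$start, g$end, g$strand,
                paste0("ID=", g$gene_id)),
      gff3_line(g$chromosome, "mRNA", g$start, g$end, g$strand,
                paste0("ID=", mid, ";Parent=", g$gene_id))
    )
    for (i in seq_len(nrow(g$exons))) {
      rows <- c(rows, gff3_line(g$chromosome, "exon",
                                g$exons[i, 1L], g$exons[i, 2L], g$strand,
                                paste0("ID=", mid, ".exon", i, ";Parent=", mid)))
    }
    phases <- cds_phases(g)
    for (i in seq_len(nrow(g$cds))) {
      rows <- c(rows, gff3_line(g$chromosome, "CDS",
                                g$cds[i, 1L], g$cds[i, 2L], g$strand,
                                paste0("ID=", mid, ".cds", i, ";Parent=", mid),
                                phase = phases[i]))
    }
    writeLines(rows, con)
  }
  invisible(path)
}

gff3_line <- function(chrom, type, start, end, strand, attrs, phase = ".") {
  paste(chrom, "genefamr", type, start, end, ".", strand, phase, attrs,
        sep = "\t")
}

cds_phases <- function(g) {
  n <- nrow(g$cds)
  if (n == 0L) return(integer(0))
  widths <- g$cds[, 2L] - g$cds[, 1L] + 1L
  ord <- if (g$strand == "+") seq_len(n) else rev(seq_len(n))
  phases <- integer(n)
  cum <- 0L
  for (i in ord) {
    phases[i] <- (3L - (cum %% 3L)) %% 3L
    cum <- cum + widths[i]
  }
  phases
}

#' Read an expression matrix with annotated samples
#'
#' The TSV has a header of sample ids (`<tissue>_<treatment>_<replicate>`),
#' a first column of gene ids, and non-negative FPKM values.
#'
#' @param path TSV path.
#' @return List with `matrix` (genes x samples) and `samples` (data.frame with
#'   sample_id, tissue, treatment, replicate).
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  if (!is.numeric(mat)) stop("expression values must be numeric")
  if (any(mat < 0)) stop("negative FPKM values in ", path)
  list(matrix = mat, samples = parse_sample_ids(colnames(mat)))
}

#' Parse sample ids of the form tissue_treatment_replicate
#' @param ids Character vector of sample ids.
#' @return data.frame with sample_id, tissue, treatment, replicate.
#' @export
parse_sample_ids <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop("sample id(s) not of the form tissue_treatment_replicate: ",
         paste(ids[bad], collapse = ", "))
  }
  ann <- data.frame(
    sample_id = ids,
    tissue = vapply(parts, function(p) {
      paste(p[seq_len(length(p) - 2L)], collapse = "_")
    }, ""),
    treatment = vapply(parts, function(p) p[[length(p) - 1L]], ""),
    replicate = vapply(parts, function(p) as.integer(p[[length(p)]]), 0L),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ann[c("tissue", "treatment", "replicate")])) {
    stop("duplicate (tissue, treatment, replicate) combinations")
  }
  ann
}

#' Write an expression matrix as TSV
#' @param mat Genes x samples numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Long-format TSV with columns gene_id, tissue, treatment, replicate, ct.
#' @param path TSV path.
#' @return data.frame.
#' @export
read_ct_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "tissue", "treatment", "replicate", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Write a phylogenetic tree in Newick format
#' @param tree An `ape::phylo` object (bootstrap supports, if any, stored as
#'   internal node labels).
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path File path.
#' @return `ape::phylo` object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a coexpression network edge list as TSV
#' @param network A `coexpression_network` (see [build_network()]).
#' @param path Output path.
#' @export
write_edge_list <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write / read the synthetic-truth record as JSON
#' @param truth Truth list from [simulate_genome()] and friends.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
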
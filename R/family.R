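# Family identification, naming and tabulation.

#' Split reference FASTA ids of the form "<ref>|<subfamily>"
#'
#' Reference proteins carry their subfamily as a "|subfamily" suffix in the
#' FASTA header, e.g. "NPF4;1|NPF4".
#'
#' @param references Named character vector of reference proteins.
#' @return List with `proteins` (renamed to the bare reference id) and
#'   `subfamily` (named character vector, reference id -> subfamily label).
#' @export
split_reference_ids <- function(references) {
  ids <- names(references)
  has_label <- grepl("|", ids, fixed = TRUE)
  ref_id <- sub("\\|.*$", "", ids)
  subfam <- ifelse(has_label, sub("^.*\\|", "", ids),
                   sub(";.*$", "", ref_id))
  names(references) <- ref_id
  list(proteins = references, subfamily = setNames(subfam, ref_id))
}

#' Identify family members by homology to labelled references
#'
#' A candidate is accepted iff its best-scoring reference hit has similarity
#' and coverage-of-longer both strictly above the thresholds. Candidates with
#' identical protein sequence are collapsed to the lexicographically smallest
#' id (redundancy removal). The subfamily of a member is that of its best
#' reference.
#'
#' @param candidates Named character vector of candidate proteins.
#' @param references Named character vector of reference proteins, headers as
#'   in [split_reference_ids()].
#' @param min_coverage,min_similarity Strict thresholds in percent.
#' @param hits Optional precomputed hit table (as from [homology_hits()]);
#'   when supplied the alignment step is skipped.
#' @param gap_open,gap_extend Affine gap penalties for the alignment step.
#' @return data.frame (class `family_members`): gene_id, subfamily,
#'   best_reference, similarity_pct, coverage_longer_pct, score.
#' @export
identify_family <- function(candidates, references,
                            min_coverage = 75, min_similarity = 75,
                            hits = NULL, gap_open = 10, gap_extend = 0.5) {
  if (length(references) == 0L) stop("empty reference set")
  refs <- split_reference_ids(references)

  # redundancy removal: identical sequences collapse to smallest id
  ord <- order(names(candidates))
  candidates <- candidates[ord]
  keep <- !duplicated(unname(candidates))
  candidates <- candidates[keep]

  if (is.null(hits)) {
    hits <- homology_hits(candidates, refs$proteins,
                          gap_open = gap_open, gap_extend = gap_extend)
  }
  hits <- hits[hits$query_id %in% names(candidates), , drop = FALSE]
  members <- lapply(split(hits, hits$query_id), function(h) {
    best <- h[order(-h$score, h$subject_id), ][1L, ]
    if (best$similarity_pct > min_similarity &&
        best$coverage_longer_pct > min_coverage) best else NULL
  })
  members <- do.call(rbind, members[!vapply(members, is.null, TRUE)])
  if (is.null(members)) {
    members <- data.frame(query_id = character(0), subject_id = character(0),
                          score = numeric(0), similarity_pct = numeric(0),
                          coverage_longer_pct = numeric(0))
  }
  out <- data.frame(
    gene_id = members$query_id,
    subfamily = unname(refs$subfamily[members$subject_id]),
    best_reference = members$subject_id,
    similarity_pct = members$similarity_pct,
    coverage_longer_pct = members$coverage_longer_pct,
    score = members$score,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("family_members", "data.frame")
  out
}

#' Assign systematic names to family members
#'
#' Names follow `<Species><Chr>.<Reference><suffix>`, e.g. "SynA01.NPF4;1a".
#' Within each reference group, suffix letters a, b, c, ... are assigned in
#' (chromosome, start) order; singleton groups get no suffix. Members without
#' a gene model get the placeholder chromosome token "nn" and sort last.
#'
#' @param members A `family_members` data.frame.
#' @param gene_models Named list of `gene_model` objects.
#' @param species_prefix Species prefix for the name.
#' @return `members` with added columns chromosome, start, end, name.
#' @export
assign_names <- function(members, gene_models, species_prefix = "Syn") {
  tab <- gene_table(gene_models)
  idx <- match(members$gene_id, tab$gene_id)
  members$chromosome <- ifelse(is.na(idx), "nn", tab$chromosome[idx])
  members$start <- ifelse(is.na(idx), .Machine$integer.max, tab$start[idx])
  members$end <- ifelse(is.na(idx), NA_integer_, tab$end[idx])
  members <- members[order(members$best_reference, members$chromosome,
                           members$start, members$gene_id), , drop = FALSE]
  name <- character(nrow(members))
  for (grp in split(seq_len(nrow(members)), members$best_reference)) {
    sfx <- if (length(grp) > 1L) letters[seq_along(grp)] else ""
    name[grp] <- paste0(species_prefix, members$chromosome[grp], ".",
                        members$best_reference[grp], sfx)
  }
  members$name <- name
  members <- members[order(members$gene_id), , drop = FALSE]
  rownames(members) <- NULL
  class(members) <- c("family_members", "data.frame")
  members
}

#' Copy-number table by subfamily and species
#'
#' @param members_per_species Named list, one element per species: either a
#'   character vector of per-member subfamily labels, or a named integer
#'   vector of per-subfamily counts.
#' @param reference Species name used as the denominator for the expansion
#'   ratios (default: the first species).
#' @return List with `table` (subfamily x species count matrix with a Total
#'   row), `ratio_to_reference` (per species, 1 decimal), `mean_per_subfamily`
#'   (per species, 3 decimals), `min` and `max` (per species).
#' @export
count_by_subfamily <- function(members_per_species,
                               reference = names(members_per_species)[1L]) {
  stopifnot(length(members_per_species) >= 1L)
  counts <- lapply(members_per_species, function(x) {
    if (is.numeric(x)) {
      setNames(as.integer(x), names(x))
    } else {
      tab <- table(x)
      setNames(as.integer(tab), names(tab))
    }
  })
  subfams <- sort(unique(unlist(lapply(counts, names))))
  mat <- matrix(0L, nrow = length(subfams), ncol = length(counts),
                dimnames = list(subfams, names(counts)))
  for (sp in names(counts)) {
    mat[names(counts[[sp]]), sp] <- counts[[sp]]
  }
  mat <- rbind(mat, Total = colSums(mat))
  totals <- setNames(mat["Total", ], colnames(mat))
  body <- mat[setdiff(rownames(mat), "Total"), , drop = FALSE]
  list(
    table = mat,
    ratio_to_reference = round(totals / totals[[reference]], 1),
    mean_per_subfamily = round(colMeans(body), 3),
    min = if (nrow(body) > 0L) apply(body, 2L, min) else
      setNames(rep(NA_integer_, ncol(body)), colnames(body)),
    max = if (nrow(body) > 0L) apply(body, 2L, max) else
      setNames(rep(NA_integer_, ncol(body)), colnames(body))
  )
}

#' Intron-count statistics for family members
#'
#' @param members A `family_members` data.frame.
#' @param gene_models Named list of `gene_model` objects.
#' @return List with `per_gene` (gene_id, intron_count) and `distribution`
#'   (introns, count, fraction; fractions sum to 1).
#' @export
intron_statistics <- function(members, gene_models) {
  models <- gene_models[members$gene_id]
  if (any(vapply(models, is.null, TRUE))) {
    stop("missing gene model(s) for: ",
         paste(members$gene_id[vapply(models, is.null, TRUE)], collapse = ", "))
  }
  per_gene <- data.frame(
    gene_id = members$gene_id,
    intron_count = vapply(models, intron_count, 0L),
    stringsAsFactors = FALSE
  )
  tab <- table(per_gene$intron_count)
  dist <- data.frame(
    introns = as.integer(names(tab)),
    count = as.integer(tab),
    fraction = as.numeric(tab) / nrow(per_gene)
  )
  list(per_gene = per_gene, distribution = dist)
}

#' Percentage helper for copy-number and DEG-count arithmetic
#'
#' @param n,total Counts.
#' @param digits Decimal places (default 0, i.e. whole percent).
#' @return `round(100 * n / total, digits)`.
#' @export
percent_of <- function(n, total, digits = 0) round(100 * n / total, digits)
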
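# Tandem vs segmental duplication classification and collinearity chaining.

#' Filter homolog pairs for duplication analysis
#'
#' Keeps unordered unique pairs whose similarity and coverage-of-longer are
#' both strictly above the thresholds; self-pairs are excluded.
#'
#' @param hits Hit table (as from [pairwise_hits()] or [homology_hits()]).
#' @param min_coverage,min_similarity Strict thresholds in percent.
#' @return data.frame: gene_a, gene_b (gene_a < gene_b), similarity_pct,
#'   coverage_longer_pct.
#' @export
filter_homolog_pairs <- function(hits, min_coverage = 75,
                                 min_similarity = 75) {
  a <- pmin(hits$query_id, hits$subject_id)
  b <- pmax(hits$query_id, hits$subject_id)
  keep <- a != b &
    hits$similarity_pct > min_similarity &
    hits$coverage_longer_pct > min_coverage
  out <- data.frame(gene_a = a[keep], gene_b = b[keep],
                    similarity_pct = hits$similarity_pct[keep],
                    coverage_longer_pct = hits$coverage_longer_pct[keep],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("gene_a", "gene_b")]), , drop = FALSE]
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect tandem duplication events
#'
#' A homologous pair is tandem iff both genes lie on the same chromosome and
#' their separation (start of the downstream gene minus end of the upstream
#' gene, floored at 0 for overlap) is at most `window`.
#'
#' @param pairs Pair table from [filter_homolog_pairs()].
#' @param gene_models Named list of `gene_model` objects.
#' @param window Maximum separation in bp (default 200,000).
#' @return data.frame: gene_a, gene_b, type ("tandem"), separation_bp.
#' @export
detect_tandem <- function(pairs, gene_models, window = 200000L) {
  tab <- gene_table(gene_models)
  rownames(tab) <- tab$gene_id
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- tab[pairs$gene_a[[i]], ]
    gb <- tab[pairs$gene_b[[i]], ]
    if (is.na(ga$gene_id) || is.na(gb$gene_id)) return(NULL)
    if (ga$chromosome != gb$chromosome) return(NULL)
    up <- if (ga$start <= gb$start) ga else gb
    dn <- if (ga$start <= gb$start) gb else ga
    sep <- max(0L, dn$start - up$end)
    if (sep > window) return(NULL)
    data.frame(gene_a = pairs$gene_a[[i]], gene_b = pairs$gene_b[[i]],
               type = "tandem", separation_bp = sep,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      type = character(0), separation_bp = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

gene_ranks <- function(gene_models) {
  tab <- gene_table(gene_models)
  tab <- tab[order(tab$chromosome, tab$start), , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(tab)), tab$chromosome, FUN = seq_along)
  data.frame(gene_id = tab$gene_id, chromosome = tab$chromosome,
             rank = rank, stringsAsFactors = FALSE, row.names = tab$gene_id)
}

# longest collinear chain by DP on rank coordinates; pts has columns ra, rb
# (unique rows); orientation "same" needs rb increasing, "inverted" decreasing;
# both rank gaps must be in [1, max_gap]
chain_points <- function(pts, orientation, max_gap) {
  if (orientation == "inverted") pts$rb <- -pts$rb
  ord <- order(pts$ra, pts$rb)
  pts <- pts[ord, , drop = FALSE]
  n <- nrow(pts)
  best <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      dra <- pts$ra[j] - pts$ra[i]
      drb <- pts$rb[j] - pts$rb[i]
      if (dra >= 1L && dra <= max_gap && drb >= 1L && drb <= max_gap &&
          best[i] + 1L > best[j]) {
        best[j] <- best[i] + 1L
        prev[j] <- i
      }
    }
  }
  list(pts = pts, best = best, prev = prev, order = ord)
}

#' Chain homologous pairs into collinear blocks
#'
#' Per chromosome pair, chains of homologous gene pairs collinear in rank
#' order are found by dynamic programming (a pair can extend a chain when
#' both rank gaps are at most `max_gap`); chains of at least `min_block`
#' pairs are reported, each pair assigned to at most one block (greedy by
#' descending chain size).
#'
#' @param pairs Pair table from [filter_homolog_pairs()]. For cross-genome
#'   synteny, gene_a must come from genome a and gene_b from genome b.
#' @param gene_models_a,gene_models_b Gene models for the two sides (the same
#'   list twice for within-genome collinearity).
#' @param min_block Minimum chain length (default 5).
#' @param max_gap Maximum rank gap (default 10).
#' @return List of blocks; each block has `pairs` (data.frame gene_a, gene_b
#'   in a-side order), `chrom_a`, `chrom_b`, `orientation`, `size`.
#' @export
chain_collinear_blocks <- function(pairs, gene_models_a, gene_models_b,
                                   min_block = 5L, max_gap = 10L) {
  if (nrow(pairs) == 0L) return(list())
  ranks_a <- gene_ranks(gene_models_a)
  ranks_b <- gene_ranks(gene_models_b)
  within <- identical(names(gene_models_a), names(gene_models_b))

  pr <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                   stringsAsFactors = FALSE)
  if (within) {
    # orient each pair so side a is the lexicographically smaller chromosome
    # (or the upstream gene on a shared chromosome)
    ca <- ranks_a[pr$gene_a, "chromosome"]
    cb <- ranks_a[pr$gene_b, "chromosome"]
    ra <- ranks_a[pr$gene_a, "rank"]
    rb <- ranks_a[pr$gene_b, "rank"]
    swap <- ifelse(is.na(ca) | is.na(cb), FALSE,
                   ca > cb | (ca == cb & ra > rb))
    tmp <- pr$gene_a[swap]
    pr$gene_a[swap] <- pr$gene_b[swap]
    pr$gene_b[swap] <- tmp
  }
  pr$chrom_a <- ranks_a[pr$gene_a, "chromosome"]
  pr$ra <- ranks_a[pr$gene_a, "rank"]
  pr$chrom_b <- ranks_b[pr$gene_b, "chromosome"]
  pr$rb <- ranks_b[pr$gene_b, "rank"]
  pr <- pr[!is.na(pr$chrom_a) & !is.na(pr$chrom_b), , drop = FALSE]
  if (nrow(pr) == 0L) return(list())

  blocks <- list()
  for (key in unique(paste(pr$chrom_a, pr$chrom_b))) {
    sub <- pr[paste(pr$chrom_a, pr$chrom_b) == key, , drop = FALSE]
    used <- rep(FALSE, nrow(sub))
    repeat {
      avail <- which(!used)
      if (length(avail) < min_block) break
      cand <- sub[avail, , drop = FALSE]
      best_chain <- integer(0)
      best_orient <- "same"
      for (orient in c("same", "inverted")) {
        dp <- chain_points(cand[c("ra", "rb")], orient, max_gap)
        j <- which.max(dp$best)
        if (dp$best[j] > length(best_chain)) {
          chain <- integer(0)
          while (!is.na(j)) {
            chain <- c(j, chain)
            j <- dp$prev[j]
          }
          best_chain <- avail[dp$order[chain]]
          best_orient <- orient
        }
      }
      if (length(best_chain) < min_block) break
      bp <- sub[best_chain, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- list(
        pairs = data.frame(gene_a = bp$gene_a, gene_b = bp$gene_b,
                           stringsAsFactors = FALSE),
        chrom_a = bp$chrom_a[[1L]], chrom_b = bp$chrom_b[[1L]],
        orientation = best_orient, size = nrow(bp)
      )
      used[best_chain] <- TRUE
    }
  }
  blocks
}

#' Classify duplication events and summarize
#'
#' Pairs present in both categories resolve to tandem (proximity is the
#' stronger, more specific claim).
#'
#' @param tandem_events From [detect_tandem()].
#' @param blocks From [chain_collinear_blocks()].
#' @param total_genes Total number of family genes (denominator for the
#'   segmental-gene fraction).
#' @return List with `events` (gene_a, gene_b, type, evidence) and `summary`
#'   (n_blocks, n_segmental_pairs, n_genes_in_segmental, n_tandem_pairs,
#'   fraction_segmental_genes_pct as a whole percent).
#' @export
classify_duplications <- function(tandem_events, blocks, total_genes) {
  tkey <- paste(tandem_events$gene_a, tandem_events$gene_b)
  seg <- list()
  for (bi in seq_along(blocks)) {
    bp <- blocks[[bi]]$pairs
    a <- pmin(bp$gene_a, bp$gene_b)
    b <- pmax(bp$gene_a, bp$gene_b)
    keep <- !(paste(a, b) %in% tkey)
    if (any(keep)) {
      seg[[length(seg) + 1L]] <- data.frame(
        gene_a = a[keep], gene_b = b[keep], type = "segmental",
        evidence = paste0("block", bi), stringsAsFactors = FALSE)
    }
  }
  seg <- if (length(seg) > 0L) do.call(rbind, seg) else
    data.frame(gene_a = character(0), gene_b = character(0),
               type = character(0), evidence = character(0))
  seg <- seg[!duplicated(seg[c("gene_a", "gene_b")]), , drop = FALSE]
  tn <- if (nrow(tandem_events) > 0L) {
    data.frame(gene_a = tandem_events$gene_a, gene_b = tandem_events$gene_b,
               type = "tandem",
               evidence = paste0(tandem_events$separation_bp, "bp"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_a = character(0), gene_b = character(0),
               type = character(0), evidence = character(0))
  }
  events <- rbind(tn, seg)
  rownames(events) <- NULL
  n_genes_seg <- length(unique(c(seg$gene_a, seg$gene_b)))
  list(
    events = events,
    summary = list(
      n_blocks = length(blocks),
      n_segmental_pairs = nrow(seg),
      n_genes_in_segmental = n_genes_seg,
      n_tandem_pairs = nrow(tn),
      fraction_segmental_genes_pct =
        if (total_genes > 0) percent_of(n_genes_seg, total_genes) else 0
    )
  )
}

#' Cross-species syntenic pairs per subgenome
#'
#' Builds collinear blocks across two genomes and reports the family-gene
#' pairs inside blocks, partitioned by the target-side subgenome (leading
#' letters of the chromosome name).
#'
#' @param target_members,ancestor_members `family_members` tables (gene ids
#'   used to flag family pairs).
#' @param pairs Cross-genome homolog pairs (gene_a from the target genome,
#'   gene_b from the ancestor genome).
#' @param gene_models_target,gene_models_ancestor Gene model lists.
#' @param min_block,max_gap Chaining parameters.
#' @return List with `blocks` and `pairs_by_subgenome` (named list of
#'   data.frames of family syntenic pairs).
#' @export
cross_species_synteny <- function(target_members, ancestor_members, pairs,
                                  gene_models_target, gene_models_ancestor,
                                  min_block = 5L, max_gap = 10L) {
  blocks <- chain_collinear_blocks(pairs, gene_models_target,
                                   gene_models_ancestor,
                                   min_block = min_block, max_gap = max_gap)
  fam_t <- target_members$gene_id
  fam_a <- ancestor_members$gene_id
  syn <- list()
  for (b in blocks) {
    keep <- b$pairs$gene_a %in% fam_t & b$pairs$gene_b %in% fam_a
    if (!any(keep)) next
    sg <- sub("[0-9].*$", "", b$chrom_a)
    if (sg == "") {
      warning("chromosome ", b$chrom_a,
              " has no subgenome prefix; using single partition")
      sg <- "all"
    }
    syn[[sg]] <- rbind(syn[[sg]], b$pairs[keep, , drop = FALSE])
  }
  syn <- lapply(syn, function(df) {
    df <- df[!duplicated(df), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  list(blocks = blocks, pairs_by_subgenome = syn)
}
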
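# DEG calling, Z-score tables, Venn partitions, coexpression hubs, 2^-ddCt.

#' Row-wise Z-score normalization
#'
#' Each row is centered and scaled to population standard deviation 1
#' (denominator n). Constant rows become all-zero with a warning.
#'
#' @param mat Numeric matrix with >= 2 columns.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  if (ncol(mat) < 2L) stop("need >= 2 samples per row")
  mu <- rowMeans(mat)
  sd_pop <- sqrt(rowMeans((mat - mu)^2))
  const <- sd_pop == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) set to zero")
    sd_pop[const] <- 1
  }
  out <- (mat - mu) / sd_pop
  out[const, ] <- 0
  out
}

welch_p <- function(x, y) {
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
}

#' Call differentially expressed genes for one tissue and contrast
#'
#' Welch t-test on log2(FPKM + pseudocount), Benjamini-Hochberg adjustment
#' within the (tissue, contrast); the fold change is the log2 ratio of group
#' mean FPKM (+ pseudocount). A gene is a DEG iff |log2FC| >= `lfc_min` and
#' FDR < `fdr_max`.
#'
#' @param mat Genes x samples FPKM matrix.
#' @param samples Sample annotation (as from [read_expression_tsv()]).
#' @param tissue Tissue to test.
#' @param contrast Treatment compared against the control.
#' @param control Control treatment (default "CK").
#' @param lfc_min,fdr_max,pseudocount DEG thresholds.
#' @return data.frame: gene_id, tissue, contrast, log2fc, p, fdr, direction,
#'   deg.
#' @export
call_degs <- function(mat, samples, tissue, contrast, control = "CK",
                      lfc_min = 1, fdr_max = 0.05, pseudocount = 1) {
  sel_t <- samples$sample_id[samples$tissue == tissue &
                               samples$treatment == contrast]
  sel_c <- samples$sample_id[samples$tissue == tissue &
                               samples$treatment == control]
  if (length(sel_t) == 0L || length(sel_c) == 0L) {
    stop("missing group for tissue ", tissue, ", contrast ", contrast)
  }
  if (length(sel_t) < 2L || length(sel_c) < 2L) {
    stop("need >= 2 replicates per group")
  }
  trt <- mat[, sel_t, drop = FALSE]
  ctl <- mat[, sel_c, drop = FALSE]
  log_trt <- log2(trt + pseudocount)
  log_ctl <- log2(ctl + pseudocount)
  p <- vapply(seq_len(nrow(mat)), function(i) {
    welch_p(log_trt[i, ], log_ctl[i, ])
  }, 0)
  lfc <- log2((rowMeans(trt) + pseudocount) / (rowMeans(ctl) + pseudocount))
  fdr <- p.adjust(p, method = "BH")
  out <- data.frame(
    gene_id = rownames(mat), tissue = tissue, contrast = contrast,
    log2fc = lfc, p = p, fdr = fdr,
    direction = ifelse(lfc > 0, "up", "down"),
    deg = abs(lfc) >= lfc_min & fdr < fdr_max,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Call DEGs for every (tissue, contrast) combination
#'
#' @param mat,samples As in [call_degs()].
#' @param control Control treatment.
#' @param ... Passed to [call_degs()].
#' @return Named list ("tissue:contrast") of DEG tables.
#' @export
call_all_degs <- function(mat, samples, control = "CK", ...) {
  tissues <- unique(samples$tissue)
  contrasts <- setdiff(unique(samples$treatment), control)
  out <- list()
  for (ti in tissues) {
    for (co in contrasts) {
      out[[paste(ti, co, sep = ":")]] <-
        call_degs(mat, samples, ti, co, control = control, ...)
    }
  }
  out
}

#' Partition the union of named sets into Venn regions
#'
#' @param deg_sets Named list (k >= 2) of character vectors.
#' @return List with `regions` (data.frame region, size) covering all
#'   2^k - 1 regions, and `membership` (data.frame gene, region).
#' @export
venn_partition <- function(deg_sets) {
  k <- length(deg_sets)
  if (k < 2L) stop("need >= 2 named sets")
  if (is.null(names(deg_sets)) || any(names(deg_sets) == "")) {
    stop("sets must be named")
  }
  nm <- names(deg_sets)
  all_genes <- sort(unique(unlist(deg_sets)))
  pattern <- vapply(deg_sets, function(s) all_genes %in% s,
                    logical(length(all_genes)))
  if (length(all_genes) == 1L) pattern <- matrix(pattern, nrow = 1L)
  region_of <- apply(pattern, 1L, function(row) {
    paste(nm[row], collapse = "&")
  })
  combos <- unlist(lapply(seq_len(k), function(m) {
    apply(combn(nm, m), 2L, paste, collapse = "&")
  }))
  sizes <- setNames(integer(length(combos)), combos)
  tab <- table(region_of)
  sizes[names(tab)] <- as.integer(tab)
  list(
    regions = data.frame(region = combos, size = unname(sizes),
                         stringsAsFactors = FALSE),
    membership = data.frame(gene = all_genes, region = region_of,
                            stringsAsFactors = FALSE)
  )
}

#' Genes differentially expressed in every condition
#'
#' @param deg_sets Named list (>= 1) of character vectors of DEG ids.
#' @return Character vector: the intersection over all sets.
#' @export
universal_responders <- function(deg_sets) {
  if (length(deg_sets) == 0L) stop("need >= 1 set")
  sort(Reduce(intersect, deg_sets))
}

#' Build a Pearson coexpression network
#'
#' Pearson correlation over the samples of the named treatments (replicates
#' used as individual samples); an edge joins two genes iff |r| > cutoff.
#' Constant genes are excluded (their correlation is undefined).
#'
#' @param mat Genes x samples FPKM matrix.
#' @param samples Sample annotation.
#' @param treatments Treatments whose samples enter the correlation (default
#'   N-sufficient and N-free, i.e. CK and LN).
#' @param cutoff Association cutoff on |r| (default 0.6, strict).
#' @return List (class `coexpression_network`): nodes, edges (gene_a, gene_b,
#'   r with gene_a < gene_b), degree (named, all nodes).
#' @export
build_network <- function(mat, samples, treatments = c("CK", "LN"),
                          cutoff = 0.6) {
  sel <- samples$sample_id[samples$treatment %in% treatments]
  if (length(sel) < 3L) stop("need >= 3 samples after treatment filtering")
  sub <- mat[, sel, drop = FALSE]
  const <- apply(sub, 1L, function(x) sd(x) == 0)
  if (any(const)) {
    warning(sum(const), " constant gene(s) excluded from the network")
    sub <- sub[!const, , drop = FALSE]
  }
  cc <- cor(t(sub))
  nodes <- rownames(sub)
  idx <- which(upper.tri(cc) & abs(cc) > cutoff, arr.ind = TRUE)
  edges <- data.frame(
    gene_a = nodes[idx[, 1L]], gene_b = nodes[idx[, 2L]],
    r = cc[idx], stringsAsFactors = FALSE
  )
  swap <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[swap]
  edges$gene_a[swap] <- edges$gene_b[swap]
  edges$gene_b[swap] <- tmp
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  degree <- setNames(integer(length(nodes)), nodes)
  tab <- table(c(edges$gene_a, edges$gene_b))
  degree[names(tab)] <- as.integer(tab)
  structure(list(nodes = nodes, edges = edges, degree = degree),
            class = "coexpression_network")
}

#' Rank hub genes by degree
#'
#' Nodes with at least one edge, ranked by degree descending with
#' lexicographic tie-break; the top k are the hub genes.
#'
#' @param network A `coexpression_network`.
#' @param k Number of hubs (default 10).
#' @return data.frame: gene_id, degree.
#' @export
hub_genes <- function(network, k = 10L) {
  deg <- network$degree[network$degree > 0L]
  ord <- order(-deg, names(deg))
  top <- head(ord, k)
  data.frame(gene_id = names(deg)[top], degree = as.integer(deg[top]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt = Ct_target - Ct_reference; per condition,
#' ddCt = mean dCt(condition) - mean dCt(calibrator) and the fold change is
#' 2^-ddCt. Significance against the calibrator is a two-sided Welch t-test
#' on the replicate dCt values, flagged "*" at P < 0.05 and "**" at P < 0.01.
#'
#' @param ct_table Long data.frame: gene_id, tissue, treatment, replicate, ct
#'   (the reference gene appears as rows like any target).
#' @param reference_gene Housekeeping gene id (e.g. "EF1a").
#' @param calibrator Length-2 character vector c(tissue, treatment).
#' @return data.frame: gene_id, tissue, treatment, n, ddct, fold, p, flag.
#' @export
ddct <- function(ct_table, reference_gene, calibrator) {
  stopifnot(length(calibrator) == 2L)
  ref <- ct_table[ct_table$gene_id == reference_gene, , drop = FALSE]
  if (nrow(ref) == 0L) stop("reference gene ", reference_gene, " not in table")
  targets <- setdiff(unique(ct_table$gene_id), reference_gene)
  key <- function(df) paste(df$tissue, df$treatment, df$replicate)
  ref_ct <- setNames(ref$ct, key(ref))
  out <- list()
  for (g in targets) {
    sub <- ct_table[ct_table$gene_id == g, , drop = FALSE]
    rk <- key(sub)
    if (anyNA(ref_ct[rk])) {
      stop("missing reference Ct for gene ", g)
    }
    dct <- sub$ct - unname(ref_ct[rk])
    cond <- paste(sub$tissue, sub$treatment)
    cal_sel <- sub$tissue == calibrator[[1L]] &
      sub$treatment == calibrator[[2L]]
    if (!any(cal_sel)) stop("calibrator condition absent for gene ", g)
    cal_dct <- dct[cal_sel]
    for (cn in unique(cond)) {
      sel <- cond == cn
      dd <- mean(dct[sel]) - mean(cal_dct)
      is_cal <- cn == paste(calibrator, collapse = " ")
      p <- if (is_cal) NA_real_ else welch_p(dct[sel], cal_dct)
      flag <- if (is.na(p)) "" else if (p < 0.01) "**"
        else if (p < 0.05) "*" else ""
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, tissue = sub$tissue[sel][1L],
        treatment = sub$treatment[sel][1L], n = sum(sel),
        ddct = dd, fold = 2^(-dd), p = p, flag = flag,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
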
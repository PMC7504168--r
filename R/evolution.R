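# Selection-pressure analysis (Nei-Gojobori 1986 Ka/Ks with Jukes-Cantor
# correction) and neighbor-joining phylogeny with bootstrap support.

GENCODE <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::GENETIC_CODE
    cache
  }
})

codons_of <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Back-translate a pairwise protein alignment to a codon alignment
#'
#' Each aligned residue column expands to its codon. Columns with a gap in
#' either sequence, or whose codon contains a non-ACGT base, are dropped and
#' recorded in the mask. Each CDS must translate (standard code) to its
#' gap-stripped protein.
#'
#' @param prot_aln Named character vector of two aligned protein strings
#'   (equal length, `-` for gaps).
#' @param cds_a,cds_b Coding sequences of the two proteins (with or without
#'   the terminal stop codon).
#' @return List (class `codon_alignment`): ids, `a` and `b` (aligned codon
#'   strings, equal length divisible by 3), `mask` (dropped alignment column
#'   indices), `n_codons`.
#' @export
backtranslate_alignment <- function(prot_aln, cds_a, cds_b) {
  stopifnot(length(prot_aln) == 2L)
  ids <- names(prot_aln)
  if (is.null(ids)) ids <- c("a", "b")
  aln_a <- seq_chars(prot_aln[[1L]])
  aln_b <- seq_chars(prot_aln[[2L]])
  if (length(aln_a) != length(aln_b)) stop("aligned strings differ in length")

  check_and_codons <- function(aln, cds, id) {
    prot <- paste(aln[aln != "-"], collapse = "")
    cod <- codons_of(cds)
    tr <- unname(GENCODE()[cod])
    tr[is.na(tr)] <- "X"
    if (length(tr) > 0L && tr[length(tr)] == "*") tr <- tr[-length(tr)]
    if (length(tr) != nchar(prot)) {
      stop("CDS of ", id, " has ", length(tr),
           " codons but protein has ", nchar(prot), " residues")
    }
    pc <- seq_chars(prot)
    bad <- which(tr != pc)
    if (length(bad) > 0L) {
      stop("CDS/protein mismatch for ", id, " at residue ", bad[[1L]])
    }
    cod[seq_along(pc)]
  }
  cod_a <- check_and_codons(aln_a, cds_a, ids[[1L]])
  cod_b <- check_and_codons(aln_b, cds_b, ids[[2L]])

  ia <- ib <- 0L
  keep_a <- keep_b <- character(0)
  mask <- integer(0)
  for (col in seq_along(aln_a)) {
    ga <- aln_a[col] == "-"
    gb <- aln_b[col] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (ga || gb) {
      mask <- c(mask, col)
      next
    }
    ca <- cod_a[ia]; cb <- cod_b[ib]
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) {
      mask <- c(mask, col)
      next
    }
    keep_a <- c(keep_a, ca)
    keep_b <- c(keep_b, cb)
  }
  structure(
    list(ids = ids, a = paste(keep_a, collapse = ""),
         b = paste(keep_b, collapse = ""), mask = mask,
         n_codons = length(keep_a)),
    class = "codon_alignment"
  )
}

# fraction of the 3 possible changes per position that are synonymous;
# changes creating a stop codon count as nonsynonymous
codon_syn_sites <- function(codon) {
  code <- GENCODE()
  aa <- code[[codon]]
  f <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (nt in setdiff(c("A", "C", "G", "T"), ref)) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (code[[alt]] != "*" && code[[alt]] == aa) f <- f + 1 / 3
    }
  }
  f
}

perm_orders <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perm_orders(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# average synonymous/nonsynonymous difference counts over all minimal
# mutational pathways between two codons; pathways through stop codons are
# excluded (if every pathway is blocked, all are used with stop steps counted
# as nonsynonymous)
codon_pair_diffs <- function(c1, c2) {
  code <- GENCODE()
  pos <- which(seq_chars(c1) != seq_chars(c2))
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths <- perm_orders(pos)
  tally <- function(order, allow_stop) {
    cur <- c1
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && (code[[nxt]] == "*" || code[[cur]] == "*")) {
        return(NULL)
      }
      if (code[[nxt]] == code[[cur]] && code[[nxt]] != "*") {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(paths, tally, allow_stop = FALSE)
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0L) res <- lapply(paths, tally, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

jukes_cantor <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks for a codon alignment
#'
#' Synonymous site fractions are averaged over the two sequences; observed
#' differences are counted over all minimal mutational pathways with equal
#' weights; proportions are corrected with Jukes-Cantor
#' \eqn{d = -3/4 \log(1 - 4p/3)}. Saturated proportions (p >= 3/4) give an
#' undefined rate; Ks = 0 gives an undefined ratio.
#'
#' @param codon_aln A `codon_alignment` from [backtranslate_alignment()], or
#'   a list with elements `a` and `b` (equal-length codon strings).
#' @return List (class `kaks_result`): ids, ka, ks, ratio, selection, and the
#'   intermediate site/difference counts.
#' @export
ng86_kaks <- function(codon_aln) {
  a <- codons_of(codon_aln$a)
  b <- codons_of(codon_aln$b)
  if (length(a) != length(b)) stop("unequal codon counts")
  if (length(a) == 0L) stop("no retained codon columns")
  s_a <- sum(vapply(a, codon_syn_sites, 0))
  s_b <- sum(vapply(b, codon_syn_sites, 0))
  S <- (s_a + s_b) / 2
  N <- 3 * length(a) - S
  diffs <- mapply(function(x, y) codon_pair_diffs(x, y), a, b)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  ks <- jukes_cantor(ps)
  ka <- jukes_cantor(pn)
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  structure(
    list(ids = codon_aln$ids, ka = ka, ks = ks, ratio = ratio,
         selection = classify_selection(ratio),
         S = S, N = N, Sd = Sd, Nd = Nd),
    class = "kaks_result"
  )
}

#' Classify selection pressure from a Ka/Ks ratio
#'
#' Ratio > 1: positive selection; < 1: purifying (functional constraint);
#' = 1: neutral; undefined ratio: undefined.
#'
#' @param ratio Ka/Ks ratio or NA.
#' @return One of "positive", "purifying", "neutral", "undefined".
#' @export
classify_selection <- function(ratio) {
  if (is.na(ratio)) return("undefined")
  if (ratio > 1) "positive" else if (ratio < 1) "purifying" else "neutral"
}

#' Ka/Ks table for member/reference pairs
#'
#' For each family member, aligns its protein to its best reference (global
#' alignment), back-translates with both CDS and computes NG86 Ka/Ks.
#'
#' @param members A `family_members` data.frame.
#' @param proteins,cds Named vectors covering the members.
#' @param ref_proteins,ref_cds Named vectors covering the references (bare
#'   reference ids).
#' @return data.frame: gene_id, reference, ka, ks, ratio, selection.
#' @export
kaks_table <- function(members, proteins, cds, ref_proteins, ref_cds) {
  rows <- lapply(seq_len(nrow(members)), function(i) {
    gid <- members$gene_id[[i]]
    rid <- members$best_reference[[i]]
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(proteins[[gid]]),
      subject = Biostrings::AAString(ref_proteins[[rid]]),
      type = "global", substitutionMatrix = blosum62_x0(),
      gapOpening = 10, gapExtension = 0.5
    )
    aln <- setNames(c(as.character(Biostrings::alignedPattern(pa)),
                      as.character(Biostrings::alignedSubject(pa))),
                    c(gid, rid))
    res <- ng86_kaks(backtranslate_alignment(aln, cds[[gid]], ref_cds[[rid]]))
    data.frame(gene_id = gid, reference = rid, ka = res$ka, ks = res$ks,
               ratio = res$ratio, selection = res$selection,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q criterion. Ties are
#' broken by the smallest (i, j) index pair; negative branch lengths are
#' clamped to zero with the deficit transferred to the sister branch.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal and
#'   row/column names (>= 3 taxa).
#' @return Unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix not symmetric")
  if (any(d < -1e-12)) stop("negative distances")
  if (any(abs(diag(d)) > 1e-12)) stop("nonzero diagonal")
  node <- rownames(d)
  fmt <- function(x) sprintf("%.10g", x)
  while (n > 3L) {
    r <- rowSums(d)
    bq <- Inf; bi <- 1L; bj <- 2L
    for (i in 1L:(n - 1L)) {
      for (j in (i + 1L):n) {
        q <- (n - 2) * d[i, j] - r[i] - r[j]
        if (q < bq) { bq <- q; bi <- i; bj <- j }
      }
    }
    vi <- d[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (n - 2))
    vj <- d[bi, bj] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newlab <- paste0("(", node[bi], ":", fmt(vi), ",",
                     node[bj], ":", fmt(vj), ")")
    dn <- (d[bi, ] + d[bj, ] - d[bi, bj]) / 2
    keep <- setdiff(seq_len(n), c(bi, bj))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    node <- c(node[keep], newlab)
    n <- n - 1L
  }
  va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- pmax(c(va, vb, vc), 0)
  nwk <- paste0("(", node[1], ":", fmt(v[1]), ",", node[2], ":", fmt(v[2]),
                ",", node[3], ":", fmt(v[3]), ");")
  ape::read.tree(text = nwk)
}

#' Pairwise p-distances of a multiple alignment
#'
#' Fraction of differing columns among columns where both sequences are
#' ungapped.
#'
#' @param alignment Named character vector of equal-length aligned sequences.
#' @return Symmetric distance matrix.
#' @export
p_distance <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      d[i, j] <- d[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
    }
  }
  d
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement; each replicate tree is
#' built by NJ on p-distances; support for each internal branch of the
#' original tree is the percentage of replicates containing that bipartition
#' (mapped onto the original topology, MEGA-style).
#'
#' @param alignment Named character vector of aligned sequences (>= 4).
#' @param n_reps Number of replicates (default 1000).
#' @param seed RNG seed.
#' @return `ape::phylo` tree with supports (percent) as node labels.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = 1L) {
  if (length(alignment) < 4L) stop("need >= 4 aligned sequences")
  m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  rownames(m) <- names(alignment)
  as_aln <- function(mm) setNames(apply(mm, 1L, paste, collapse = ""),
                                  rownames(mm))
  orig <- nj_tree(p_distance(as_aln(m)))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    idx <- sample.int(ncol(m), replace = TRUE)
    reps[[k]] <- nj_tree(p_distance(as_aln(m[, idx, drop = FALSE])))
  }
  counts <- ape::prop.clades(orig, reps, rooted = FALSE)
  supp <- round(100 * counts / n_reps)
  supp_chr <- ifelse(is.na(supp), "", as.character(supp))
  orig$node.label <- supp_chr
  orig
}

#' Center-star multiple protein alignment
#'
#' Progressive desk-scale aligner: the longest sequence is the center; every
#' other sequence is globally aligned to it and the pairwise gap patterns are
#' merged into one multiple alignment.
#'
#' @param seqs Named character vector of protein sequences (>= 2).
#' @param gap_open,gap_extend Affine gap penalties.
#' @return Named character vector of equal-length aligned sequences.
#' @export
align_proteins <- function(seqs, gap_open = 10, gap_extend = 0.5) {
  stopifnot(length(seqs) >= 2L)
  ci <- which.max(nchar(seqs))
  center <- seqs[[ci]]
  others <- seqs[-ci]
  L <- nchar(center)
  # per sequence: ins[[c]] = residues inserted before center residue c
  # (c = L+1 for a tail insertion); al[c] = residue aligned to center residue c
  parsed <- lapply(others, function(s) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(s),
      subject = Biostrings::AAString(center),
      type = "global", substitutionMatrix = blosum62_x0(),
      gapOpening = gap_open, gapExtension = gap_extend
    )
    sc <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
    pc <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
    ins <- vector("list", L + 1L)
    al <- character(L)
    c_idx <- 0L
    for (k in seq_along(sc)) {
      if (sc[k] == "-") {
        slot <- c_idx + 1L
        ins[[slot]] <- c(ins[[slot]], pc[k])
      } else {
        c_idx <- c_idx + 1L
        al[c_idx] <- pc[k]
      }
    }
    list(ins = ins, al = al)
  })
  maxins <- vapply(seq_len(L + 1L), function(c) {
    max(c(0L, vapply(parsed, function(p) length(p$ins[[c]]), 0L)))
  }, 0L)
  build_row <- function(ins, al) {
    out <- character(0)
    for (c in seq_len(L)) {
      pad <- maxins[c] - length(ins[[c]])
      out <- c(out, ins[[c]], rep("-", pad), al[c])
    }
    pad <- maxins[L + 1L] - length(ins[[L + 1L]])
    paste(c(out, ins[[L + 1L]], rep("-", pad)), collapse = "")
  }
  center_row <- build_row(vector("list", L + 1L), seq_chars(center))
  rows <- vapply(parsed, function(p) build_row(p$ins, p$al), "")
  out <- c(setNames(center_row, names(seqs)[ci]), rows)
  out[names(seqs)]
}
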
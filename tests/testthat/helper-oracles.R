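# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately use different code paths from the package.

# --- affine-gap local alignment (Gotoh matrices, score only) ---------------
oracle_local_score <- function(a, b, go = 10, ge = 0.5) {
  mat <- genefamr:::blosum62_x0()
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1L, m + 1L)
  Ix <- matrix(-Inf, n + 1L, m + 1L)
  Iy <- matrix(-Inf, n + 1L, m + 1L)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      Ix[i, j] <- max(M[i - 1L, j] - go - ge, Ix[i - 1L, j] - ge)
      Iy[i, j] <- max(M[i, j - 1L] - go - ge, Iy[i, j - 1L] - ge)
      M[i, j] <- max(0, max(M[i - 1L, j - 1L], Ix[i - 1L, j - 1L],
                            Iy[i - 1L, j - 1L]) + mat[A[i - 1L], B[j - 1L]])
      best <- max(best, M[i, j], Ix[i, j], Iy[i, j])
    }
  }
  best
}

# --- NG86 via depth-first pathway enumeration ------------------------------
oracle_ng86 <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  split_codons <- function(s) substring(s, seq(1, nchar(s), 3),
                                        seq(3, nchar(s), 3))
  ca <- split_codons(a); cb <- split_codons(b)
  syn_sites <- function(codon) {
    total <- 0
    for (pos in 1:3) {
      for (nt in c("A", "C", "G", "T")) {
        if (nt == substr(codon, pos, pos)) next
        alt <- codon
        substr(alt, pos, pos) <- nt
        if (code[[alt]] != "*" && code[[alt]] == code[[codon]]) {
          total <- total + 1 / 3
        }
      }
    }
    total
  }
  # DFS over orders of applying the differing positions
  walk <- function(cur, target, pos_left, allow_stop) {
    if (length(pos_left) == 0L) return(list(c(0, 0)))
    out <- list()
    for (p in pos_left) {
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      if (!allow_stop && code[[nxt]] == "*") next
      step <- if (code[[nxt]] == code[[cur]] && code[[nxt]] != "*") {
        c(1, 0)
      } else {
        c(0, 1)
      }
      for (tail in walk(nxt, target, setdiff(pos_left, p), allow_stop)) {
        out[[length(out) + 1L]] <- step + tail
      }
    }
    out
  }
  S <- (sum(vapply(ca, syn_sites, 0)) + sum(vapply(cb, syn_sites, 0))) / 2
  N <- 3 * length(ca) - S
  Sd <- Nd <- 0
  for (k in seq_along(ca)) {
    pos <- which(strsplit(ca[k], "")[[1L]] != strsplit(cb[k], "")[[1L]])
    if (length(pos) == 0L) next
    paths <- walk(ca[k], cb[k], pos, allow_stop = FALSE)
    if (length(paths) == 0L) paths <- walk(ca[k], cb[k], pos, TRUE)
    avg <- Reduce(`+`, paths) / length(paths)
    Sd <- Sd + avg[1L]
    Nd <- Nd + avg[2L]
  }
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else {
    -0.75 * log(1 - 4 * p / 3)
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       ks = jc(if (S > 0) Sd / S else NA), ka = jc(if (N > 0) Nd / N else NA))
}

random_stopfree_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), 3 * n_codons, TRUE),
               collapse = "")
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    if (!any(code[cods] == "*")) return(s)
  }
}

# --- longest collinear chain by exhaustive subset search -------------------
oracle_longest_chain <- function(ra, rb, max_gap) {
  n <- length(ra)
  best <- 0L
  check <- function(idx, rb_sign) {
    o <- order(ra[idx])
    a <- ra[idx][o]; b <- rb_sign * rb[idx][o]
    all(diff(a) >= 1 & diff(a) <= max_gap & diff(b) >= 1 & diff(b) <= max_gap)
  }
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= best) next
    if (length(idx) == 1L || check(idx, 1) || check(idx, -1)) {
      best <- length(idx)
    }
  }
  best
}

# --- IUPAC scan position-by-position ---------------------------------------
oracle_iupac_hits <- function(seq, consensus) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  sc <- strsplit(seq, "")[[1L]]
  cc <- strsplit(consensus, "")[[1L]]
  w <- length(cc)
  hits <- integer(0)
  for (p in seq_len(length(sc) - w + 1L)) {
    ok <- TRUE
    for (k in seq_len(w)) {
      if (!sc[p + k - 1L] %in% sets[[cc[k]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

# --- random additive tree distances (via ape) ------------------------------
random_additive_case <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) runif(k, 0.1, 2))
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
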
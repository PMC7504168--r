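# Protein characterization: MW, theoretical pI, GRAVY, hydropathy-window TMDs.

# average (free amino acid) masses in Da; peptide MW = sum - (n-1) * water
AA_MASS <- c(
  G = 75.0669, A = 89.0935, S = 105.0930, P = 115.1310, V = 117.1469,
  T = 119.1197, C = 121.1590, L = 131.1736, I = 131.1736, N = 132.1184,
  D = 133.1032, Q = 146.1451, K = 146.1882, E = 147.1293, M = 149.2124,
  H = 155.1552, F = 165.1900, R = 174.2017, Y = 181.1894, W = 204.2262
)
WATER_MASS <- 18.01528

#' Kyte-Doolittle hydropathy scale
#' @return Named numeric vector, one value per residue.
#' @export
kyte_doolittle <- function() c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# EMBOSS pKa values
EMBOSS_PKA <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
                H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

#' Molecular weight of a protein
#'
#' Sum of average amino-acid masses minus one water per peptide bond.
#' Unknown residues (X) take the mean residue mass.
#'
#' @param seq Protein sequence.
#' @return MW in kDa (unrounded; round to 2 decimals for reporting).
#' @export
compute_mw <- function(seq) {
  if (nchar(seq) == 0L) stop("empty sequence")
  ch <- seq_chars(seq)
  masses <- AA_MASS[ch]
  masses[is.na(masses)] <- mean(AA_MASS)
  (sum(masses) - (length(ch) - 1L) * WATER_MASS) / 1000
}

#' Theoretical isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge is zero, found by
#' bisection on [0, 14] to a tolerance of 0.001 pH units.
#'
#' @param seq Protein sequence.
#' @param pka Named pKa vector covering Nterm, Cterm and the ionizable
#'   residues D, E, C, Y, H, K, R (default: EMBOSS values).
#' @return pI in pH units.
#' @export
compute_pi <- function(seq, pka = EMBOSS_PKA) {
  if (nchar(seq) == 0L) stop("empty sequence")
  ch <- seq_chars(seq)
  counts <- table(ch)
  n_of <- function(a) if (a %in% names(counts)) as.numeric(counts[[a]]) else 0
  charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - pka[["Nterm"]])) +
      n_of("K") / (1 + 10^(ph - pka[["K"]])) +
      n_of("R") / (1 + 10^(ph - pka[["R"]])) +
      n_of("H") / (1 + 10^(ph - pka[["H"]]))
    neg <- 1 / (1 + 10^(pka[["Cterm"]] - ph)) +
      n_of("D") / (1 + 10^(pka[["D"]] - ph)) +
      n_of("E") / (1 + 10^(pka[["E"]] - ph)) +
      n_of("C") / (1 + 10^(pka[["C"]] - ph)) +
      n_of("Y") / (1 + 10^(pka[["Y"]] - ph))
    pos - neg
  }
  lo <- 0; hi <- 14
  while (hi - lo > 0.001) {
    mid <- (lo + hi) / 2
    if (charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Grand average of hydropathy (GRAVY)
#'
#' Sum of per-residue hydropathy values divided by the protein length.
#' A protein is classified hydrophobic when GRAVY > 0.
#'
#' @param seq Protein sequence.
#' @param scale Hydropathy scale (default Kyte-Doolittle).
#' @return GRAVY value (dimensionless).
#' @export
compute_gravy <- function(seq, scale = kyte_doolittle()) {
  if (nchar(seq) == 0L) stop("empty sequence")
  ch <- seq_chars(seq)
  vals <- scale[ch]
  if (anyNA(vals)) {
    stop("hydropathy scale undefined for residue(s): ",
         paste(unique(ch[is.na(vals)]), collapse = ", "))
  }
  mean(vals)
}

#' Predict transmembrane domains by hydropathy windows
#'
#' Centered sliding-window mean hydropathy; window positions whose mean
#' exceeds the threshold are expanded to their window extent and overlapping
#' extents are merged; each merged run is one TMD.
#'
#' @param seq Protein sequence.
#' @param window Window length in residues (odd; default 19).
#' @param threshold Window-mean hydropathy cutoff (default 1.6).
#' @param scale Hydropathy scale.
#' @return List with `segments` (matrix of start, end; each >= window long)
#'   and `count`.
#' @export
predict_tmds <- function(seq, window = 19L, threshold = 1.6,
                         scale = kyte_doolittle()) {
  n <- nchar(seq)
  if (n < window) {
    warning("sequence shorter than window; 0 TMDs reported")
    return(list(segments = matrix(integer(0), ncol = 2L,
                                  dimnames = list(NULL, c("start", "end"))),
                count = 0L))
  }
  vals <- scale[seq_chars(seq)]
  if (anyNA(vals)) stop("hydropathy scale undefined for some residue")
  cs <- cumsum(c(0, vals))
  means <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  qual <- which(means > threshold)  # window start positions
  if (length(qual) == 0L) {
    return(list(segments = matrix(integer(0), ncol = 2L,
                                  dimnames = list(NULL, c("start", "end"))),
                count = 0L))
  }
  # merge overlapping window extents [q, q + window - 1]
  starts <- ends <- integer(0)
  cur_s <- qual[[1L]]
  cur_e <- qual[[1L]] + window - 1L
  for (q in qual[-1L]) {
    if (q <= cur_e + 1L) {
      cur_e <- q + window - 1L
    } else {
      starts <- c(starts, cur_s); ends <- c(ends, cur_e)
      cur_s <- q; cur_e <- q + window - 1L
    }
  }
  starts <- c(starts, cur_s); ends <- c(ends, cur_e)
  segs <- cbind(start = starts, end = ends)
  list(segments = segs, count = nrow(segs))
}

#' Characterization table for a set of proteins
#'
#' @param seqs Named character vector of protein sequences.
#' @param tmd_window,tmd_threshold Parameters for [predict_tmds()].
#' @return data.frame: protein_id, length, mw_kda (2 decimals), pi, gravy,
#'   hydrophobic, high_pi, tmd_count.
#' @export
protein_properties <- function(seqs, tmd_window = 19L, tmd_threshold = 1.6) {
  rows <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    gravy <- compute_gravy(s)
    pi <- compute_pi(s)
    data.frame(
      protein_id = id,
      length = nchar(s),
      mw_kda = round(compute_mw(s), 2),
      pi = round(pi, 2),
      gravy = gravy,
      hydrophobic = gravy > 0,
      high_pi = pi > 7,
      tmd_count = predict_tmds(s, window = tmd_window,
                               threshold = tmd_threshold)$count,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
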
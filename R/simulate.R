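# Synthetic-study generator: genome, annotation, family proteins, planted
# duplications, expression with planted DEGs and a hub module, promoters with
# planted CREs, and qPCR Ct tables -- all with a machine-readable truth record.

AA20 <- names(AA_MASS)

SYN_CODONS <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- split(names(Biostrings::GENETIC_CODE),
                                        unname(Biostrings::GENETIC_CODE))
    cache
  }
})

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(len) {
  paste(c("M", sample(AA20, len - 1L, replace = TRUE)), collapse = "")
}

# substitute residues at the given per-site rate (initiator M kept fixed);
# substituted residues always change
mutate_protein <- function(prot, rate) {
  ch <- seq_chars(prot)
  idx <- which(runif(length(ch)) < rate)
  idx <- idx[idx > 1L]
  for (i in idx) ch[i] <- sample(setdiff(AA20, ch[i]), 1L)
  paste(ch, collapse = "")
}

protein_to_cds <- function(prot) {
  syn <- SYN_CODONS()
  ch <- seq_chars(prot)
  codons <- vapply(ch, function(a) {
    opts <- syn[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  stop_cod <- syn[["*"]][sample.int(3L, 1L)]
  paste(c(codons, stop_cod), collapse = "")
}

# derive a child CDS from a parent CDS given the child protein: unchanged
# residues keep the parent codon (with probability swap_rate replaced by a
# different synonymous codon), changed residues get a random codon of the new
# amino acid
derive_cds <- function(parent_cds, child_prot, swap_rate) {
  syn <- SYN_CODONS()
  code <- Biostrings::GENETIC_CODE
  codons <- codons_of(parent_cds)
  ch <- seq_chars(child_prot)
  stopifnot(length(codons) == length(ch) + 1L)
  out <- character(length(codons))
  for (i in seq_along(ch)) {
    parent_aa <- code[[codons[i]]]
    if (parent_aa == ch[i]) {
      opts <- syn[[ch[i]]]
      if (length(opts) > 1L && runif(1L) < swap_rate) {
        alt <- setdiff(opts, codons[i])
        out[i] <- alt[sample.int(length(alt), 1L)]
      } else {
        out[i] <- codons[i]
      }
    } else {
      opts <- syn[[ch[i]]]
      out[i] <- opts[sample.int(length(opts), 1L)]
    }
  }
  last <- codons[length(codons)]
  out[length(codons)] <- if (runif(1L) < swap_rate) {
    syn[["*"]][sample.int(3L, 1L)]
  } else {
    last
  }
  paste(out, collapse = "")
}

choose_intron_count <- function(probs, cds_len, min_exon = 30L) {
  k <- as.integer(sample(names(probs), 1L, prob = probs))
  max_k <- max(0L, cds_len %/% min_exon - 1L)
  min(k, max_k)
}

# split a CDS into exons separated by GT..AG introns; local coordinates start
# at 1 for the first CDS base
build_gene_body <- function(cds_seq, n_introns, min_exon = 30L) {
  L <- nchar(cds_seq)
  if (n_introns == 0L) {
    return(list(seq = cds_seq,
                exons = matrix(c(1L, L), ncol = 2L,
                               dimnames = list(NULL, c("start", "end")))))
  }
  repeat {
    cuts <- sort(sample(seq(min_exon, L - min_exon), n_introns))
    if (n_introns == 1L || min(diff(cuts)) >= min_exon) break
  }
  bounds <- c(0L, cuts, L)
  pieces <- character(0)
  exons <- matrix(0L, nrow = n_introns + 1L, ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  pos <- 0L
  for (i in seq_len(n_introns + 1L)) {
    ex <- substr(cds_seq, bounds[i] + 1L, bounds[i + 1L])
    exons[i, ] <- c(pos + 1L, pos + nchar(ex))
    pieces <- c(pieces, ex)
    pos <- pos + nchar(ex)
    if (i <= n_introns) {
      ilen <- sample(80:300, 1L)
      pieces <- c(pieces, paste0("GT", random_dna(ilen - 4L), "AG"))
      pos <- pos + ilen
    }
  }
  list(seq = paste(pieces, collapse = ""), exons = exons)
}

# promoter background free of catalog matches
scrub_background <- function(len, catalog, max_iter = 50L) {
  seq <- random_dna(len)
  for (iter in seq_len(max_iter)) {
    hits <- scan_cres(seq, catalog)
    if (nrow(hits) == 0L) return(seq)
    for (i in seq_len(nrow(hits))) {
      w <- nchar(hits$matched[[i]])
      p <- hits$position[[i]] + sample.int(w, 1L) - 1L
      substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(seq, p, p)), 1L)
    }
  }
  stop("could not scrub promoter background of catalog matches")
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

realize_consensus <- function(cons) {
  paste(vapply(seq_chars(cons), function(l) {
    s <- IUPAC_SETS[[l]]
    s[sample.int(length(s), 1L)]
  }, ""), collapse = "")
}

# build one promoter with planted CREs; returns the sequence plus the full
# expected hit set (which, on a scrubbed background, is exactly the planted
# signal including palindrome mirror hits and strand-twin motifs)
plant_promoter <- function(len, catalog, n_range, max_retry = 20L) {
  if (any(nchar(catalog$consensus) > len)) {
    stop("motif longer than promoter")
  }
  for (attempt in seq_len(max_retry)) {
    seq <- scrub_background(len, catalog)
    k <- sample(seq(n_range[1L], n_range[2L]), 1L)
    rows <- catalog[sample.int(nrow(catalog), k, replace = TRUE), ,
                    drop = FALSE]
    intervals <- matrix(0L, nrow = 0L, ncol = 2L)
    planted <- list()
    ok <- TRUE
    for (i in seq_len(k)) {
      w <- nchar(rows$consensus[[i]])
      placed <- FALSE
      for (try in seq_len(50L)) {
        pos <- sample.int(len - w + 1L, 1L)
        if (nrow(intervals) == 0L ||
            all(pos + w - 1L < intervals[, 1L] - 1L |
                pos > intervals[, 2L] + 1L)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
      strand <- sample(c("+", "-"), 1L)
      realized <- realize_consensus(rows$consensus[[i]])
      inserted <- if (strand == "+") realized else revcomp(realized)
      substr(seq, pos, pos + w - 1L) <- inserted
      intervals <- rbind(intervals, c(pos, pos + w - 1L))
      planted[[i]] <- data.frame(motif = rows$name[[i]], position = pos,
                                 strand = strand, matched = inserted,
                                 stringsAsFactors = FALSE)
    }
    if (!ok) next
    planted <- do.call(rbind, planted)
    hits <- scan_cres(seq, catalog)
    if (nrow(hits) == 0L) next
    # every planted instance must be found, and every hit must lie fully
    # inside a planted interval (no junction or background artefacts)
    found <- paste(hits$motif, hits$position, hits$strand)
    want <- paste(planted$motif, planted$position, planted$strand)
    inside <- vapply(seq_len(nrow(hits)), function(j) {
      s <- hits$position[[j]]
      e <- s + nchar(hits$matched[[j]]) - 1L
      any(s >= intervals[, 1L] & e <= intervals[, 2L])
    }, TRUE)
    if (all(want %in% found) && all(inside)) {
      return(list(seq = seq, hits = hits))
    }
  }
  stop("could not plant promoter CREs cleanly after ", max_retry, " retries")
}

#' Simulate a genome with a planted gene family
#'
#' Generates reference subfamily proteins, family members derived from them
#' by amino-acid substitution (so they pass the 75/75 homology filter while
#' random decoys do not), two cross-subgenome collinear blocks (one inverted),
#' one tandem pair at the configured separation, intron structures drawn
#' mostly from 2-5 introns, and promoters with planted cis-regulatory
#' elements on a background scrubbed of chance matches.
#'
#' @param config Configuration from [default_config()] / [run_config()].
#' @param catalog CRE catalog (default: the one shipped with the package).
#' @return List: `genome` (named chromosome sequences), `genes` (gene model
#'   list), `proteins`, `cds` (members + decoys), `ref_proteins`, `ref_cds`,
#'   `ref_subfamily`, `truth`, `config`.
#' @export
simulate_genome <- function(config = default_config(),
                            catalog = read_cre_catalog()) {
  g <- config$genome
  nsub <- g$n_subfamilies
  if (g$n_family < nsub) {
    stop("family size ", g$n_family, " cannot cover ", nsub, " subfamilies")
  }
  bs <- g$block_size
  n_planted <- 4L * bs + 2L
  if (g$n_family < n_planted) {
    stop("family size must be >= ", n_planted,
         " to hold two blocks of ", bs, " plus a tandem pair")
  }
  if (g$refs_per_subfamily < 2L) stop("need >= 2 references per subfamily")
  if (length(g$chromosomes) < 4L) stop("need >= 4 chromosomes (A/C pairs)")
  set.seed(config$seed)
  prom_len <- config$promoter$length

  # --- reference set -------------------------------------------------------
  ref_ids <- as.vector(outer(seq_len(nsub), seq_len(g$refs_per_subfamily),
                             function(s, i) sprintf("NPF%d;%d", s, i)))
  ref_subfamily <- setNames(sprintf("NPF%d", rep(seq_len(nsub),
                                                 g$refs_per_subfamily)),
                            ref_ids)
  ref_len <- sample(g$ref_length_range[1L]:g$ref_length_range[2L],
                    length(ref_ids), replace = TRUE)
  ref_proteins <- setNames(vapply(ref_len, random_protein, ""), ref_ids)
  ref_cds <- setNames(vapply(ref_proteins, protein_to_cds, ""), ref_ids)

  # --- family member plan --------------------------------------------------
  chroms <- g$chromosomes[1:4]  # A-side pair then C-side pair
  block1_refs <- sprintf("NPF%d;1", seq_len(bs))
  block2_refs <- sprintf("NPF%d;2", (nsub - bs + 1L):nsub)
  tandem_ref <- sprintf("NPF%d;%d", min(4L, nsub), g$refs_per_subfamily)
  used <- c(block1_refs, block2_refs, tandem_ref)
  pool <- setdiff(ref_ids, used)
  n_ind <- g$n_family - n_planted
  if (n_ind > 2L * length(pool)) {
    stop("not enough unused references for ", n_ind, " independent members")
  }
  ind_refs <- rep(pool, length.out = n_ind)

  members <- list()
  add_member <- function(role, ref, prot, cds, chrom) {
    members[[length(members) + 1L]] <<- list(role = role, ref = ref,
                                             prot = prot, cds = cds,
                                             chrom = chrom)
  }
  for (i in seq_len(bs)) {
    r <- block1_refs[[i]]
    pa <- mutate_protein(ref_proteins[[r]], g$aa_substitution_rate)
    ca <- derive_cds(ref_cds[[r]], pa, g$syn_codon_swap_rate)
    pc <- mutate_protein(pa, g$copy_substitution_rate)
    cc <- derive_cds(ca, pc, g$copy_codon_swap_rate)
    add_member(sprintf("block1A.%d", i), r, pa, ca, chroms[1L])
    add_member(sprintf("block1C.%d", i), r, pc, cc, chroms[3L])
  }
  for (i in seq_len(bs)) {
    r <- block2_refs[[i]]
    pa <- mutate_protein(ref_proteins[[r]], g$aa_substitution_rate)
    ca <- derive_cds(ref_cds[[r]], pa, g$syn_codon_swap_rate)
    pc <- mutate_protein(pa, g$copy_substitution_rate)
    cc <- derive_cds(ca, pc, g$copy_codon_swap_rate)
    add_member(sprintf("block2A.%d", i), r, pa, ca, chroms[2L])
    add_member(sprintf("block2C.%d", i), r, pc, cc, chroms[4L])
  }
  p1 <- mutate_protein(ref_proteins[[tandem_ref]], g$aa_substitution_rate)
  c1 <- derive_cds(ref_cds[[tandem_ref]], p1, g$syn_codon_swap_rate)
  p2 <- mutate_protein(p1, g$copy_substitution_rate)
  c2 <- derive_cds(c1, p2, g$copy_codon_swap_rate)
  add_member("tandem.1", tandem_ref, p1, c1, chroms[1L])
  add_member("tandem.2", tandem_ref, p2, c2, chroms[1L])

  # independents: a reference used twice must keep its two members off one
  # chromosome (no false tandems) and off the planted block chromosome pairs
  # (A01,C01)/(A02,C02), so stray homolog pairs can never join a planted chain
  block_partner <- setNames(c(chroms[3L], chroms[4L], chroms[1L], chroms[2L]),
                            chroms)
  first_chrom <- character(0)
  for (j in seq_len(n_ind)) {
    r <- ind_refs[[j]]
    prot <- mutate_protein(ref_proteins[[r]], g$aa_substitution_rate)
    cds <- derive_cds(ref_cds[[r]], prot, g$syn_codon_swap_rate)
    if (is.na(first_chrom[r])) {
      chrom <- sample(chroms, 1L)
      first_chrom[r] <- chrom
    } else {
      allowed <- setdiff(chroms, c(first_chrom[[r]],
                                   block_partner[[first_chrom[[r]]]]))
      chrom <- sample(allowed, 1L)
    }
    add_member(sprintf("independent.%d", j), r, prot, cds, chrom)
  }

  # --- decoys --------------------------------------------------------------
  decoys <- list()
  for (j in seq_len(g$n_decoys)) {
    len <- sample(g$decoy_length_range[1L]:g$decoy_length_range[2L], 1L)
    prot <- random_protein(len)
    decoys[[j]] <- list(role = sprintf("decoy.%d", j), ref = NA_character_,
                        prot = prot, cds = protein_to_cds(prot),
                        chrom = sample(chroms, 1L))
  }

  # --- per-chromosome placement -------------------------------------------
  all_entries <- c(members, decoys)
  is_member <- c(rep(TRUE, length(members)), rep(FALSE, length(decoys)))
  roles <- vapply(all_entries, `[[`, "", "role")

  unit_of <- function(role) {
    if (grepl("^block1A", role)) "block1A"
    else if (grepl("^block1C", role)) "block1C"
    else if (grepl("^block2A", role)) "block2A"
    else if (grepl("^block2C", role)) "block2C"
    else if (grepl("^tandem", role)) "tandem"
    else role
  }

  chrom_layout <- list()
  for (ch in chroms) {
    on_ch <- which(vapply(all_entries, `[[`, "", "chrom") == ch)
    units <- split(on_ch, vapply(roles[on_ch], unit_of, ""))
    # order within planted units: block position order; tandem order 1,2;
    # block2C is laid down in reverse (inverted orientation)
    units <- lapply(names(units), function(u) {
      idx <- units[[u]]
      if (grepl("^block", u)) {
        pos <- as.integer(sub("^.*\\.", "", roles[idx]))
        idx <- idx[order(pos)]
        if (u == "block2C") idx <- rev(idx)
      } else if (u == "tandem") {
        idx <- idx[order(roles[idx])]
      }
      idx
    })
    chrom_layout[[ch]] <- units[sample.int(length(units))]
  }

  # --- build gene bodies and assemble chromosomes --------------------------
  genome <- character(0)
  genes <- list()
  truth_cres <- list()
  id_of_role <- character(0)

  for (ch in chroms) {
    pieces <- character(0)
    offset <- 0L
    gene_counter <- 0L
    prev_end <- NA_integer_
    units <- chrom_layout[[ch]]
    for (u in units) {
      for (pos_in_unit in seq_along(u)) {
        k <- u[[pos_in_unit]]
        entry <- all_entries[[k]]
        gene_counter <- gene_counter + 1L
        gid <- sprintf("%s%sg%03d", config$species_prefix, ch,
                       gene_counter * 10L)
        id_of_role[[entry$role]] <- gid

        tandem2 <- entry$role == "tandem.2"
        strand <- if (grepl("^tandem", entry$role)) "+" else {
          if (runif(1L) < g$minus_strand_prob) "-" else "+"
        }
        n_int <- choose_intron_count(g$intron_count_probs, nchar(entry$cds))
        body <- build_gene_body(entry$cds, n_int)

        if (is_member[[k]]) {
          pl <- plant_promoter(prom_len, catalog, g$cres_per_promoter)
          promoter <- pl$seq
          if (nrow(pl$hits) > 0L) {
            hits <- pl$hits
            hits$gene_id <- gid
            truth_cres[[length(truth_cres) + 1L]] <-
              hits[c("gene_id", "motif", "position", "strand", "matched")]
          }
        } else {
          promoter <- random_dna(prom_len)
        }

        cassette <- paste0(promoter, body$seq)
        Lc <- nchar(cassette)
        spacer <- if (tandem2) {
          g$tandem_gap_bp - prom_len - 1L
        } else {
          sample(g$spacer_range[1L]:g$spacer_range[2L], 1L)
        }
        if (spacer < 0L) stop("tandem gap smaller than promoter length + 1")
        pieces <- c(pieces, random_dna(spacer))
        offset <- offset + spacer

        if (strand == "+") {
          cas_seq <- cassette
          exons <- body$exons + prom_len + offset
          g_start <- offset + prom_len + 1L
          g_end <- offset + Lc
        } else {
          cas_seq <- revcomp(cassette)
          loc <- body$exons + prom_len
          exons <- cbind(Lc - loc[, 2L] + 1L, Lc - loc[, 1L] + 1L) + offset
          exons <- exons[order(exons[, 1L]), , drop = FALSE]
          g_start <- offset + 1L
          g_end <- offset + Lc - prom_len
        }
        pieces <- c(pieces, cas_seq)
        offset <- offset + Lc
        genes[[gid]] <- gene_model(gid, ch, strand, g_start, g_end,
                                   exons, exons)
        prev_end <- g_end
      }
    }
    tail_len <- sample(g$spacer_range[1L]:g$spacer_range[2L], 1L)
    pieces <- c(pieces, random_dna(tail_len))
    genome[[ch]] <- paste(pieces, collapse = "")
  }

  member_ids <- vapply(members, function(m) id_of_role[[m$role]], "")
  decoy_ids <- vapply(decoys, function(m) id_of_role[[m$role]], "")
  proteins <- setNames(c(vapply(members, `[[`, "", "prot"),
                         vapply(decoys, `[[`, "", "prot")),
                       c(member_ids, decoy_ids))
  cds <- setNames(c(vapply(members, `[[`, "", "cds"),
                    vapply(decoys, `[[`, "", "cds")),
                  c(member_ids, decoy_ids))

  block_truth <- lapply(list(list("block1A", "block1C", chroms[1L], chroms[3L],
                                  "same"),
                             list("block2A", "block2C", chroms[2L], chroms[4L],
                                  "inverted")),
                        function(b) {
    a_ids <- id_of_role[sprintf("%s.%d", b[[1L]], seq_len(bs))]
    b_ids <- id_of_role[sprintf("%s.%d", b[[2L]], seq_len(bs))]
    list(chrom_a = b[[3L]], chrom_b = b[[4L]], orientation = b[[5L]],
         gene_a = unname(a_ids), gene_b = unname(b_ids), size = bs)
  })

  truth <- list(
    seed = config$seed,
    species_prefix = config$species_prefix,
    family_members = data.frame(
      gene_id = member_ids,
      subfamily = unname(ref_subfamily[vapply(members, `[[`, "", "ref")]),
      reference = vapply(members, `[[`, "", "ref"),
      role = vapply(members, `[[`, "", "role"),
      stringsAsFactors = FALSE
    ),
    decoy_genes = unname(decoy_ids),
    planted_tandem_pairs = data.frame(
      gene_a = unname(id_of_role[["tandem.1"]]),
      gene_b = unname(id_of_role[["tandem.2"]]),
      separation_bp = g$tandem_gap_bp,
      stringsAsFactors = FALSE
    ),
    planted_collinear_blocks = block_truth,
    planted_cres = if (length(truth_cres) > 0L) {
      out <- do.call(rbind, truth_cres)
      rownames(out) <- NULL
      out
    } else NULL
  )

  tab <- gene_table(genes)
  genes <- genes[order(tab$chromosome, tab$start)]
  list(genome = genome, genes = genes, proteins = proteins, cds = cds,
       ref_proteins = ref_proteins, ref_cds = ref_cds,
       ref_subfamily = ref_subfamily, truth = truth, config = config)
}

#' Simulate the expression study
#'
#' Log-normal baseline FPKM with i.i.d. Gaussian noise on the log2 scale;
#' planted DEG sets shifted by the configured log2 effect per (tissue,
#' contrast); one universal responder planted in every set; a hub module
#' generated from a shared latent factor to hit the target Pearson r.
#'
#' @param truth Truth record from [simulate_genome()].
#' @param config Configuration.
#' @return List: `matrix` (FPKM, genes x samples), `samples` annotation, and
#'   `truth` augmented with `planted_deg_sets` and `planted_hub`.
#' @export
simulate_expression <- function(truth, config = default_config()) {
  e <- config$expression
  if (e$replicates < 2L) stop("need >= 2 replicates for DEG testing")
  set.seed(config$seed + 1L)
  gene_ids <- c(truth$family_members$gene_id, truth$decoy_genes)
  grid <- expand.grid(replicate = seq_len(e$replicates),
                      treatment = e$treatments, tissue = e$tissues,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste(grid$tissue, grid$treatment, grid$replicate, sep = "_"),
    tissue = grid$tissue, treatment = grid$treatment,
    replicate = grid$replicate, stringsAsFactors = FALSE
  )
  n_g <- length(gene_ids)
  n_s <- nrow(samples)
  logm <- matrix(rnorm(n_g, e$baseline_log2_mean, e$baseline_log2_sd),
                 nrow = n_g, ncol = n_s,
                 dimnames = list(gene_ids, samples$sample_id))

  members <- truth$family_members$gene_id
  decoy_ids <- truth$decoy_genes
  module_size <- min(e$hub_module_size, max(2L, length(members) %/% 3L))
  module <- sample(members, module_size)
  hub <- module[[1L]]
  universal <- sample(setdiff(members, module), 1L)
  pool <- setdiff(members, c(module, universal))

  # shared latent factor of the hub module: a replicate-linked biological
  # covariate, balanced within every (tissue, treatment) group so it cannot
  # shift group means (no false DEGs), with guaranteed spread in every
  # sample subset so the planted correlation always materializes
  latent <- sqrt(1.5) * (samples$replicate - 2) + 0.3 * rnorm(n_s)
  latent <- (latent - mean(latent)) / sqrt(mean((latent - mean(latent))^2))
  z <- matrix(0, nrow = module_size, ncol = n_s)
  z[1L, ] <- latent
  for (i in seq_len(module_size)[-1L]) {
    z[i, ] <- e$hub_r * latent + sqrt(1 - e$hub_r^2) * rnorm(n_s)
  }
  logm[module, ] <- logm[module, ] + e$latent_sd * z

  # DEG design: every (tissue, contrast) gets a set large enough for the
  # BH adjustment to be adaptive at n = 3 (the realistic regime where a
  # quarter of the genes respond to a nutrient stress). The nitrogen contrast feeds the CK/LN
  # coexpression network, so its responders are drawn from genes outside the
  # family (plus the strong universal responder) -- family-side nitrogen
  # signal stays confined to the planted hub module and the universal gene,
  # keeping the hub recoverable. The other contrasts freely recruit family
  # members since their samples never enter the network.
  contrasts <- setdiff(e$treatments, "CK")
  network_contrast <- setdiff(e$network_treatments, "CK")
  deg_sets <- list()
  for (ti in e$tissues) {
    for (co in contrasts) {
      if (co %in% network_contrast) {
        fam_up <- character(0)
        fam_dn <- character(0)
        n_dec_up <- 17L
        n_dec_dn <- 10L
      } else {
        n_fam_up <- min(6L, length(pool) %/% 2L)
        fam_up <- sample(pool, n_fam_up)
        fam_dn <- sample(setdiff(pool, fam_up),
                         min(3L, length(pool) - n_fam_up))
        n_dec_up <- 12L
        n_dec_dn <- 6L
      }
      # cap at the available decoy population (small test configs)
      n_dec_up <- min(n_dec_up, (length(decoy_ids) + 1L) %/% 2L)
      n_dec_dn <- min(n_dec_dn, length(decoy_ids) - n_dec_up)
      dec <- sample(decoy_ids, n_dec_up + n_dec_dn)
      deg_sets[[paste(ti, co, sep = ":")]] <- list(
        tissue = ti, contrast = co,
        up = c(universal, fam_up, dec[seq_len(n_dec_up)]),
        down = c(fam_dn, dec[-seq_len(n_dec_up)]),
        lfc = e$lfc
      )
    }
  }
  # only the universal responder may appear in every set
  in_all <- Reduce(intersect, lapply(deg_sets, function(s) c(s$up, s$down)))
  for (g in setdiff(in_all, universal)) {
    last <- names(deg_sets)[[length(deg_sets)]]
    deg_sets[[last]]$up <- setdiff(deg_sets[[last]]$up, g)
    deg_sets[[last]]$down <- setdiff(deg_sets[[last]]$down, g)
  }
  for (s in deg_sets) {
    cols <- samples$sample_id[samples$tissue == s$tissue &
                                samples$treatment == s$contrast]
    up2 <- setdiff(s$up, universal)
    logm[up2, cols] <- logm[up2, cols] + e$lfc
    logm[universal, cols] <- logm[universal, cols] + e$universal_lfc
    logm[s$down, cols] <- logm[s$down, cols] - e$lfc
  }
  logm <- logm + rnorm(n_g * n_s, 0, e$noise_sd)
  fpkm <- 2^logm

  truth$planted_deg_sets <- deg_sets
  truth$planted_hub <- list(gene = hub, module = module, r = e$hub_r,
                            universal_responder = universal)
  list(matrix = fpkm, samples = samples, truth = truth)
}

#' Extract all promoters of a simulated genome
#'
#' @param sim Output of [simulate_genome()].
#' @param config Configuration.
#' @return Named character vector of promoter sequences (family members and
#'   decoys).
#' @export
simulate_promoters <- function(sim, config = sim$config) {
  len <- config$promoter$length
  vapply(sim$genes, function(g) {
    extract_promoter(g, sim$genome, length = len)
  }, "")
}

#' Simulate a qPCR Ct table
#'
#' Ct values satisfy Ct_target = Ct_ref - log2(expression ratio) + offset +
#' noise, so the 2^-ddCt analysis recovers the planted fold changes exactly
#' at zero noise.
#'
#' @param truth Truth record.
#' @param config Configuration (`config$qpcr$noise_sd` sets the Ct noise).
#' @return List: `ct_table` (long data.frame incl. reference-gene rows) and
#'   `truth` augmented with `planted_fold_changes`.
#' @export
simulate_ct <- function(truth, config = default_config()) {
  q <- config$qpcr
  set.seed(config$seed + 3L)
  genes <- head(truth$family_members$gene_id, q$n_genes)
  cal_tissue <- q$tissues[[1L]]
  cal_treatment <- q$treatments[[1L]]
  conds <- expand.grid(treatment = q$treatments, tissue = q$tissues,
                       stringsAsFactors = FALSE)
  folds <- list()
  for (g in genes) {
    f <- sample(c(0.25, 0.5, 1, 2, 4, 8), nrow(conds), replace = TRUE)
    f[conds$tissue == cal_tissue & conds$treatment == cal_treatment] <- 1
    folds[[g]] <- f
  }
  rows <- list()
  for (ci in seq_len(nrow(conds))) {
    for (rep_i in seq_len(q$replicates)) {
      ct_ref <- 20 + rnorm(1L, 0, q$noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = q$reference_gene, tissue = conds$tissue[[ci]],
        treatment = conds$treatment[[ci]], replicate = rep_i, ct = ct_ref,
        stringsAsFactors = FALSE)
      for (g in genes) {
        offset <- 6  # constant target-vs-reference Ct offset
        ct <- ct_ref + offset - log2(folds[[g]][[ci]]) +
          rnorm(1L, 0, q$noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, tissue = conds$tissue[[ci]],
          treatment = conds$treatment[[ci]], replicate = rep_i, ct = ct,
          stringsAsFactors = FALSE)
      }
    }
  }
  ct_table <- do.call(rbind, rows)
  rownames(ct_table) <- NULL
  truth$planted_fold_changes <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g, tissue = conds$tissue,
               treatment = conds$treatment, fold = folds[[g]],
               stringsAsFactors = FALSE)
  }))
  truth$qpcr_calibrator <- c(cal_tissue, cal_treatment)
  list(ct_table = ct_table, truth = truth)
}

#' Generate and write a complete synthetic study
#'
#' Writes genome.fasta, genes.gff3, proteins.fasta, cds.fasta,
#' references.fasta (headers `<ref>|<subfamily>`), references_cds.fasta,
#' promoters.fasta, expression.tsv, ct.tsv and truth.json into `dir`.
#'
#' @param dir Output directory (created if missing).
#' @param config Configuration.
#' @return Invisibly, the full in-memory corpus (genome simulation,
#'   expression, promoters, Ct table, merged truth, file paths).
#' @export
simulate_corpus <- function(dir, config = default_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- read_cre_catalog()
  sim <- simulate_genome(config, catalog)
  expr <- simulate_expression(sim$truth, config)
  ct <- simulate_ct(expr$truth, config)
  truth <- ct$truth
  promoters <- simulate_promoters(sim, config)

  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    gff3 = file.path(dir, "genes.gff3"),
    proteins = file.path(dir, "proteins.fasta"),
    cds = file.path(dir, "cds.fasta"),
    references = file.path(dir, "references.fasta"),
    references_cds = file.path(dir, "references_cds.fasta"),
    promoters = file.path(dir, "promoters.fasta"),
    expression = file.path(dir, "expression.tsv"),
    ct = file.path(dir, "ct.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_fasta(sim$genome, paths$genome)
  write_gff3(sim$genes, paths$gff3)
  write_fasta(sim$proteins, paths$proteins)
  write_fasta(sim$cds, paths$cds)
  refs_labelled <- setNames(sim$ref_proteins,
                            paste0(names(sim$ref_proteins), "|",
                                   sim$ref_subfamily))
  write_fasta(refs_labelled, paths$references)
  write_fasta(sim$ref_cds, paths$references_cds)
  write_fasta(promoters, paths$promoters)
  write_expression_tsv(expr$matrix, paths$expression)
  write.table(ct$ct_table, paths$ct, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_truth(truth, paths$truth)
  invisible(list(sim = sim, expression = expr, ct = ct,
                 promoters = promoters, truth = truth, paths = paths))
}
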
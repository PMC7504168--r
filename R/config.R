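#' Default run configuration
#'
#' All tunable parameters of every pipeline stage, with their defaults.
#' Override individual entries with [run_config()]; unknown keys are rejected
#' so typos cannot silently fall back to defaults.
#'
#' Key defaults: homology filters strict \code{> 75} percent coverage-of-longer
#' and \code{> 75} percent similarity; tandem window 200 kb; collinear blocks
#' of at least 5 pairs with rank gap at most 10; DEG thresholds
#' \code{|log2FC| >= 1} and BH FDR \code{< 0.05}; coexpression edge cutoff
#' \code{|r| > 0.6}; promoter length 2,000 bp; Kyte-Doolittle TMD window 19 at
#' cutoff 1.6; 1000 bootstrap replicates.
#'
#' @return Nested named list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 20200815L,
    species_prefix = "Syn",
    genome = list(
      chromosomes = c("A01", "A02", "C01", "C02"),
      n_family = 40L,
      n_decoys = 60L,
      n_subfamilies = 8L,
      refs_per_subfamily = 3L,
      ref_length_range = c(400L, 500L),
      decoy_length_range = c(250L, 550L),
      aa_substitution_rate = 0.15,
      copy_substitution_rate = 0.03,
      syn_codon_swap_rate = 0.30,
      copy_codon_swap_rate = 0.05,
      intron_count_probs = c("1" = 0.05, "2" = 0.20, "3" = 0.456,
                             "4" = 0.18, "5" = 0.094, "6" = 0.02),
      tandem_gap_bp = 6500L,
      block_size = 5L,
      spacer_range = c(500L, 2000L),
      minus_strand_prob = 0.4,
      cres_per_promoter = c(2L, 6L)
    ),
    family = list(
      min_coverage = 75,
      min_similarity = 75,
      gap_open = 10,
      gap_extend = 0.5
    ),
    protein = list(
      tmd_window = 19L,
      tmd_threshold = 1.6
    ),
    tree = list(
      bootstrap_reps = 1000L
    ),
    duplication = list(
      tandem_window = 200000L,
      min_block = 5L,
      max_gap = 10L
    ),
    expression = list(
      tissues = c("leaf", "root"),
      treatments = c("CK", "LN", "LP", "LK", "NH4"),
      replicates = 3L,
      baseline_log2_mean = 6,
      baseline_log2_sd = 1.2,
      noise_sd = 0.25,
      lfc = 2,
      universal_lfc = 4,
      hub_module_size = 12L,
      hub_r = 0.85,
      latent_sd = 1.0,
      lfc_min = 1,
      fdr_max = 0.05,
      pseudocount = 1,
      network_treatments = c("CK", "LN"),
      network_cutoff = 0.6,
      n_hubs = 10L
    ),
    promoter = list(
      length = 2000L,
      both_strands = TRUE
    ),
    qpcr = list(
      n_genes = 3L,
      tissues = c("root", "hypocotyl", "basal_node", "petiole",
                  "expanded_leaf", "new_leaf"),
      treatments = c("CK", "LN"),
      replicates = 3L,
      noise_sd = 0.2,
      reference_gene = "EF1a"
    )
  )
}

#' Build a run configuration from overrides
#'
#' @param ... Named overrides, nested as in [default_config()], e.g.
#'   \code{run_config(genome = list(n_family = 16))}. Unnamed or unknown keys
#'   raise an error.
#' @return Full configuration list with overrides applied.
#' @export
run_config <- function(...) {
  overrides <- list(...)
  merge_config(default_config(), overrides, path = "")
}

merge_config <- function(base, overrides, path) {
  if (length(overrides) == 0L) return(base)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == "")) {
    stop("configuration overrides must be named (at ", path, ")")
  }
  unknown <- setdiff(nm, names(base))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in nm) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(overrides[[k]])) {
        stop("configuration key ", path, k, " must be a named list")
      }
      base[[k]] <- merge_config(base[[k]], overrides[[k]],
                                path = paste0(path, k, "$"))
    } else {
      base[[k]] <- overrides[[k]]
    }
  }
  base
}

#' Echo the parameters of a stage to the log
#'
#' Every threshold in the configuration subtree is printed via [message()] so
#' published-style counts are auditable from the run log.
#'
#' @param stage Stage name used as the log prefix.
#' @param params Named list (possibly nested) of parameters.
#' @export
log_params <- function(stage, params) {
  flat <- flatten_params(params)
  for (k in names(flat)) {
    message(sprintf("[%s] %s = %s", stage, k, flat[[k]]))
  }
  invisible(flat)
}

flatten_params <- function(x, prefix = "") {
  out <- list()
  for (k in names(x)) {
    key <- paste0(prefix, k)
    if (is.list(x[[k]])) {
      out <- c(out, flatten_params(x[[k]], paste0(key, ".")))
    } else {
      out[[key]] <- paste(x[[k]], collapse = ",")
    }
  }
  out
}
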
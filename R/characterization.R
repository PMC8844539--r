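#' Assemble the membrane proteome from replicated identifications
#'
#' Combines per-replicate identifications from whole-cell-lysate and
#' cell-surface proteomics: sources are unioned within each replicate, and a
#' protein is kept when seen in at least `min_replicates` distinct
#' biological replicates (either source counts), then intersected with the
#' membrane cellular-component class.
#'
#' @param identifications `data.frame` with columns `protein_id`, `source`
#'   (`"LYSATE"` or `"SURFACE"`) and `replicate` (integer).
#' @param ann An [annotation_table()].
#' @param min_replicates Minimum number of distinct replicates (default 2).
#'
#' @return A list of class `membrane_proteome` with `protein_ids`
#'   (character) and `evidence` (the per-protein replicate counts).
#' @export
assemble_membrane_proteome <- function(identifications, ann,
                                       min_replicates = 2L) {
  stopifnot(all(c("protein_id", "source", "replicate") %in%
                  names(identifications)))
  if (!all(identifications$source %in% c("LYSATE", "SURFACE")))
    stop("source must be LYSATE or SURFACE")
  n_rep <- length(unique(identifications$replicate))
  if (min_replicates > n_rep)
    stop("min_replicates (", min_replicates,
         ") exceeds available replicates (", n_rep, ")")
  ev <- unique(identifications[, c("protein_id", "replicate")])
  counts <- table(ev$protein_id)
  enough <- names(counts)[counts >= min_replicates]
  mem <- ann$protein_id[ann$cc_class == "MEMBRANE"]
  ids <- sort(intersect(enough, mem))
  structure(list(protein_ids = ids,
                 evidence = data.frame(protein_id = names(counts),
                                       n_replicates = as.integer(counts),
                                       stringsAsFactors = FALSE)),
            class = "membrane_proteome")
}

#' Counter-receptor fraction of the membrane proteome
#'
#' The percentage of the membrane proteome made up by the counter-receptor
#' set, reported to one decimal place. Counter-receptors absent from the
#' proteome are excluded from the numerator and reported via the
#' `outside_proteome` attribute.
#'
#' @param cr_set Character vector of counter-receptor protein ids.
#' @param proteome A [assemble_membrane_proteome()] result, or a character
#'   vector of protein ids.
#' @return Percentage in \[0, 100\], rounded to one decimal.
#' @export
counter_receptor_fraction <- function(cr_set, proteome) {
  ids <- if (inherits(proteome, "membrane_proteome")) proteome$protein_ids
         else as.character(proteome)
  if (length(ids) == 0L) stop("membrane proteome is empty: fraction undefined")
  violators <- setdiff(cr_set, ids)
  frac <- round(100 * length(intersect(cr_set, ids)) / length(ids), 1)
  attr(frac, "outside_proteome") <- violators
  frac
}

#' Histone-ruler configuration
#'
#' Constants for proteomic-ruler copy-number estimation. The ruler assumes
#' total histone mass per cell approximates DNA mass per cell; the default
#' 5.9 pg corresponds to a diploid mouse genome.
#'
#' @param dna_mass_per_cell DNA mass per cell in grams (default 5.9e-12).
#' @param histone_ids Character vector of histone protein accessions.
#' @param avogadro Avogadro constant (per mol).
#' @return A list of class `ruler_config`.
#' @export
ruler_config <- function(dna_mass_per_cell = 5.9e-12, histone_ids,
                         avogadro = 6.02214076e23) {
  stopifnot(dna_mass_per_cell > 0, length(histone_ids) >= 1)
  structure(list(dna_mass_per_cell = dna_mass_per_cell,
                 histone_ids = as.character(histone_ids),
                 avogadro = avogadro),
            class = "ruler_config")
}

#' Protein copy numbers per cell via the histone ruler
#'
#' Scales each protein's MS intensity by the summed histone intensity:
#' `copies_i = (I_i / sum_h I_h) * dna_mass_per_cell * N_A / MW_i`, with the
#' molecular weight in g/mol. Proteins lacking a molecular weight are
#' skipped and counted in the `n_skipped_no_mw` attribute.
#'
#' @param quant A [quant_table()] whose `proteins` carry `mw_kda`.
#' @param sample_id Sample (column) to score.
#' @param cfg A [ruler_config()].
#' @return Named numeric vector of copies per cell (missing intensities
#'   scored as 0 copies).
#' @export
histone_ruler_copies <- function(quant, sample_id, cfg) {
  if (!sample_id %in% colnames(quant$intensities))
    stop("sample ", sample_id, " not in quant table")
  I <- quant$intensities[, sample_id]
  I[is.na(I)] <- 0
  h_idx <- quant$proteins$protein_id %in% cfg$histone_ids
  if (!any(h_idx & I > 0))
    stop("no histone quantified in sample ", sample_id)
  h_total <- sum(I[h_idx])
  if (h_total <= 0) stop("zero total histone intensity in sample ", sample_id)
  mw <- quant$proteins$mw_kda
  if (is.null(mw)) stop("quant table has no molecular weights (mw_kda)")
  has_mw <- !is.na(mw) & mw > 0
  copies <- (I[has_mw] / h_total) * cfg$dna_mass_per_cell * cfg$avogadro /
    (mw[has_mw] * 1000)
  names(copies) <- quant$proteins$protein_id[has_mw]
  attr(copies, "n_skipped_no_mw") <- sum(!has_mw)
  if (any(!has_mw))
    warning(sum(!has_mw), " protein(s) skipped: no molecular weight")
  copies
}

#' Find N-glycosylation sequons in a protein sequence
#'
#' Scans for the N-X-S/T motif with X != P (1-based position of the N).
#' Overlapping sequons are all reported. Sequences shorter than 3 residues
#' yield an empty result.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet plus X.
#' @return Integer vector of 1-based sequon start positions.
#' @export
find_sequons <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  if (n < 3L) return(integer(0))
  ok <- s[1:(n - 2)] == "N" & s[2:(n - 1)] != "P" & s[3:n] %in% c("S", "T")
  which(ok)
}

#' Compare sequon density per Ig-like domain between groups
#'
#' For Ig-superfamily proteins, the density is the number of predicted
#' N-glycosylation sequons per Ig-like domain. The summary reports, per
#' group, the size, median density, and the split at one site per domain
#' (strictly above 1 vs at most 1). Proteins with zero Ig-like domains must
#' be excluded upstream.
#'
#' @param rows `data.frame` with columns `protein_id`, `n_sequons`,
#'   `n_ig_domains` (all >= 1) and `group` (`"COUNTER_RECEPTOR"` or
#'   `"OTHER"`).
#' @return A `data.frame` with one row per group: `group`, `n`,
#'   `median_density`, `n_gt1`, `n_le1`, `present`.
#' @export
sequon_density_comparison <- function(rows) {
  if (nrow(rows) == 0L) stop("no rows to summarize")
  if (any(rows$n_ig_domains < 1))
    stop("rows with n_ig_domains = 0 must be excluded upstream")
  rows$density <- rows$n_sequons / rows$n_ig_domains
  groups <- c("COUNTER_RECEPTOR", "OTHER")
  out <- do.call(rbind, lapply(groups, function(g) {
    d <- rows$density[rows$group == g]
    data.frame(group = g, n = length(d),
               median_density = if (length(d)) stats::median(d) else NA_real_,
               n_gt1 = sum(d > 1), n_le1 = sum(d <= 1),
               present = length(d) > 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Map counter-receptors onto an abundance histogram
#'
#' Bins proteins with abundance strictly above `threshold` into `n_bins`
#' log10-spaced bins and flags the bin of every counter-receptor, mirroring
#' abundance-distribution plots where each counter-receptor is a marked
#' point on the histogram of membrane-glycoprotein abundances (e.g.
#' normalized mRNA counts above 100, or ruler copy numbers).
#'
#' @param cr_set Character vector of counter-receptor ids.
#' @param abundance Named numeric vector of positive abundances.
#' @param threshold Strict lower abundance bound (default 100).
#' @param n_bins Number of log10-spaced bins (default 30).
#' @return A list of class `abundance_histogram`: `breaks_log10`, `counts`,
#'   `cr_counts` (counter-receptors per bin), `bin_of` (per-protein bin
#'   index), `n_used`.
#' @export
map_to_abundance <- function(cr_set, abundance, threshold = 100,
                             n_bins = 30L) {
  stopifnot(all(abundance > 0))
  keep <- abundance > threshold
  a <- abundance[keep]
  if (length(a) == 0L)
    return(structure(list(breaks_log10 = numeric(0), counts = integer(0),
                          cr_counts = integer(0), bin_of = integer(0),
                          n_used = 0L), class = "abundance_histogram"))
  lo <- log10(min(a)); hi <- log10(max(a))
  if (hi == lo) hi <- lo + 1e-9   # all equal: single occupied bin
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(log10(a), breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  is_cr <- names(a) %in% cr_set
  cr_counts <- tabulate(bin[is_cr], nbins = n_bins)
  structure(list(breaks_log10 = breaks, counts = counts,
                 cr_counts = cr_counts,
                 bin_of = stats::setNames(bin, names(a)),
                 n_used = length(a)),
            class = "abundance_histogram")
}

#' Summarize a glycogene panel from normalized count matrices
#'
#' For each panel gene present in both condition matrices: the mean
#' normalized count per condition, `log2((mean_act + c) / (mean_rest + c))`
#' with pseudocount `c = 1`, a two-sample Student t p value across replicate
#' columns, and Benjamini-Hochberg q values computed over the panel only.
#' This is a panel summary over already-normalized counts, not a
#' differential-expression engine.
#'
#' @param counts_rest,counts_activated Numeric matrices (genes x replicate
#'   columns, >= 2 columns each) of normalized counts, with gene row names.
#' @param panel Character vector of panel gene names.
#' @param pseudocount Added to both means before the ratio (default 1).
#' @return A `data.frame` with columns `gene`, `mean_rest`,
#'   `mean_activated`, `log2fc`, `p_value`, `q_value`; panel genes absent
#'   from either matrix are listed in the `misses` attribute.
#' @export
glycogene_panel_report <- function(counts_rest, counts_activated, panel,
                                   pseudocount = 1) {
  stopifnot(ncol(counts_rest) >= 2, ncol(counts_activated) >= 2)
  found <- panel[panel %in% rownames(counts_rest) &
                   panel %in% rownames(counts_activated)]
  misses <- setdiff(panel, found)
  res <- do.call(rbind, lapply(found, function(g) {
    r <- counts_rest[g, ]; a <- counts_activated[g, ]
    p <- if (stats::sd(r) == 0 && stats::sd(a) == 0) {
      if (mean(a) == mean(r)) 1 else .Machine$double.xmin
    } else {
      stats::t.test(a, r, var.equal = TRUE)$p.value
    }
    data.frame(gene = g, mean_rest = mean(r), mean_activated = mean(a),
               log2fc = log2((mean(a) + pseudocount) /
                               (mean(r) + pseudocount)),
               p_value = p, stringsAsFactors = FALSE)
  }))
  if (is.null(res)) res <- data.frame(gene = character(0),
                                      mean_rest = numeric(0),
                                      mean_activated = numeric(0),
                                      log2fc = numeric(0),
                                      p_value = numeric(0))
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  attr(res, "misses") <- misses
  res
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()`, returning plain named
#' character sequences for sequon scanning.
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}
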
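# Shared in-code fixtures and independent brute-force oracles.

toy_design <- function(n_datasets = 2L) {
  ds <- paste0("DS", seq_len(n_datasets))
  sample_design(
    sample_id = as.vector(rbind(paste0(ds, "_b"), paste0(ds, "_c"))),
    dataset_id = rep(ds, each = 2),
    bait = rep(c("ACTIVE_SN", "CONTROL_R97A"), n_datasets),
    multimer = rep("IN_SOLUTION", 2 * n_datasets),
    replicate = rep(seq_len(n_datasets), each = 2))
}

toy_quant <- function(intensities, ids = NULL, mw = NULL) {
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(nrow(intensities)))
  proteins <- data.frame(protein_id = ids, gene_name = ids,
                         stringsAsFactors = FALSE)
  if (!is.null(mw)) proteins$mw_kda <- mw
  quant_table(proteins, intensities)
}

toy_annotation <- function(ids, cc_class = "MEMBRANE",
                           plasma_membrane = TRUE, n_sequons = 2L,
                           n_ig_domains = 1L) {
  annotation_table(data.frame(
    protein_id = ids,
    cc_class = rep_len(cc_class, length(ids)),
    plasma_membrane = rep_len(plasma_membrane, length(ids)),
    n_sequons = rep_len(as.integer(n_sequons), length(ids)),
    n_ig_domains = rep_len(as.integer(n_ig_domains), length(ids)),
    stringsAsFactors = FALSE))
}

# Exact hypergeometric upper-tail probability by explicit combinatorial
# summation over the support (independent of stats::phyper).
hyper_tail_bruteforce <- function(x_min, n_mem, n_tot, k) {
  supp <- max(0, k - (n_tot - n_mem)):min(k, n_mem)
  supp <- supp[supp >= x_min]
  sum(choose(n_mem, supp) * choose(n_tot - n_mem, k - supp)) /
    choose(n_tot, k)
}

# Regular-expression-free sequon scan by explicit triple loop.
sequon_bruteforce <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  hits <- integer(0)
  if (length(s) < 3) return(hits)
  for (i in 1:(length(s) - 2)) {
    if (s[i] == "N" && s[i + 1] != "P" && (s[i + 2] == "S" || s[i + 2] == "T"))
      hits <- c(hits, i)
  }
  hits
}

random_aa <- function(n, alphabet = c(LETTERS[!LETTERS %in%
                                                c("B", "J", "O", "U", "Z")])) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
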
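#' Simulation configuration for synthetic proximity-labelling experiments
#'
#' Defaults emulate the study design the pipeline targets: three biological
#' replicates with two multimer formats (six bait/control datasets), a
#' membrane fraction of 30% among ~2000 quantified proteins, 50 spiked
#' counter-receptors with log2 enrichment effects around 2.5, and
#' intensity-dependent (MNAR) missingness as is characteristic of LFQ data.
#'
#' @param n_proteins Number of simulated proteins (default 2000).
#' @param membrane_fraction Fraction annotated as membrane (default 0.3).
#' @param n_spiked Number of spiked counter-receptors (default 50); must
#'   not exceed the membrane pool.
#' @param spike_log2_mean,spike_log2_sd Mean and sd of per-protein spike
#'   effects in log2 units (default 2.5, 0.5), truncated at >= 0.5.
#' @param replicate_sd Per-sample log2 intensity noise sd (default 0.6);
#'   applied independently to bait and control samples.
#' @param baseline_log10_mean,baseline_log10_sd Log10-intensity
#'   distribution across proteins (default 6.5, 0.8).
#' @param missing_rate_base Overall target missingness rate (default 0.1).
#' @param mnar_quantile Intensity quantile below which missingness
#'   probability rises (default 0.2).
#' @param n_replicates Biological replicates per multimer format
#'   (default 3).
#' @param multimer_formats Formats simulated (default both).
#' @param degrade_datasets Dataset ids whose spike effects are zeroed
#'   (exercises the dataset-exclusion stage; default none).
#' @param sticky_fraction Fraction of cytoplasmic proteins given a small
#'   off-target positive effect (default 0; stresses the annotation
#'   filter).
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 2000L, membrane_fraction = 0.3,
                       n_spiked = 50L, spike_log2_mean = 2.5,
                       spike_log2_sd = 0.5, replicate_sd = 0.6,
                       baseline_log10_mean = 6.5, baseline_log10_sd = 0.8,
                       missing_rate_base = 0.1, mnar_quantile = 0.2,
                       n_replicates = 3L,
                       multimer_formats = c("IN_SOLUTION", "ON_BEAD"),
                       degrade_datasets = character(0),
                       sticky_fraction = 0, seed = 1L) {
  stopifnot(membrane_fraction > 0, membrane_fraction <= 1,
            missing_rate_base >= 0, missing_rate_base <= 1,
            mnar_quantile >= 0, mnar_quantile < 1,
            n_replicates >= 1,
            all(multimer_formats %in% c("IN_SOLUTION", "ON_BEAD")))
  if (n_spiked > floor(n_proteins * membrane_fraction))
    stop("n_spiked exceeds the membrane protein pool")
  structure(as.list(environment()), class = "sim_config")
}

# MNAR missingness: zero dropout above the mnar_quantile of the pooled
# log-intensity ranks, rising linearly to p_max at the lowest intensity.
# p_max is set so the expected overall missingness (q * p_max / 2) equals
# missing_rate_base, mirroring LFQ data where dropout is confined to
# signals near the detection limit. mnar_quantile = 0 degrades to MCAR.
mnar_miss_prob <- function(u, base, q) {
  if (base == 0) return(rep(0, length(u)))
  if (q == 0) return(rep(base, length(u)))
  p_max <- min(1, 2 * base / q)
  ifelse(u >= q, 0, (q - u) / q * p_max)
}

#' Generate a synthetic proximity-labelling experiment with known truth
#'
#' Simulates per-protein baseline abundances (log-normal across proteins),
#' bait and control intensities per dataset (bait = control-side baseline
#' times `2^effect` for spiked proteins, with independent per-sample
#' `2^Normal(0, replicate_sd)` noise on both samples), MNAR missingness,
#' and a matching annotation table. Spiked proteins are membrane-class,
#' plasma-membrane, and carry at least one sequon, so they are recoverable
#' by the full pipeline. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `synthetic_experiment` with elements `quant`
#'   ([quant_table()]), `design` ([sample_design()]), `annotation`
#'   ([annotation_table()]), and `truth` (list: `spiked_ids`, `effects`,
#'   `config`, `seed`).
#' @export
generate_experiment <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_proteins
  ids <- sprintf("P%05d", seq_len(n))
  genes <- sprintf("Gene%05d", seq_len(n))
  mw <- round(10^stats::rnorm(n, log10(50), 0.25), 1)

  n_mem <- floor(n * cfg$membrane_fraction)
  cc <- c(rep("MEMBRANE", n_mem),
          sample(c("CYTOPLASM", "NUCLEUS", "OTHER"), n - n_mem,
                 replace = TRUE))
  cc <- sample(cc)
  is_mem <- cc == "MEMBRANE"
  pm <- is_mem & stats::runif(n) < 0.7
  n_seq <- ifelse(is_mem, stats::rpois(n, 3), stats::rpois(n, 0.5))
  n_ig <- ifelse(is_mem, stats::rpois(n, 0.8), 0L)

  spiked <- sort(sample(which(is_mem), cfg$n_spiked))
  pm[spiked] <- TRUE
  n_seq[spiked] <- pmax(n_seq[spiked], 1L)

  effects <- numeric(0)
  if (cfg$n_spiked > 0) {
    effects <- stats::rnorm(cfg$n_spiked, cfg$spike_log2_mean,
                            cfg$spike_log2_sd)
    while (any(effects < 0.5))   # truncated at 0.5 by rejection
      effects[effects < 0.5] <- stats::rnorm(sum(effects < 0.5),
                                             cfg$spike_log2_mean,
                                             cfg$spike_log2_sd)
  }
  effect_vec <- numeric(n)
  effect_vec[spiked] <- effects

  sticky <- integer(0)
  if (cfg$sticky_fraction > 0) {
    cyto <- which(cc == "CYTOPLASM")
    sticky <- sample(cyto, floor(length(cyto) * cfg$sticky_fraction))
    effect_vec[sticky] <- abs(stats::rnorm(length(sticky), 0.8, 0.3))
  }

  baseline <- 10^stats::rnorm(n, cfg$baseline_log10_mean,
                              cfg$baseline_log10_sd)

  datasets <- character(0); fmt_of <- character(0); rep_of <- integer(0)
  for (f in cfg$multimer_formats) for (r in seq_len(cfg$n_replicates)) {
    datasets <- c(datasets, paste0(substr(f, 1, 6), "_R", r))
    fmt_of <- c(fmt_of, f); rep_of <- c(rep_of, r)
  }

  intens <- matrix(NA_real_, n, 2 * length(datasets))
  sample_ids <- character(2 * length(datasets))
  for (i in seq_along(datasets)) {
    eff <- effect_vec
    if (datasets[i] %in% cfg$degrade_datasets) eff <- numeric(n)
    ctrl <- baseline * 2^stats::rnorm(n, 0, cfg$replicate_sd)
    bait <- baseline * 2^eff * 2^stats::rnorm(n, 0, cfg$replicate_sd)
    intens[, 2 * i - 1] <- bait
    intens[, 2 * i] <- ctrl
    sample_ids[2 * i - 1] <- paste0(datasets[i], "_bait")
    sample_ids[2 * i] <- paste0(datasets[i], "_ctrl")
  }
  colnames(intens) <- sample_ids

  if (cfg$missing_rate_base > 0) {
    u <- matrix(rank(log10(intens)) / length(intens), nrow = n)
    pmiss <- mnar_miss_prob(u, cfg$missing_rate_base, cfg$mnar_quantile)
    drop <- matrix(stats::runif(length(intens)) < pmiss, nrow = n)
    intens[drop] <- NA_real_
  }

  design <- sample_design(
    sample_id = sample_ids,
    dataset_id = rep(datasets, each = 2),
    bait = rep(c("ACTIVE_SN", "CONTROL_R97A"), length(datasets)),
    multimer = rep(fmt_of, each = 2),
    replicate = rep(rep_of, each = 2))

  quant <- quant_table(
    data.frame(protein_id = ids, gene_name = genes, mw_kda = mw,
               stringsAsFactors = FALSE),
    intens)

  ann <- annotation_table(data.frame(
    protein_id = ids, cc_class = cc, plasma_membrane = pm,
    n_sequons = as.integer(n_seq), n_ig_domains = as.integer(n_ig),
    stringsAsFactors = FALSE))

  truth <- list(spiked_ids = ids[spiked],
                effects = stats::setNames(effects, ids[spiked]),
                sticky_ids = ids[sticky],
                config = unclass(cfg), seed = cfg$seed)

  structure(list(quant = quant, design = design, annotation = ann,
                 truth = truth),
            class = "synthetic_experiment")
}

#' Write a synthetic experiment to disk
#'
#' Emits the same TSV formats the readers consume (quant table, annotation
#' table) plus the ground truth as JSON, so a generator-written experiment
#' round-trips through [read_quant_table()] / [read_annotation_table()].
#'
#' @param exp_ A [generate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_experiment <- function(exp_, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qp <- file.path(dir, "quant.tsv")
  ap <- file.path(dir, "annotation.tsv")
  dp <- file.path(dir, "design.tsv")
  tp <- file.path(dir, "truth.json")
  write_quant_table(exp_$quant, qp)
  utils::write.table(as.data.frame(exp_$annotation), ap, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(exp_$design), dp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_report(list(spiked_ids = exp_$truth$spiked_ids,
                    effects = as.list(exp_$truth$effects),
                    seed = exp_$truth$seed), tp)
  invisible(c(quant = qp, annotation = ap, design = dp, truth = tp))
}

#' Read a sample design table from TSV
#'
#' @param path Path to a TSV with the columns of [sample_design()].
#' @return A [sample_design()].
#' @export
read_sample_design <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  sample_design(d$sample_id, d$dataset_id, d$bait, d$multimer, d$replicate)
}

#' Perturb annotation records to stress the annotation filter
#'
#' Flips the plasma-membrane flag or zeroes the sequon count for a random
#' `flip_rate` fraction of proteins. Spiked (protected) proteins are left
#' untouched by default, so pipeline sensitivity should be unaffected.
#'
#' @param ann An [annotation_table()].
#' @param flip_rate Fraction perturbed, in \[0, 0.5).
#' @param seed Integer RNG seed.
#' @param protect_ids Protein ids never perturbed (default none).
#' @return A perturbed [annotation_table()].
#' @export
generate_annotation_noise <- function(ann, flip_rate, seed,
                                      protect_ids = character(0)) {
  stopifnot(flip_rate >= 0, flip_rate < 0.5)
  if (flip_rate == 0) return(ann)
  set.seed(seed)
  df <- as.data.frame(ann)
  eligible <- which(!df$protein_id %in% protect_ids)
  hit <- eligible[stats::runif(length(eligible)) < flip_rate]
  mode <- sample(c("pm", "seq"), length(hit), replace = TRUE)
  pm_hit <- hit[mode == "pm"]
  # flipping FALSE -> TRUE must keep the class invariant (PM implies MEMBRANE)
  df$plasma_membrane[pm_hit] <- !df$plasma_membrane[pm_hit]
  df$cc_class[pm_hit][df$plasma_membrane[pm_hit]] <- "MEMBRANE"
  df$n_sequons[hit[mode == "seq"]] <- 0L
  out <- annotation_table(df)
  attr(out, "n_flipped") <- length(hit)
  out
}

#' Generate a synthetic MALDI peak list from known compositions
#'
#' One peak per composition at its theoretical permethylated \[M+Na\]+ m/z
#' plus Gaussian mass jitter, with optional uniform-random noise peaks.
#'
#' @param compositions List of compositions (objects or strings).
#' @param abundances Positive peak intensities, one per composition.
#' @param mass_error_sd_da Gaussian m/z jitter sd in Da (default 0).
#' @param n_noise_peaks Number of uniform noise peaks (default 0).
#' @param seed Integer RNG seed.
#' @param mz_range Range for noise-peak m/z (default spans the signal
#'   peaks, widened by 100 Da each side).
#' @param noise_intensity_max Upper bound of uniform noise intensities
#'   (default 10% of the smallest signal abundance).
#' @param condition_label Spectrum label.
#' @return A [peak_list()].
#' @export
generate_spectrum <- function(compositions, abundances,
                              mass_error_sd_da = 0, n_noise_peaks = 0L,
                              seed = 1L, mz_range = NULL,
                              noise_intensity_max = NULL,
                              condition_label = "synthetic") {
  stopifnot(length(compositions) == length(abundances),
            all(abundances > 0))
  set.seed(seed)
  theo <- vapply(lapply(compositions, as_composition),
                 permethylated_mz, numeric(1))
  mz <- theo + stats::rnorm(length(theo), 0, mass_error_sd_da)
  intensity <- abundances
  if (n_noise_peaks > 0) {
    if (is.null(mz_range)) mz_range <- range(theo) + c(-100, 100)
    if (is.null(noise_intensity_max))
      noise_intensity_max <- 0.1 * min(abundances)
    mz <- c(mz, stats::runif(n_noise_peaks, mz_range[1], mz_range[2]))
    intensity <- c(intensity,
                   stats::runif(n_noise_peaks, 0, noise_intensity_max))
  }
  peak_list(mz, intensity, condition_label)
}
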
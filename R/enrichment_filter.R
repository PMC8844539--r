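#' Pipeline configuration for counter-receptor filtration
#'
#' Collects the thresholds of the four-stage filtration. The tail criterion
#' operationalises the visual "proximity labelling tail" call: a dataset is
#' retained when at least `k_min` membrane proteins exceed the
#' `tail_quantile` quantile of the non-membrane log2 fold-change
#' distribution and their excess is hypergeometrically significant at
#' `p_tail`. Significance selection defaults to raw paired-t p values below
#' `alpha` with mean log2 fold change above `min_log2fc`; set
#' `use_adjusted_p = TRUE` to select on Benjamini-Hochberg q values instead.
#'
#' @param noise_floor_quantile Quantile of a sample's quantified intensities
#'   used as the imputation value for missing intensities (default 0.01,
#'   i.e. the 1st percentile).
#' @param tail_quantile Quantile of the non-membrane log2FC distribution
#'   defining the per-dataset tail cutoff (default 0.99).
#' @param k_min Minimum number of membrane proteins above the cutoff for a
#'   tail call (default 20).
#' @param p_tail Hypergeometric significance threshold for the tail call
#'   (default 0.01).
#' @param alpha Significance threshold for volcano selection (default 0.05).
#' @param min_log2fc Minimum mean log2 fold change for selection
#'   (default 1.0); selection is on the enrichment side only.
#' @param use_adjusted_p Select on BH-adjusted q values instead of raw p
#'   values (default `FALSE`).
#' @param backmap_min_in_tail Minimum number of retained datasets in which a
#'   candidate must lie inside the tail. The default `NULL` means "all
#'   retained datasets in which the protein was observed".
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(noise_floor_quantile = 0.01,
                            tail_quantile = 0.99,
                            k_min = 20L,
                            p_tail = 0.01,
                            alpha = 0.05,
                            min_log2fc = 1.0,
                            use_adjusted_p = FALSE,
                            backmap_min_in_tail = NULL) {
  stopifnot(noise_floor_quantile > 0, noise_floor_quantile < 1,
            tail_quantile > 0, tail_quantile < 1,
            p_tail > 0, p_tail < 1, alpha > 0, alpha < 1,
            min_log2fc >= 0, k_min >= 1)
  structure(list(noise_floor_quantile = noise_floor_quantile,
                 tail_quantile = tail_quantile,
                 k_min = as.integer(k_min),
                 p_tail = p_tail,
                 alpha = alpha,
                 min_log2fc = min_log2fc,
                 use_adjusted_p = isTRUE(use_adjusted_p),
                 backmap_min_in_tail = backmap_min_in_tail),
            class = "pipeline_config")
}

#' Per-dataset log2 fold changes with noise-floor imputation
#'
#' For every labelling dataset, computes `log2(bait / control)` per protein.
#' A missing intensity on one side is imputed with that sample's noise floor
#' (the `noise_floor_quantile` quantile of its quantified intensities) and
#' flagged; bait-only proteins are the signal of interest, so rows are never
#' dropped for one-sided missingness. Proteins missing on both sides of a
#' dataset get no entry for that dataset.
#'
#' @param quant A [quant_table()].
#' @param design A [sample_design()] table; each dataset's bait and control
#'   samples must be columns of `quant`.
#' @param cfg A [pipeline_config()].
#'
#' @return A `data.frame` of class `log2fc_table` with columns `protein_id`,
#'   `dataset_id`, `log2fc`, `imputed`.
#' @export
compute_log2fc <- function(quant, design, cfg = pipeline_config()) {
  missing_cols <- setdiff(design$sample_id, colnames(quant$intensities))
  if (length(missing_cols))
    stop("design sample(s) absent from quant table: ",
         paste(missing_cols, collapse = ", "))
  floors <- apply(quant$intensities, 2, function(v)
    stats::quantile(v[!is.na(v)], cfg$noise_floor_quantile, names = FALSE))
  out <- list()
  for (ds in unique(design$dataset_id)) {
    bait_s <- design$sample_id[design$dataset_id == ds &
                                 design$bait == "ACTIVE_SN"]
    ctrl_s <- design$sample_id[design$dataset_id == ds &
                                 design$bait == "CONTROL_R97A"]
    if (length(bait_s) != 1L || length(ctrl_s) != 1L)
      stop("dataset ", ds, " lacks a bait/control sample pair")
    b <- quant$intensities[, bait_s]
    c_ <- quant$intensities[, ctrl_s]
    keep <- !(is.na(b) & is.na(c_))
    imputed <- keep & (is.na(b) | is.na(c_))
    bi <- ifelse(is.na(b), floors[bait_s], b)
    ci <- ifelse(is.na(c_), floors[ctrl_s], c_)
    out[[ds]] <- data.frame(
      protein_id = quant$proteins$protein_id[keep],
      dataset_id = ds,
      log2fc = log2(bi[keep] / ci[keep]),
      imputed = imputed[keep],
      stringsAsFactors = FALSE
    )
  }
  fc <- do.call(rbind, out)
  rownames(fc) <- NULL
  class(fc) <- c("log2fc_table", "data.frame")
  fc
}

#' Assess the proximity labelling tail of one dataset
#'
#' The tail cutoff is the `tail_quantile` quantile of the log2 fold changes
#' of non-membrane proteins. Proteins strictly above the cutoff are counted
#' by class, and a one-sided hypergeometric test asks whether membrane
#' proteins are over-represented among the above-cutoff set given the class
#' totals. A dataset "has a tail" when the membrane count reaches `k_min`
#' and the enrichment p value is below `p_tail`.
#'
#' @param fc A [compute_log2fc()] table.
#' @param ann An [annotation_table()].
#' @param dataset_id Dataset to assess.
#' @param cfg A [pipeline_config()].
#'
#' @return A list of class `tail_assessment` with elements `dataset_id`,
#'   `cutoff`, `n_above_cutoff_membrane`, `n_above_cutoff_other`,
#'   `enrichment_p`, `has_tail`.
#' @export
assess_tail <- function(fc, ann, dataset_id, cfg = pipeline_config()) {
  sub <- fc[fc$dataset_id == dataset_id, ]
  if (nrow(sub) < 50L)
    stop("dataset ", dataset_id, ": fewer than 50 proteins with a log2 fold change")
  is_mem <- ann$cc_class[match(sub$protein_id, ann$protein_id)] == "MEMBRANE"
  is_mem[is.na(is_mem)] <- FALSE
  if (!any(!is_mem))
    stop("dataset ", dataset_id, ": no non-membrane proteins")
  cutoff <- stats::quantile(sub$log2fc[!is_mem], cfg$tail_quantile,
                            names = FALSE)
  above <- sub$log2fc > cutoff
  n_mem_above <- sum(above & is_mem)
  n_other_above <- sum(above & !is_mem)
  n_mem <- sum(is_mem)
  n_tot <- nrow(sub)
  k <- n_mem_above + n_other_above
  # P(X >= n_mem_above) drawing k proteins from n_mem membrane / rest
  p <- stats::phyper(n_mem_above - 1L, n_mem, n_tot - n_mem, k,
                     lower.tail = FALSE)
  structure(list(dataset_id = dataset_id,
                 cutoff = cutoff,
                 n_above_cutoff_membrane = n_mem_above,
                 n_above_cutoff_other = n_other_above,
                 enrichment_p = p,
                 has_tail = (n_mem_above >= cfg$k_min) && (p < cfg$p_tail)),
            class = "tail_assessment")
}

#' Paired-t volcano statistics over retained datasets
#'
#' For each protein, the per-dataset log2 fold changes over the retained
#' datasets form the paired differences: `t = mean(x) / (sd(x)/sqrt(n))`
#' with a two-sided p value from the Student t distribution on `n - 1`
#' degrees of freedom, followed by Benjamini-Hochberg adjustment across all
#' tested proteins. Proteins observed in fewer than two retained datasets
#' are skipped. Zero-variance vectors are degenerate small-n cases: with a
#' nonzero mean the p value is set to the smallest representable positive
#' double and flagged; with zero mean, `t = 0` and `p = 1`.
#'
#' @param fc A [compute_log2fc()] table.
#' @param retained Character vector of retained dataset ids.
#' @param cfg A [pipeline_config()].
#'
#' @return A `data.frame` of class `volcano_table` with columns
#'   `protein_id`, `mean_log2fc`, `t_stat`, `p_value`, `q_value`, `n_pairs`,
#'   `degenerate`, plus attribute `skipped` (protein ids with < 2 pairs).
#' @export
paired_t_volcano <- function(fc, retained, cfg = pipeline_config()) {
  if (length(retained) < 2L)
    stop("at least 2 retained datasets are required for the paired t-test")
  sub <- fc[fc$dataset_id %in% retained, ]
  sp <- split(sub$log2fc, sub$protein_id)
  n <- lengths(sp)
  skipped <- names(sp)[n < 2L]
  sp <- sp[n >= 2L]
  n <- n[n >= 2L]
  m <- vapply(sp, mean, numeric(1))
  s <- vapply(sp, stats::sd, numeric(1))
  t_stat <- numeric(length(sp))
  p <- numeric(length(sp))
  degenerate <- s == 0
  ok <- !degenerate
  t_stat[ok] <- m[ok] / (s[ok] / sqrt(n[ok]))
  p[ok] <- 2 * stats::pt(-abs(t_stat[ok]), df = n[ok] - 1)
  deg_nz <- degenerate & m != 0
  t_stat[deg_nz] <- sign(m[deg_nz]) * Inf
  p[deg_nz] <- .Machine$double.xmin
  deg_z <- degenerate & m == 0
  t_stat[deg_z] <- 0
  p[deg_z] <- 1
  out <- data.frame(protein_id = names(sp),
                    mean_log2fc = unname(m),
                    t_stat = unname(t_stat),
                    p_value = unname(p),
                    q_value = stats::p.adjust(unname(p), method = "BH"),
                    n_pairs = unname(as.integer(n)),
                    degenerate = unname(degenerate),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("volcano_table", "data.frame")
  out
}

#' Select significantly enriched proteins from a volcano table
#'
#' Retains proteins with p (or BH q, when `use_adjusted_p`) below `alpha`
#' and mean log2 fold change above `min_log2fc`. Selection is one-sided:
#' depleted proteins are never selected, however significant.
#'
#' @param volcano A [paired_t_volcano()] table.
#' @param cfg A [pipeline_config()].
#' @return Character vector of selected protein ids.
#' @export
select_significant <- function(volcano, cfg = pipeline_config()) {
  if (nrow(volcano) == 0L) stop("empty volcano table")
  pv <- if (cfg$use_adjusted_p) volcano$q_value else volcano$p_value
  volcano$protein_id[pv < cfg$alpha & volcano$mean_log2fc > cfg$min_log2fc]
}

#' Glycosylation / plasma-membrane annotation filter
#'
#' Removes candidates without predicted N-glycosylation sites or unlikely to
#' reside on the plasma membrane: a protein is retained iff `n_sequons >= 1`
#' and `plasma_membrane = TRUE`. Candidates with no annotation record are
#' removed with reason `UNANNOTATED`; among annotated failures the recorded
#' reason is `NO_GLYCOSITES` before `NOT_PLASMA_MEMBRANE` when both apply.
#'
#' @param candidates Character vector of protein ids.
#' @param ann An [annotation_table()].
#' @return Character vector of retained ids, with attribute `removed`
#'   (a `data.frame` of `protein_id`, `reason`).
#' @export
annotation_filter <- function(candidates, ann) {
  idx <- match(candidates, ann$protein_id)
  reason <- rep(NA_character_, length(candidates))
  reason[is.na(idx)] <- "UNANNOTATED"
  known <- !is.na(idx)
  ns <- ann$n_sequons[idx[known]]
  pm <- ann$plasma_membrane[idx[known]]
  r <- rep(NA_character_, sum(known))
  r[!pm] <- "NOT_PLASMA_MEMBRANE"
  r[is.na(ns) | ns < 1] <- "NO_GLYCOSITES"
  reason[known] <- r
  retained <- candidates[is.na(reason)]
  removed <- data.frame(protein_id = candidates[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  attr(retained, "removed") <- removed
  retained
}

#' Back-map candidates to every retained fold-change histogram
#'
#' Final filtration stage: each candidate is mapped back to the per-dataset
#' log2 fold-change histograms of the retained datasets and removed if it
#' falls outside the proximity labelling tail (below the dataset's cutoff)
#' anywhere. Membership uses `log2fc >= cutoff` (the tail call itself uses a
#' strict `>`; the asymmetry is deliberate: conservative tail calling,
#' permissive retention). By default a protein is judged only on the
#' retained datasets in which it was observed; `cfg$backmap_min_in_tail`
#' switches to a minimum-count policy.
#'
#' @param candidates Character vector of protein ids.
#' @param fc A [compute_log2fc()] table.
#' @param tails List of [assess_tail()] results for the retained
#'   (`has_tail`) datasets.
#' @param cfg A [pipeline_config()].
#' @return Character vector of retained ids, with attribute `removed`
#'   (`data.frame` of `protein_id`, `reason = "OUTSIDE_TAIL"`).
#' @export
backmap_filter <- function(candidates, fc, tails, cfg = pipeline_config()) {
  if (any(!vapply(tails, function(t) isTRUE(t$has_tail), logical(1))))
    stop("backmap_filter expects tail assessments of retained datasets only")
  cutoffs <- vapply(tails, function(t) t$cutoff, numeric(1))
  names(cutoffs) <- vapply(tails, function(t) t$dataset_id, character(1))
  sub <- fc[fc$dataset_id %in% names(cutoffs) &
              fc$protein_id %in% candidates, ]
  in_tail <- sub$log2fc >= cutoffs[sub$dataset_id]
  n_obs <- tapply(in_tail, sub$protein_id, length)
  n_in <- tapply(in_tail, sub$protein_id, sum)
  keep_ids <- names(n_obs)[
    if (is.null(cfg$backmap_min_in_tail)) n_in == n_obs
    else n_in >= cfg$backmap_min_in_tail]
  retained <- candidates[candidates %in% keep_ids]
  removed <- setdiff(candidates, retained)
  attr(retained, "removed") <-
    data.frame(protein_id = removed,
               reason = rep("OUTSIDE_TAIL", length(removed)),
               stringsAsFactors = FALSE)
  retained
}

#' Run the four-stage counter-receptor filtration pipeline
#'
#' Executes, in order: (1) per-dataset log2 fold-change computation and tail
#' assessment, excluding datasets without a proximity labelling tail;
#' (2) paired-t volcano selection over the retained datasets; (3) the
#' glycosylation / plasma-membrane annotation filter; (4) back-mapping of
#' the survivors to every retained histogram. The stage sets are nested and
#' the run is fully deterministic for fixed inputs.
#'
#' @param quant A [quant_table()].
#' @param design A [sample_design()] table.
#' @param ann An [annotation_table()].
#' @param cfg A [pipeline_config()].
#'
#' @return A list of class `counter_receptor_report`: `tails` (all
#'   assessments), `retained_datasets`, `volcano`, `stage_sets` (protein-id
#'   sets after stages 2-4), `final_set`, `audit` (one removal reason per
#'   excluded tested protein), and `config`.
#' @export
run_pipeline <- function(quant, design, ann, cfg = pipeline_config()) {
  fc <- compute_log2fc(quant, design, cfg)
  tails <- lapply(unique(design$dataset_id), function(ds)
    assess_tail(fc, ann, ds, cfg))
  names(tails) <- unique(design$dataset_id)
  retained <- names(tails)[vapply(tails, `[[`, logical(1), "has_tail")]
  if (length(retained) < 2L)
    stop("NO_RETAINED_DATASETS: fewer than 2 datasets show a proximity labelling tail")
  volcano <- paired_t_volcano(fc, retained, cfg)
  stage2 <- select_significant(volcano, cfg)
  stage3 <- annotation_filter(stage2, ann)
  stage4 <- backmap_filter(stage3, fc, tails[retained], cfg)

  audit_rows <- function(ids, stage, reason) {
    data.frame(protein_id = as.character(ids),
               stage = rep_len(stage, length(ids)),
               reason = rep_len(reason, length(ids)),
               stringsAsFactors = FALSE)
  }
  rm3 <- attr(stage3, "removed")
  rm4 <- attr(stage4, "removed")
  audit <- rbind(
    audit_rows(attr(volcano, "skipped"), "volcano", "TOO_FEW_PAIRS"),
    audit_rows(setdiff(volcano$protein_id, stage2), "volcano",
               "NOT_SIGNIFICANT"),
    audit_rows(rm3$protein_id, "annotation", rm3$reason),
    audit_rows(rm4$protein_id, "backmap", rm4$reason)
  )
  rownames(audit) <- NULL

  structure(list(
    tails = tails,
    retained_datasets = retained,
    volcano = volcano,
    stage_sets = list(significant = as.character(stage2),
                      annotated = as.character(stage3),
                      backmapped = as.character(stage4)),
    final_set = as.character(stage4),
    audit = audit,
    config = unclass(cfg)
  ), class = "counter_receptor_report")
}

#' @export
print.counter_receptor_report <- function(x, ...) {
  cat("counter_receptor_report\n")
  cat("  datasets retained:", length(x$retained_datasets), "of",
      length(x$tails), "\n")
  cat("  proteins tested:  ", nrow(x$volcano), "\n")
  cat("  significant:      ", length(x$stage_sets$significant), "\n")
  cat("  annotation-passed:", length(x$stage_sets$annotated), "\n")
  cat("  final set:        ", length(x$final_set), "\n")
  invisible(x)
}

#' Export a counter-receptor report
#'
#' `report_to_list()` flattens a report for JSON serialization via
#' [write_report()]. `export_final_table()` writes the final set as a TSV
#' shaped like the published counter-receptor list (gene name, log2 fold
#' change, p value).
#'
#' @param report A [run_pipeline()] report.
#' @return A plain named list.
#' @export
report_to_list <- function(report) {
  list(
    retained_datasets = report$retained_datasets,
    tails = lapply(report$tails, unclass),
    n_tested = nrow(report$volcano),
    stage_sets = report$stage_sets,
    final_set = report$final_set,
    audit = report$audit,
    config = report$config
  )
}

#' @rdname report_to_list
#' @param quant The [quant_table()] the report was computed from (for gene
#'   names).
#' @param path Output TSV path.
#' @export
export_final_table <- function(report, quant, path) {
  idx <- match(report$final_set, quant$proteins$protein_id)
  v <- report$volcano[match(report$final_set, report$volcano$protein_id), ]
  out <- data.frame(gene_name = quant$proteins$gene_name[idx],
                    log2_fold_change = v$mean_log2fc,
                    p_value = v$p_value,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$log2_fold_change), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
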
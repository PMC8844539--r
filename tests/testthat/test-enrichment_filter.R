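test_that("log2 fold changes follow the stated imputation rule", {
  # noise floor of the control sample is driven to 1e4 by the low quantiles
  m <- matrix(c(8e6, 5e5, 1e6, rep(1e4, 7),
                1e6, 5e5, NA, rep(1e4, 7)), ncol = 2,
              dimnames = list(NULL, c("DS1_b", "DS1_c")))
  q <- toy_quant(m)
  fc <- compute_log2fc(q, toy_design(1L))
  expect_equal(fc$log2fc[fc$protein_id == "P001"], 3.0)
  expect_equal(fc$log2fc[fc$protein_id == "P002"], 0.0)
  # control missing: imputed at the control sample's noise floor (1e4)
  p3 <- fc[fc$protein_id == "P003", ]
  expect_true(p3$imputed)
  expect_equal(p3$log2fc, log2(1e6 / 1e4), tolerance = 1e-9)
  expect_false(any(fc$imputed[fc$protein_id != "P003"]))
})

test_that("proteins missing on both sides of a dataset get no entry", {
  m <- matrix(c(1e6, NA, 1e5, 2e6, NA, 3e5), ncol = 2,
              dimnames = list(NULL, c("DS1_b", "DS1_c")))
  fc <- compute_log2fc(toy_quant(m), toy_design(1L))
  expect_equal(sort(fc$protein_id), c("P001", "P003"))
})

test_that("tail enrichment p equals exact combinatorial summation", {
  set.seed(42)
  for (rep_i in 1:200) {
    n_tot <- sample(10:60, 1)
    n_mem <- sample(1:(n_tot - 1), 1)
    k <- sample(1:n_tot, 1)
    x <- sample(max(0, k - (n_tot - n_mem)):min(k, n_mem), 1)
    p_pkg <- phyper(x - 1, n_mem, n_tot - n_mem, k, lower.tail = FALSE)
    expect_equal(p_pkg, hyper_tail_bruteforce(x, n_mem, n_tot, k),
                 tolerance = 1e-12)
  }
  # the urn of the worked example: 10 of 20 membrane above cutoff,
  # 30 above in total, 100 proteins
  expect_equal(phyper(9, 20, 80, 30, lower.tail = FALSE),
               hyper_tail_bruteforce(10, 20, 100, 30), tolerance = 1e-12)
})

test_that("assess_tail calls tails on spiked data and not on flat data", {
  # all log2fc equal: ties are not counted above the cutoff (strict >)
  m <- matrix(rep(c(2e5, 1e5), each = 60), ncol = 2,
              dimnames = list(NULL, c("DS1_b", "DS1_c")))
  q <- toy_quant(m)
  ann <- toy_annotation(q$proteins$protein_id,
                        cc_class = rep(c("MEMBRANE", "CYTOPLASM"), 30),
                        plasma_membrane = FALSE)
  ta <- assess_tail(compute_log2fc(q, toy_design(1L)), ann, "DS1")
  expect_equal(ta$n_above_cutoff_membrane, 0L)
  expect_false(ta$has_tail)

  # 50 spiked membrane proteins at log2fc ~ +3 among 2000
  ex <- generate_experiment(sim_config(seed = 7, spike_log2_mean = 3,
                                       spike_log2_sd = 0))
  fc <- compute_log2fc(ex$quant, ex$design)
  ta2 <- assess_tail(fc, ex$annotation, ex$design$dataset_id[1])
  expect_true(ta2$has_tail)
  expect_gte(ta2$n_above_cutoff_membrane, 20L)
  expect_lt(ta2$enrichment_p, 0.01)

  expect_error(assess_tail(fc[1:10, ], ex$annotation,
                           ex$design$dataset_id[1]), "fewer than 50")
})

test_that("paired-t statistics match the independent textbook oracle", {
  fc_of <- function(x) data.frame(
    protein_id = "P1", dataset_id = paste0("D", seq_along(x)),
    log2fc = x, imputed = FALSE)
  v <- paired_t_volcano(fc_of(c(1, -1, 0)), paste0("D", 1:3))
  expect_equal(v$t_stat, 0)
  expect_equal(v$p_value, 1)

  v <- paired_t_volcano(fc_of(c(2, 3, 4)), paste0("D", 1:3))
  expect_equal(v$t_stat, 3 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(v$p_value, 0.0351, tolerance = 1e-3)
  expect_equal(v$p_value, t.test(c(2, 3, 4))$p.value, tolerance = 1e-12)

  # zero variance, nonzero mean: degenerate, smallest representable p
  v <- paired_t_volcano(fc_of(c(2, 2, 2)), paste0("D", 1:3))
  expect_true(v$degenerate)
  expect_equal(v$p_value, .Machine$double.xmin)

  set.seed(1234)
  for (i in 1:1000) {
    x <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.1, 2))
    v <- paired_t_volcano(fc_of(x), paste0("D", seq_along(x)))
    tt <- t.test(x)
    expect_equal(v$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(v$p_value, tt$p.value, tolerance = 1e-8)
  }
})

test_that("BH adjustment follows the step-up procedure", {
  fc <- data.frame(protein_id = rep(paste0("P", 1:4), each = 2),
                   dataset_id = rep(c("D1", "D2"), 4),
                   log2fc = 0, imputed = FALSE)
  # directly check the adjustment on a hand-worked case
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  v <- paired_t_volcano(fc, c("D1", "D2"))
  expect_true(all(v$q_value >= v$p_value))
})

test_that("significance selection is one-sided on the enrichment side", {
  v <- data.frame(protein_id = c("A", "B", "C", "D"),
                  mean_log2fc = c(2, -2, 0.5, 1.5),
                  t_stat = 0, p_value = c(0.01, 0.01, 0.01, 0.2),
                  q_value = c(0.02, 0.02, 0.02, 0.3),
                  n_pairs = 3L, degenerate = FALSE)
  expect_equal(select_significant(v), "A")
  # the defaults keep every row of the published table
  t1 <- read_table1_fixture()
  vt <- data.frame(protein_id = t1$gene_name,
                   mean_log2fc = t1$log2_fold_change,
                   t_stat = 0, p_value = t1$p_value, q_value = t1$p_value,
                   n_pairs = 5L, degenerate = FALSE)
  expect_equal(length(select_significant(vt)), 49L)
})

test_that("annotation filter applies the sequon and membrane rules", {
  ann <- annotation_table(data.frame(
    protein_id = c("A", "B", "C", "D"),
    cc_class = c("MEMBRANE", "MEMBRANE", "MEMBRANE", "CYTOPLASM"),
    plasma_membrane = c(TRUE, TRUE, FALSE, FALSE),
    n_sequons = c(4L, 0L, 2L, 1L),
    n_ig_domains = 1L))
  kept <- annotation_filter(c("A", "B", "C", "D", "E"), ann)
  expect_equal(as.character(kept), "A")
  removed <- attr(kept, "removed")
  expect_equal(removed$reason[removed$protein_id == "B"], "NO_GLYCOSITES")
  expect_equal(removed$reason[removed$protein_id == "C"],
               "NOT_PLASMA_MEMBRANE")
  expect_equal(removed$reason[removed$protein_id == "E"], "UNANNOTATED")

  # random candidate sets against a set-comprehension oracle
  set.seed(99)
  ids <- sprintf("P%03d", 1:100)
  ann2 <- annotation_table(data.frame(
    protein_id = ids,
    cc_class = ifelse(runif(100) < 0.5, "MEMBRANE", "OTHER"),
    plasma_membrane = FALSE, n_sequons = rpois(100, 1),
    n_ig_domains = 0L))
  ann2$plasma_membrane <- ann2$cc_class == "MEMBRANE" & runif(100) < 0.7
  ann2 <- annotation_table(as.data.frame(ann2))
  for (i in 1:20) {
    cand <- sample(ids, 30)
    oracle <- cand[vapply(cand, function(p) {
      r <- ann2[ann2$protein_id == p, ]
      r$n_sequons >= 1 && r$plasma_membrane
    }, logical(1))]
    expect_equal(as.character(annotation_filter(cand, ann2)), oracle)
  }
})

test_that("back-mapping removes proteins outside any retained tail", {
  tails <- lapply(c("D1", "D2"), function(d)
    structure(list(dataset_id = d, cutoff = 1.0,
                   n_above_cutoff_membrane = 25L, n_above_cutoff_other = 1L,
                   enrichment_p = 1e-6, has_tail = TRUE),
              class = "tail_assessment"))
  fc <- data.frame(
    protein_id = c("A", "A", "B", "B", "C"),
    dataset_id = c("D1", "D2", "D1", "D2", "D1"),
    log2fc = c(2, 1.0, 2, 0.5, 3), imputed = FALSE)
  kept <- backmap_filter(c("A", "B", "C"), fc, tails)
  # A is at the cutoff in D2 (>= retains); B falls below in D2;
  # C is judged only on the dataset where it was observed
  expect_equal(as.character(kept), c("A", "C"))
  expect_equal(attr(kept, "removed")$reason, "OUTSIDE_TAIL")

  # brute-force all-datasets oracle on random candidate sets
  set.seed(7)
  ids <- sprintf("P%02d", 1:40)
  fc2 <- expand.grid(protein_id = ids, dataset_id = c("D1", "D2"),
                     stringsAsFactors = FALSE)
  fc2$log2fc <- rnorm(nrow(fc2), 1, 1)
  fc2$imputed <- FALSE
  for (i in 1:10) {
    cand <- sample(ids, 15)
    oracle <- cand[vapply(cand, function(p) {
      all(fc2$log2fc[fc2$protein_id == p] >= 1.0)
    }, logical(1))]
    expect_equal(as.character(backmap_filter(cand, fc2, tails)), oracle)
  }
})

test_that("the four stages nest and the pipeline is deterministic", {
  ex <- generate_experiment(sim_config(n_proteins = 600L, n_spiked = 40L,
                                       seed = 3L))
  rep1 <- run_pipeline(ex$quant, ex$design, ex$annotation)
  rep2 <- run_pipeline(ex$quant, ex$design, ex$annotation)
  expect_identical(rep1, rep2)
  ss <- rep1$stage_sets
  expect_true(all(ss$backmapped %in% ss$annotated))
  expect_true(all(ss$annotated %in% ss$significant))
  expect_true(all(ss$significant %in% rep1$volcano$protein_id))
  expect_identical(rep1$final_set, ss$backmapped)
  # each audited protein carries exactly one removal reason
  expect_false(anyDuplicated(rep1$audit$protein_id) > 0)
  expect_equal(sort(c(rep1$final_set, rep1$audit$protein_id)),
               sort(union(rep1$volcano$protein_id,
                          attr(rep1$volcano, "skipped"))))
})

test_that("the volcano stage recovers nearly all spiked proteins", {
  ex <- generate_experiment(sim_config(seed = 7))
  rep <- run_pipeline(ex$quant, ex$design, ex$annotation)
  stage2 <- rep$stage_sets$significant
  hits <- length(intersect(stage2, ex$truth$spiked_ids))
  expect_gte(hits / length(ex$truth$spiked_ids), 0.85)
  # and the final set stays essentially free of false discoveries
  fp <- length(setdiff(rep$final_set, ex$truth$spiked_ids))
  expect_lte(fp / max(1, length(rep$final_set)), 0.1)
})

test_that("a pure-noise dataset is excluded without changing the result", {
  cfg <- sim_config(seed = 21L, degrade_datasets = "ON_BEA_R2")
  ex <- generate_experiment(cfg)
  rep <- run_pipeline(ex$quant, ex$design, ex$annotation)
  expect_false("ON_BEA_R2" %in% rep$retained_datasets)

  # rerun without the degraded dataset at all: same final set
  keep <- ex$design$dataset_id != "ON_BEA_R2"
  design2 <- ex$design[keep, ]
  q2 <- quant_table(ex$quant$proteins,
                    ex$quant$intensities[, design2$sample_id])
  rep2 <- run_pipeline(q2, design2, ex$annotation)
  expect_identical(sort(rep$final_set), sort(rep2$final_set))
})

test_that("an all-noise experiment yields no retained datasets", {
  ex <- generate_experiment(sim_config(n_spiked = 0L, seed = 5L))
  expect_error(run_pipeline(ex$quant, ex$design, ex$annotation),
               "NO_RETAINED_DATASETS")
})
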
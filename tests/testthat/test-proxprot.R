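mk_table <- function(m, peptides = rep(5L, nrow(m)),
                     contaminant = rep(FALSE, nrow(m)),
                     construct = NULL, genotype = NULL) {
  ns <- ncol(m)
  if (is.null(construct)) construct <- rep(c("bait", "control"), each = ns / 2)
  if (is.null(genotype)) genotype <- rep("WT", ns)
  meta <- data.frame(sample = paste0(construct, "_", genotype, "_",
                                     seq_len(ns)),
                     construct = construct, genotype = genotype,
                     replicate = seq_len(ns))
  quant_table(m, peptides, contaminant, meta)
}

test_that("quality filters drop contaminants, low-peptide ids, and the raw floor", {
  m <- matrix(log2(c(2000, 2000, 2000, 2000,
                     999,  2000, 2000, 2000,
                     1000, 2000, 2000, 2000,
                     2000, 2000, 2000, 2000,
                     2000, 2000, 2000, 2000)),
              5, 4, byrow = TRUE)
  rownames(m) <- paste0("P", 1:5)
  tab <- mk_table(m, peptides = c(5L, 5L, 5L, 1L, 5L),
                  contaminant = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  out <- quality_filter(tab)
  tl <- attr(out, "tallies")
  expect_false("P4" %in% rownames(out$log2))  # single peptide
  expect_false("P5" %in% rownames(out$log2))  # contaminant
  expect_true(is.na(out$log2["P2", 1]))       # raw 999: strictly below floor
  expect_equal(out$log2["P3", 1], log2(1000)) # raw 1000 kept (not below)
  expect_equal(tl$contaminant, 1L)
  expect_equal(tl$few_peptides, 1L)
  expect_equal(tl$low_intensity_cells, 1L)
  expect_equal(tl$kept, nrow(out$log2))
  expect_lte(nrow(out$log2), nrow(tab$log2))  # never increases counts

  # clean table passes through unchanged
  clean <- mk_table(matrix(log2(4000), 3, 4,
                           dimnames = list(paste0("Q", 1:3), NULL)))
  expect_equal(quality_filter(clean)$log2, clean$log2)
})

test_that("proteins must be quantified in two replicates of some condition group", {
  m <- matrix(log2(5000), 2, 6)
  rownames(m) <- c("A", "B")
  # B quantified once per group only
  m[2, c(2, 3, 5, 6)] <- NA
  tab <- mk_table(m, construct = rep(c("bait", "control"), each = 3))
  out <- quality_filter(tab)
  expect_equal(rownames(out$log2), "A")
  expect_equal(attr(out, "tallies")$underquantified, 1L)
})

test_that("mode normalization recovers constructed sample shifts", {
  set.seed(4)
  base <- rnorm(300, 13, 1.5)
  m <- cbind(A = base, B = base + 0.5)
  rownames(m) <- paste0("P", seq_len(300))
  tab <- mk_table(m, construct = c("bait", "control"),
                  genotype = c("WT", "WT"))
  out <- mode_normalize(tab)
  f <- attr(out, "factors")
  expect_equal(unname(f), c(-0.25, 0.25), tolerance = 0.02)
  expect_equal(sum(f), 0, tolerance = 1e-9)
  # post-normalization pairwise mode ~ 0
  d <- out$log2[, 1] - out$log2[, 2]
  expect_lt(abs(stats::density(d, bw = "nrd0")$x[
    which.max(stats::density(d, bw = "nrd0")$y)]), 0.05)

  # identical samples: all factors 0
  m2 <- cbind(base, base, base, base)
  rownames(m2) <- paste0("P", seq_len(300))
  f2 <- attr(mode_normalize(mk_table(m2)), "factors")
  expect_equal(unname(f2), rep(0, 4), tolerance = 1e-6)

  # idempotent: renormalizing gives factors below 0.01
  f3 <- attr(mode_normalize(out), "factors")
  expect_true(all(abs(f3) < 0.01))
})

test_that("mode normalization warns and falls back on sparse overlap", {
  m <- matrix(c(13, 14, NA, NA, 13.5, NA,
                NA, NA, 13, 14, NA, 13.2), 6, 2)
  rownames(m) <- paste0("P", 1:6)
  expect_warning(mode_normalize(mk_table(m, construct = c("bait", "control"))),
                 "share only")
})

test_that("imputation draws the documented distribution, deterministically", {
  m <- matrix(NA_real_, 250, 4)
  m[1:50, ] <- 14
  rownames(m) <- paste0("P", seq_len(250))
  tab <- mk_table(m)
  out1 <- impute_missing(tab, seed = 7)
  out2 <- impute_missing(tab, seed = 7)
  expect_identical(out1$log2, out2$log2)
  expect_false(any(is.na(out1$log2)))
  expect_equal(unname(out1$log2[1:50, ]), unname(m[1:50, ]))  # observed cells untouched
  expect_equal(sum(attr(out1, "imputed")), 200 * 4)

  # no missing values: unchanged
  full <- mk_table(matrix(12, 5, 4, dimnames = list(paste0("P", 1:5), NULL)))
  expect_equal(impute_missing(full, seed = 1)$log2, full$log2)

  imp <- out1$log2[attr(out1, "imputed")]
  expect_equal(mean(imp), 9.96, tolerance = 0.1)
  expect_equal(sd(imp), 0.75, tolerance = 0.1)
})

test_that("signal over control subtracts the genotype-matched control mean", {
  m <- matrix(c(12, 12, 12, 10, 10, 10,   # P1: bait 12, control mean 10
                8,  9, 10,  9,  9,  9),   # P2
              2, 6, byrow = TRUE)
  rownames(m) <- c("P1", "P2")
  tab <- mk_table(m, construct = rep(c("bait", "control"), each = 3))
  soc <- signal_over_control(tab)
  expect_equal(unname(soc["P1", ]), c(2, 2, 2))
  expect_equal(unname(soc["P2", ]), c(-1, 0, 1))

  # bait equal to control mean -> 0
  expect_equal(unname(soc["P2", 2]), 0)

  # missing genotype pairing is an error
  bad <- mk_table(m, construct = rep(c("bait", "control"), each = 3),
                  genotype = c("KD", "KD", "KD", "WT", "WT", "WT"))
  expect_error(signal_over_control(bad), "no matched control")
})

test_that("differential test matches the closed-form pooled t", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  p <- differential_test(a, b)
  expect_equal(p, oracle_t_p(a, b), tolerance = 1e-12)
  expect_equal(p, 0.0213, tolerance = 1e-2)  # t = -3.674, df = 4

  set.seed(12)
  for (rep in 1:10) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1), 0.5)
    expect_equal(differential_test(a, b), oracle_t_p(a, b), tolerance = 1e-12)
  }

  # same values permuted: equal means, p = 1
  a <- c(1, 5, 9)
  expect_equal(differential_test(a, c(9, 1, 5)), 1, tolerance = 1e-12)

  expect_error(differential_test(1, c(1, 2)), "two values")
  expect_error(differential_test(c(2, 2), c(3, 3)), "zero pooled variance")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))^2
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # sorted inputs give non-decreasing outputs
    expect_true(all(diff(bh_adjust(sort(p))) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("target selection applies strict published thresholds", {
  res <- data.frame(protein = c("A", "B", "C", "D"),
                    log2_ratio = c(1.5, 1.0, 2.0, 1.4),
                    p = c(1e-4, 1e-4, 5e-3, 2e-2),
                    adj_p = c(0.001, 0.001, 0.02, 0.0099))
  expect_equal(select_targets(res), c("A", "D"))
  # boundary: ratio exactly 1 and adj_p 0.02 are both excluded
  expect_false("B" %in% select_targets(res))
  expect_false("C" %in% select_targets(res))
})

test_that("knockdown contrast requires significance and the right direction", {
  soc_wt <- matrix(c(3, 3.2, 2.8,  2, 2.1, 1.9,  1, 1.1, 0.9), 3,
                   byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), NULL))
  soc_kd <- soc_wt
  soc_kd["A", ] <- soc_wt["A", ] - 3          # strongly reduced
  soc_kd["C", ] <- soc_wt["C", ] + 3          # reversed direction
  out <- knockdown_contrast(c("A", "B", "C"), soc_wt, soc_kd)
  expect_true(out$selected[out$protein == "A"])
  expect_false(out$selected[out$protein == "B"])  # identical values
  expect_false(out$selected[out$protein == "C"])  # significant but reversed

  # planted knockdown-sensitive proteins are detected reliably
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    wt <- matrix(rnorm(30, 3, 0.3), 10, 3,
                 dimnames = list(paste0("T", 1:10), NULL))
    kd <- matrix(rnorm(30, 3, 0.3), 10, 3,
                 dimnames = list(paste0("T", 1:10), NULL))
    kd["T1", ] <- kd["T1", ] - 3
    out <- knockdown_contrast(paste0("T", 1:10), wt, kd)
    if (out$selected[out$protein == "T1"]) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("pipeline recall tracks the noncentral-t/BH oracle with controlled FDP", {
  # At 3 vs 3 replicates the pooled t has 4 degrees of freedom, so the
  # sample-s.d. fluctuation caps BH(<0.01) detection power well below 1;
  # the analytic self-consistent power is the right yardstick.
  recalls <- c()
  for (seed in 1:6) {
    g <- gen_quant_table(seed = seed)
    out <- run_enrichment(g$table, seed = seed + 1000)
    truth <- g$truth$enriched
    found <- out$targets
    recalls <- c(recalls,
                 length(intersect(found, truth)) / length(truth))
    fdp <- if (length(found)) length(setdiff(found, truth)) / length(found)
           else 0
    expect_lte(fdp, 0.1)
  }
  expected <- oracle_bh_recall(effect = 3, sigma = 0.3, n_rep = 3,
                               n_proteins = 600, n_enriched = 30)
  expect_equal(mean(recalls), expected, tolerance = 0.35)
  expect_gt(mean(recalls), 0.4)  # far above the ~0.0005 chance level
})

test_that("a null table yields almost no selected targets", {
  for (seed in 1:3) {
    g <- gen_quant_table(n_enriched = 0, seed = seed)
    out <- run_enrichment(g$table, seed = seed + 2000)
    # nominal alpha 0.01 on ~600 proteins, with the ratio cut on top
    expect_lte(length(out$targets), ceiling(3 * 0.01 * 600))
  }
})

test_that("TSV round-trip preserves the quantification table", {
  g <- gen_quant_table(n_proteins = 40, n_enriched = 5, seed = 6)
  qp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  raw <- 2^g$table$log2
  raw[is.na(raw)] <- 0
  df <- data.frame(protein = rownames(g$table$log2),
                   peptides = g$table$peptides,
                   contaminant = g$table$contaminant, raw,
                   check.names = FALSE)
  write.table(df, qp, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(g$table$meta, sp, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_quant_tsv(qp, sp)
  expect_equal(back$log2, g$table$log2, tolerance = 1e-12)
  expect_equal(back$meta$construct, g$table$meta$construct)
})
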
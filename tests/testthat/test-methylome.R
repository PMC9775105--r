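sites_df <- function(pos, m, u, chrom = "chr1", context = "CpG",
                     strand = "+") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             context = context, count_methylated = as.integer(m),
             count_unmethylated = as.integer(u), stringsAsFactors = FALSE)
}

test_that("context summary calls fully methylated and unmethylated sites", {
  full <- sites_df(1:50 * 10, m = 20, u = 0)
  expect_equal(context_summary(full)$frac_methylated, 1)
  none <- sites_df(1:50 * 10, m = 0, u = 20)
  expect_equal(context_summary(none)$frac_methylated, 0)
})

test_that("simulated contexts separate in the summary", {
  cfg <- sim_config(seed = 81)
  p <- simulate_parents(cfg)
  sim <- simulate_sperm_methylomes(p$genes, NULL, cfg)
  cs <- context_summary(sim$X)
  frac <- setNames(cs$frac_methylated, cs$context)
  expect_gt(frac[["CpG"]], 0.9)
  expect_lt(frac[["CHH"]], 0.1)
  expect_lt(frac[["CHG"]], 0.1)
  expect_gt(frac[["CpG"]], 10 * frac[["CHH"]])
})

test_that("conversion efficiency is the unmethylated fraction of the spike-in", {
  s <- sites_df(c(1, 2), m = c(3, 1), u = c(500, 496), chrom = "lambda")
  expect_equal(conversion_efficiency(s), 0.996)
  expect_equal(conversion_efficiency(sites_df(1:5, 0, 30, chrom = "lambda")),
               1.0)
  expect_error(conversion_efficiency(sites_df(1, 1, 1, chrom = "chr1")),
               "spike-in")
  cfg <- sim_config(seed = 82)
  p <- simulate_parents(cfg)
  sim <- simulate_sperm_methylomes(p$genes, NULL, cfg,
                                   non_conversion = 0.004)
  eff <- conversion_efficiency(sim$X)
  n_reads <- sum(sapply(sim$X, function(s)
    sum(s[s$chrom == "lambda", c("count_methylated", "count_unmethylated")])))
  expect_lt(abs(eff - 0.996), 3 * sqrt(0.004 * 0.996 / n_reads))
})

test_that("global site comparison counts matched covered sites", {
  x <- sites_df(1:10, m = c(5, 5, 5, 8, 8, 8, 8, 5, 5, 5), u = 5)
  y <- sites_df(1:10, m = c(8, 8, 8, 5, 5, 5, 5, 5, 5, 5), u = 5)
  got <- global_site_comparison(x, y, min_cov = 1)
  expect_equal(unname(got), c(0.3, 0.4, 0.3), ignore_attr = TRUE)
  expect_equal(sum(got), 1)
  # identical tables tie everywhere; swapping groups swaps the fractions
  same <- global_site_comparison(x, x, min_cov = 1)
  expect_equal(unname(same), c(0, 0, 1), ignore_attr = TRUE)
  sw <- global_site_comparison(y, x, min_cov = 1)
  expect_equal(sw[["y_higher"]], got[["x_higher"]])
  expect_error(global_site_comparison(x, sites_df(100:110, 1, 1)),
               "matched")
})

test_that("a global offset shows up as a directional site-level skew", {
  cfg <- sim_config(seed = 83)
  p <- simulate_parents(cfg)
  sim <- simulate_sperm_methylomes(p$genes, NULL, cfg, baseline = 0.90,
                                   y_offset = -0.02)
  got <- global_site_comparison(sim$X, sim$Y)
  expect_lt(got[["y_higher"]], got[["x_higher"]])
})

test_that("identical replicate groups yield no DMRs", {
  reps <- lapply(1:3, function(i) sites_df(1:40 * 25, m = 20 + i, u = 5))
  got <- call_dmrs(reps, reps)
  expect_equal(nrow(got), 0)
})

test_that("window differences and Fisher p-values match the 2x2 oracle", {
  x <- sites_df(1:10 * 100, m = 8, u = 2)    # pooled 80/20
  y <- sites_df(1:10 * 100, m = 4, u = 6)    # pooled 40/60
  got <- call_dmrs(list(x), list(y), test = "fisher", q_thresh = 1,
                   diff_thresh = 0)
  expect_equal(nrow(got), 1)
  expect_equal(got$meth_diff, -40)
  expect_equal(got$direction, "hypo")
  expect_equal(got$n_cpg, 10)
  want <- fisher.test(rbind(c(80, 20), c(40, 60)))$p.value
  expect_equal(got$p, want, tolerance = 1e-12)
})

test_that("vectorized Fisher window p equals stats::fisher.test on random tables", {
  set.seed(13)
  mx <- rpois(200, 20); ux <- rpois(200, 10)
  my <- rpois(200, 15); uy <- rpois(200, 15)
  got <- fisher_window_p(mx, ux, my, uy)
  want <- vapply(1:200, function(i)
    fisher.test(rbind(c(mx[i], ux[i]), c(my[i], uy[i])))$p.value,
    numeric(1))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("the default LRT window test matches a logistic-regression LRT", {
  mx <- c(70, 33); ux <- c(30, 67); my <- c(40, 31); uy <- c(60, 69)
  x <- list(sites_df(1:10 * 100, m = mx[1] / 10, u = ux[1] / 10),
            sites_df(1:10 * 100, m = mx[1] / 10, u = ux[1] / 10))
  got <- call_dmrs(x, list(sites_df(1:10 * 100, m = my[1] / 10,
                                    u = uy[1] / 10),
                           sites_df(1:10 * 100, m = my[1] / 10,
                                    u = uy[1] / 10)),
                   q_thresh = 1, diff_thresh = 0, min_cpg = 5)
  for (i in 1) {
    dat <- data.frame(m = c(2 * mx[i], 2 * my[i]), u = c(2 * ux[i], 2 * uy[i]),
                      grp = c("X", "Y"))
    fit <- glm(cbind(m, u) ~ grp, binomial, dat)
    null <- glm(cbind(m, u) ~ 1, binomial, dat)
    p_glm <- pchisq(null$deviance - fit$deviance, 1, lower.tail = FALSE)
    expect_equal(got$p[i], p_glm, tolerance = 1e-9)
  }
})

test_that("planted DMRs are recovered and clean nulls stay clean", {
  cfg <- sim_config(seed = 84)
  p <- simulate_parents(cfg)
  spec <- data.frame(chrom = "chr1",
                     start = c(5000L, 250000L, 700000L),
                     end = c(6000L, 251000L, 701000L),
                     direction = c("hypo", "hypo", "hyper"),
                     delta = c(0.4, 0.4, 0.4))
  sim <- simulate_sperm_methylomes(p$genes, spec, cfg, baseline = 0.55)
  got <- call_dmrs(sim$X, sim$Y)
  key <- paste(got$chrom, got$start)
  expect_true(all(paste(spec$chrom, spec$start) %in% key))
  expect_equal(nrow(got), 3)
  dir_got <- got$direction[match(paste(spec$chrom, spec$start), key)]
  expect_equal(dir_got, spec$direction)
})

test_that("window width below 50 bp is a configuration error", {
  x <- sites_df(1:10, 5, 5)
  expect_error(call_dmrs(list(x), list(x), window = 20), "50 bp")
})

test_that("DMR feature annotation follows the precedence rules", {
  genes <- data.frame(gene_id = c("gPlus", "gMinus"),
                      chrom = c("chr1", "chr1"),
                      start = c(10000L, 40000L), end = c(12000L, 42000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  dmr <- function(s, e, dir = "hyper")
    data.frame(chrom = "chr1", start = s, end = e, n_cpg = 10L,
               mean_x = 0.9, mean_y = 0.5,
               meth_diff = if (dir == "hyper") 30 else -30,
               p = 1e-5, q = 1e-4, direction = dir, stringsAsFactors = FALSE)
  dmrs <- rbind(
    dmr(9000, 10000),      # midpoint 9500, 500 bp upstream of + TSS
    dmr(10500, 11500),     # inside gPlus
    dmr(12500, 13500),     # downstream of gPlus
    dmr(42500, 43500),     # minus-strand promoter (upstream = right side)
    dmr(39000, 40000, "hypo"),  # downstream of gMinus
    dmr(500000, 501000)    # far from everything
  )
  got <- annotate_dmrs(dmrs, genes)
  expect_equal(got$annotated$feature,
               c("promoter", "genic", "downstream", "promoter",
                 "downstream", "distal_intergenic"))
  expect_equal(got$annotated$gene_id[1], "gPlus")
  expect_equal(got$annotated$gene_id[4], "gMinus")
  expect_equal(got$hyper_genes, c("gMinus", "gPlus"))
  expect_equal(got$hypo_genes, "gMinus")

  # with exons, genic splits into exon/intron and promoter still wins
  exons <- data.frame(gene_id = "gPlus", chrom = "chr1",
                      start = 10400L, end = 10800L, stringsAsFactors = FALSE)
  with_ex <- annotate_dmrs(rbind(dmr(10500, 10700), dmr(11000, 11800)),
                           genes, exons = exons)
  expect_equal(with_ex$annotated$feature, c("exon", "intron"))
})

test_that("annotation equals a quadratic precedence oracle on random DMRs", {
  set.seed(14)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:8),
                      chrom = "chr1",
                      start = sort(sample.int(80000, 8)) + c(0:7) * 10000,
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + sample(2000:6000, 8)
  genes$strand <- sample(c("+", "-"), 8, replace = TRUE)
  dmrs <- data.frame(chrom = "chr1", start = sample.int(180000, 60),
                     stringsAsFactors = FALSE)
  dmrs$end <- dmrs$start + 1000L
  dmrs$direction <- sample(c("hyper", "hypo"), 60, replace = TRUE)
  got <- annotate_dmrs(dmrs, genes)$annotated$feature

  want <- vapply(seq_len(nrow(dmrs)), function(i) {
    mid <- (dmrs$start[i] + dmrs$end[i]) %/% 2 + 1  # 1-based midpoint
    inside <- function(s, e) mid > s & mid <= e
    lab <- "distal_intergenic"
    for (j in seq_len(nrow(genes))) {
      plus <- genes$strand[j] == "+"
      dn_s <- if (plus) genes$end[j] else genes$start[j] - 2000
      if (inside(dn_s, dn_s + 2000)) lab <- "downstream"
    }
    for (j in seq_len(nrow(genes)))
      if (inside(genes$start[j], genes$end[j])) lab <- "genic"
    for (j in seq_len(nrow(genes))) {
      plus <- genes$strand[j] == "+"
      pr_s <- if (plus) genes$start[j] - 2000 else genes$end[j]
      if (inside(pr_s, pr_s + 2000)) lab <- "promoter"
    }
    lab
  }, character(1))
  expect_equal(got, want)
})

test_that("meta-profiles have 2*flank/bin bins and match a grouped average", {
  dmrs <- data.frame(chrom = "chr1", start = c(10000L, 30000L),
                     end = c(11000L, 31000L), stringsAsFactors = FALSE)
  flat <- sites_df(seq(8000, 33000, by = 40), m = 5, u = 5)
  prof <- dmr_meta_profile(dmrs, flat, flat)
  expect_equal(nrow(prof), 80)
  expect_true(all(abs(prof$level_x - 0.5) < 1e-12, na.rm = TRUE))

  # hand-computed oracle for one bin of a tiny asymmetric fixture
  x <- sites_df(c(10480, 10490, 30495), m = c(9, 1, 5), u = c(1, 9, 5))
  prof2 <- dmr_meta_profile(dmrs, x, x, flank = 2000, bin = 50)
  # DMR centers are 10500 and 30500; all three sites fall in the bin
  # covering offsets (-50, 0]
  b <- prof2$bin[prof2$offset == -50]
  expect_equal(prof2$level_x[b], mean(c(0.9, 0.1, 0.5)))
  expect_true(all(is.na(prof2$level_x[-b])))
})

test_that("profiles around planted DMRs are most extreme at the center", {
  cfg <- sim_config(seed = 85)
  p <- simulate_parents(cfg)
  spec <- data.frame(chrom = "chr1", start = 100000L, end = 101000L,
                     direction = "hypo", delta = 0.4)
  sim <- simulate_sperm_methylomes(p$genes, spec, cfg, baseline = 0.9)
  prof <- dmr_meta_profile(sim$truth, sim$X, sim$Y)
  center <- prof$offset >= -500 & prof$offset < 500
  expect_lt(mean(prof$level_y[center], na.rm = TRUE),
            mean(prof$level_y[!center], na.rm = TRUE) - 0.2)
  expect_gt(mean(prof$level_x[center], na.rm = TRUE), 0.85)
})

test_that("k-means integration separates planted expression archetypes", {
  set.seed(15)
  up <- matrix(rep(c(1, 1, 1, 9, 9, 9), each = 30), 30, 6)
  dn <- matrix(rep(c(9, 9, 9, 1, 1, 1), each = 30), 30, 6)
  fpkm <- rbind(up, dn)
  rownames(fpkm) <- c(sprintf("up%02d", 1:30), sprintf("dn%02d", 1:30))
  colnames(fpkm) <- c(paste0("X_r", 1:3), paste0("Y_r", 1:3))
  groups <- rep(c("X", "Y"), each = 3)
  de <- data.frame(gene_id = rownames(fpkm),
                   log2fc = rep(c(3, -3), each = 30),
                   padj = 1e-4, stringsAsFactors = FALSE)
  got <- integrate_with_expression(hyper_genes = rownames(fpkm),
                                   hypo_genes = rownames(fpkm),
                                   fpkm, groups, de, k = 2)
  expect_setequal(got$concordant$hyper_down, sprintf("dn%02d", 1:30))
  expect_setequal(got$concordant$hypo_up, sprintf("up%02d", 1:30))
  expect_setequal(got$concordant_degs$hypo_up_deg, sprintf("up%02d", 1:30))

  # k = 1: single cluster, centroid equals the column means of z-scores
  one <- integrate_with_expression(rownames(fpkm), character(0), fpkm,
                                   groups, de, k = 1)
  expect_true(all(one$clusters$hyper$assign == 1))
  expect_error(integrate_with_expression(rownames(fpkm)[1:3], character(0),
                                         fpkm, groups, de, k = 10),
               "exceeds")

  # hypo genes disjoint from up-DEGs leave the concordant DEG set empty
  de_ns <- transform(de, padj = 1)
  none <- integrate_with_expression(character(0), rownames(fpkm), fpkm,
                                    groups, de_ns, k = 2)
  expect_equal(length(none$concordant_degs$hypo_up_deg), 0)
})
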
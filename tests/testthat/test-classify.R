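test_that("site genotype calls follow the evidence thresholds", {
  expect_equal(call_marker_genotype(5, 4), "both")
  expect_equal(call_marker_genotype(0, 0), "uncovered")
  expect_equal(call_marker_genotype(5, 0), "maternal_only")
  expect_equal(call_marker_genotype(0, 6), "paternal_only")
  expect_equal(call_marker_genotype(3, 1), "uncovered")  # total below 5
  expect_equal(call_marker_genotype(3, 1, other_reads = 1), "maternal_only")

  # vectorized calls equal a scalar re-statement of the predicate
  set.seed(1)
  m <- rpois(1000, 3); p <- rpois(1000, 3); o <- rpois(1000, 1)
  got <- call_marker_genotype(m, p, o)
  want <- vapply(seq_along(m), function(i) {
    tot <- m[i] + p[i] + o[i]
    if (m[i] >= 2 && p[i] >= 2) "both"
    else if (m[i] >= 2 && tot >= 5) "maternal_only"
    else if (p[i] >= 2 && tot >= 5) "paternal_only"
    else "uncovered"
  }, character(1))
  expect_equal(got, want)
})

test_that("gene classification applies the zygotic > maternal > paternal priority", {
  expect_equal(classify_gene(c("maternal_only", "both")), "zygotic")
  expect_equal(classify_gene(c("maternal_only", "paternal_only")), "maternal")
  expect_equal(classify_gene(c("paternal_only", "paternal_only")), "paternal")
  expect_equal(classify_gene("uncovered"), "unobserved")
  expect_equal(classify_gene(character(0)), "unobserved")
})

test_that("replicate evidence is pooled before calling under the union rule", {
  gene_map <- data.frame(gene_id = "g1", chrom = "chr1", pos = 10L,
                         stringsAsFactors = FALSE)
  obs <- data.frame(
    sample = c("s1", "s2"), stage = "2-cell", replicate = 1:2,
    chrom = "chr1", pos = 10L,
    maternal_reads = c(5L, 0L), paternal_reads = c(0L, 5L),
    other_reads = 0L, stringsAsFactors = FALSE)
  got <- classify_stage(obs, gene_map, stages = "2-cell")
  expect_equal(got$classification$category, "zygotic")
  # majority mode sees one maternal-only and one paternal-only replicate
  maj <- classify_stage(obs, gene_map, stages = "2-cell",
                        replicate_rule = "majority")
  expect_equal(maj$classification$category, "maternal")
})

test_that("a zero-depth stage leaves every gene unobserved", {
  gene_map <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                         pos = c(10L, 20L), stringsAsFactors = FALSE)
  obs <- data.frame(sample = "s", stage = "2-cell", replicate = 1L,
                    chrom = "chr1", pos = 10L, maternal_reads = 9L,
                    paternal_reads = 0L, other_reads = 0L,
                    stringsAsFactors = FALSE)
  got <- classify_stage(obs, gene_map, stages = c("2-cell", "64-cell"))
  second <- got$counts[got$counts$stage == "64-cell", ]
  expect_equal(unlist(second[c("maternal", "zygotic", "paternal")]),
               c(maternal = 0, zygotic = 0, paternal = 0))
  expect_equal(second$unobserved, 2)
})

test_that("an undeclared stage in the observations is an input error", {
  gene_map <- data.frame(gene_id = "g1", chrom = "chr1", pos = 10L,
                         stringsAsFactors = FALSE)
  obs <- data.frame(sample = "s", stage = "gastrula", replicate = 1L,
                    chrom = "chr1", pos = 10L, maternal_reads = 9L,
                    paternal_reads = 0L, other_reads = 0L,
                    stringsAsFactors = FALSE)
  expect_error(classify_stage(obs, gene_map, stages = c("2-cell")),
               "gastrula")
})

test_that("category counts conserve the mapped gene total at every stage", {
  study <- small_embryo_study(seed = 61)
  res <- classification_agreement(study)$result
  n_mapped <- length(unique(study$gene_map$gene_id))
  sums <- rowSums(res$counts[c("maternal", "zygotic", "paternal",
                               "unobserved")])
  expect_true(all(sums == n_mapped))
})

test_that("noise-free classification recovers the programmed truth", {
  study <- small_embryo_study(seed = 62, allele_error_rate = 0)
  expect_equal(classification_agreement(study, "XX")$agreement, 1)
  expect_equal(classification_agreement(study, "XY")$agreement, 1)
})

test_that("snp composition percentages sum to 100 over covered sites", {
  toy <- data.frame(stage = "bud",
                    chrom = "chr1", pos = 1:10,
                    call = c(rep("maternal_only", 6), rep("both", 3),
                             "paternal_only"), stringsAsFactors = FALSE)
  got <- snp_composition(toy)
  expect_equal(got$pct_maternal, 60)
  expect_equal(got$pct_zygotic, 30)
  expect_equal(got$pct_paternal, 10)

  study <- small_embryo_study(seed = 63)
  res <- classification_agreement(study)$result
  comp <- snp_composition(res$site_calls)
  expect_equal(comp$pct_maternal + comp$pct_zygotic + comp$pct_paternal,
               rep(100, nrow(comp)))
  # counting oracle on one stage
  st <- comp$stage[1]
  cl <- res$site_calls$call[res$site_calls$stage == st]
  expect_equal(comp$pct_maternal[1], 100 * sum(cl == "maternal_only") /
                 length(cl))
})

test_that("transition detection finds the largest zygotic jump", {
  stages <- c("2-cell", "64-cell", "high-blastocyst", "low-blastocyst", "bud")
  got <- detect_transition(stages, c(10, 12, 15, 400, 450),
                           c(500, 480, 470, 90, 60))
  expect_equal(unname(got$zygotic_up),
               c("high-blastocyst", "low-blastocyst"))
  expect_equal(unname(got$maternal_down),
               c("high-blastocyst", "low-blastocyst"))
  expect_null(detect_transition(stages, rep(7, 5))$zygotic_up)

  # argmax-of-differences oracle on random series, ties to the earlier pair
  set.seed(2)
  for (i in 1:20) {
    z <- sample(0:30, 5, replace = TRUE)
    got <- detect_transition(stages, z)
    d <- diff(z)
    if (all(d <= 0)) {
      expect_null(got$zygotic_up)
    } else {
      expect_equal(unname(got$zygotic_up[1]), stages[which.max(d)])
    }
  }
})

test_that("paternal-zygotic coupling reports Pearson correlation", {
  z <- c(0, 0, 10, 400, 420)
  expect_equal(paternal_zygotic_coupling(0.5 * z, z), 1.0)
  expect_lt(paternal_zygotic_coupling(c(5, 4, 3, 2, 1), 1:5), 0)
  expect_warning(r <- paternal_zygotic_coupling(rep(2, 5), z), "variance")
  expect_true(is.na(r))
})

test_that("sex comparison matches the pooled-variance t-test by hand", {
  same <- compare_sexes(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  got <- compare_sexes(c(1, 2, 3), c(4, 5, 6))
  sp <- sqrt((2 * var(c(1, 2, 3)) + 2 * var(c(4, 5, 6))) / 4)
  t_hand <- (2 - 5) / (sp * sqrt(2 / 3))
  expect_equal(got$t, t_hand)
  expect_equal(got$p, 2 * pt(-abs(t_hand), 4))
  expect_equal(got$stars, "*")
  expect_error(compare_sexes(1, c(2, 3)), "replicates")
})

test_that("the sex-comparison test holds its nominal size under the null", {
  set.seed(3)
  reject <- replicate(2000, {
    compare_sexes(rnorm(3), rnorm(3))$p < 0.05
  })
  expect_lt(abs(mean(reject) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
})
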
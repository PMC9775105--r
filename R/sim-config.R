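#' Configuration for the synthetic MZT study generator
#'
#' Bundles every tunable of the synthetic-data generator into a validated
#' list. The defaults encode the study design the generator emulates: a
#' hybrid cross between two homozygous-divergent parents, a five-stage
#' early-embryo series in which maternal transcripts decay multiplicatively
#' while zygotic and paternal programs switch on at the high- to
#' low-blastocyst transition, and three replicates per stage and cross.
#'
#' @param n_chromosomes Number of simulated chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Total number of genes, spread evenly over chromosomes.
#' @param gene_length Length of each gene interval in bp.
#' @param n_snps_per_gene Mean number of informative markers per gene. The
#'   total number of planted informative sites is exactly
#'   `round(n_genes * n_snps_per_gene)`, distributed at random over genes,
#'   so individual genes may carry zero markers.
#' @param stages Ordered character vector of stage labels.
#' @param activation_stage Stage at which the zygotic and paternal programs
#'   switch on. Must be one of `stages`.
#' @param maternal_decay_rate Multiplicative per-stage survival factor for
#'   maternal transcript abundance, in (0, 1]. 0.4 means each stage retains
#'   40 percent of the previous stage's maternal signal.
#' @param n_replicates Replicates per stage per cross.
#' @param depth Mean reads per expressed marker site per replicate.
#' @param allele_error_rate Probability that a read reports the wrong
#'   parental allele.
#' @param dispersion Negative-binomial dispersion for simulated counts.
#' @param expr_mean Mean expression count of a fully expressed gene.
#' @param frac_maternal,frac_zygotic,frac_paternal,frac_constitutive
#'   Fractions of genes given the decaying-maternal, zygotic-activation,
#'   paternal-activation and constitutive expression programs; the
#'   remainder stays silent throughout the series. Constitutive genes
#'   (off by default) are expressed at a constant level, carry maternal
#'   transcripts before the activation stage and biparental transcripts
#'   from it onwards (the classic maternal-zygotic class); enable them
#'   when an analysis relies on median-of-ratios normalization across
#'   stages, which assumes most expressed genes are stable.
#' @param pgc_fraction Fraction of maternal/zygotic genes whose expression
#'   profile is tied to a PGC marker-gene archetype.
#' @param seed Integer seed; all simulators derive their random streams
#'   from it so that identical configurations give identical output.
#'
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 7)
#' cfg$activation_stage
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 1e6,
                       n_genes = 200,
                       gene_length = 2000,
                       n_snps_per_gene = 3,
                       stages = c("2-cell", "64-cell", "high-blastocyst",
                                  "low-blastocyst", "bud"),
                       activation_stage = "low-blastocyst",
                       maternal_decay_rate = 0.4,
                       n_replicates = 3,
                       depth = 30,
                       allele_error_rate = 0.002,
                       dispersion = 0.1,
                       expr_mean = 200,
                       frac_maternal = 0.5,
                       frac_zygotic = 0.3,
                       frac_paternal = 0.06,
                       frac_constitutive = 0,
                       pgc_fraction = 0.1,
                       seed = 1L) {
  stopifnot(
    length(stages) >= 1, !anyDuplicated(stages),
    is.character(stages),
    n_chromosomes >= 1, chrom_length > 0, n_genes >= 1, gene_length > 0,
    n_snps_per_gene >= 0, n_replicates >= 1, depth > 0, dispersion > 0,
    expr_mean > 0
  )
  if (!activation_stage %in% stages)
    stop("`activation_stage` must be one of `stages`", call. = FALSE)
  if (maternal_decay_rate <= 0 || maternal_decay_rate > 1)
    stop("`maternal_decay_rate` must lie in (0, 1]", call. = FALSE)
  if (allele_error_rate < 0 || allele_error_rate > 1)
    stop("`allele_error_rate` must lie in [0, 1]", call. = FALSE)
  for (f in c(frac_maternal, frac_zygotic, frac_paternal,
              frac_constitutive, pgc_fraction))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (frac_maternal + frac_zygotic + frac_paternal + frac_constitutive > 1)
    stop("program fractions must sum to at most 1", call. = FALSE)
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    n_snps_per_gene = n_snps_per_gene,
    stages = stages,
    activation_stage = activation_stage,
    maternal_decay_rate = maternal_decay_rate,
    n_replicates = as.integer(n_replicates),
    depth = depth,
    allele_error_rate = allele_error_rate,
    dispersion = dispersion,
    expr_mean = expr_mean,
    frac_maternal = frac_maternal,
    frac_zygotic = frac_zygotic,
    frac_paternal = frac_paternal,
    frac_constitutive = frac_constitutive,
    pgc_fraction = pgc_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}
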
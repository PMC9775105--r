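#' Stage-profile archetypes of the PGC marker genes
#'
#' Deterministic per-stage relative abundance archetypes for the five PGC
#' marker genes (sox2, nanog, ddx4, dnd1, nanos3) used to seed
#' marker-correlated gene profiles in the generator. The self-renewal
#' markers follow a U-shaped maternal-then-zygotic profile; the formation
#' and migration markers decay and recover later, mirroring germ-plasm
#' transcripts that are maternally deposited and re-expressed around
#' zygotic genome activation.
#'
#' @param stages Ordered stage labels.
#' @return A numeric matrix, one row per marker gene, one column per stage.
#' @export
pgc_marker_archetypes <- function(stages) {
  s <- length(stages)
  t <- seq(0, 1, length.out = s)
  prof <- rbind(
    sox2   = 1.0 - 0.8 * t + 1.2 * t^2,
    nanog  = 1.2 - 1.0 * t + 1.4 * t^2,
    ddx4   = 1.0 * exp(-2 * t) + 0.8 * t^3,
    dnd1   = 0.8 * exp(-1.5 * t) + 0.6 * t^2,
    nanos3 = 1.1 * exp(-2.5 * t) + 1.0 * t^4
  )
  colnames(prof) <- stages
  prof
}

#' Simulate an allele-resolved embryo stage series for two crosses
#'
#' Realizes the maternal-to-zygotic transition on the simulated gene set:
#' maternal-program genes start fully expressed and decay multiplicatively
#' each stage, zygotic- and paternal-program genes are silent before the
#' activation stage and fully expressed from it onwards. At every
#' informative marker of an expressed gene, reads are drawn from a
#' negative binomial with the configured mean and dispersion; maternal
#' genes emit maternal-allele reads (each read flipped with probability
#' `allele_error_rate`), zygotic genes emit both alleles with expected
#' fraction one half, paternal genes emit paternal-allele reads. A
#' per-cross expression count matrix with the same stage program and the
#' full ground truth are returned alongside.
#'
#' @param parents Output of [simulate_parents()].
#' @param annotation Gene annotation; defaults to the annotation carried by
#'   `parents`.
#' @param config The [sim_config()] used for `parents`.
#'
#' @return A list of class `"mzt_embryo_sim"` with elements
#'   `allele_counts` (data frame: `sample`, `cross`, `stage`, `replicate`,
#'   `chrom`, `pos`, `maternal_reads`, `paternal_reads`, `other_reads`),
#'   `expression` (list of per-cross count matrices, genes x samples,
#'   including the five PGC marker transcripts), `gene_lengths`,
#'   `truth` (list: `categories` with per gene x stage x cross category in
#'   maternal/zygotic/paternal/silent, `pgc` flags, `programs`), `stages`
#'   and `config`.
#' @export
simulate_embryo_series <- function(parents, annotation = parents$genes, config) {
  stopifnot(inherits(parents, "mzt_parents"), inherits(config, "sim_config"))
  if (!identical(sort(config$stages), sort(unique(config$stages))) ||
      length(config$stages) < 1)
    stop("configuration error: invalid stage list", call. = FALSE)
  set.seed(config$seed + 1000L)

  genes <- annotation
  ng <- nrow(genes)
  stages <- config$stages
  s_act <- match(config$activation_stage, stages)

  program <- .assign_programs(ng, config)
  names(program) <- genes$gene_id

  # relative expression level per gene x stage
  lvl <- matrix(0, ng, length(stages), dimnames = list(genes$gene_id, stages))
  mat <- program == "maternal"
  lvl[mat, ] <- rep(config$maternal_decay_rate^(seq_along(stages) - 1),
                    each = sum(mat))
  on_after <- seq_along(stages) >= s_act
  lvl[program == "zygotic", on_after] <- 1
  lvl[program == "paternal", on_after] <- 1
  lvl[program == "constitutive", ] <- 1

  truth_cat <- .truth_categories(program, lvl, stages, s_act)

  # PGC-correlated profiles for a slice of the expressed genes
  arch <- pgc_marker_archetypes(stages)
  eligible <- which(program %in% c("maternal", "zygotic"))
  n_pgc <- round(config$pgc_fraction * length(eligible))
  pgc_idx <- if (n_pgc > 0) sample(eligible, n_pgc) else integer(0)
  pgc_marker <- rep(NA_character_, ng)
  pgc_marker[pgc_idx] <- sample(rownames(arch), length(pgc_idx), replace = TRUE)

  crosses <- c("XX", "XY")
  allele_counts <- do.call(rbind, lapply(crosses, function(cr)
    .draw_allele_counts(parents$markers, program, lvl, cr, config, s_act)))
  rownames(allele_counts) <- NULL

  expression <- lapply(crosses, function(cr)
    .draw_expression(genes, program, lvl, pgc_marker, arch, cr, config))
  names(expression) <- crosses

  gene_lengths <- c(stats::setNames(genes$end - genes$start, genes$gene_id),
                    stats::setNames(rep(config$gene_length, nrow(arch)),
                                    rownames(arch)))

  truth <- list(
    categories = truth_cat,
    pgc = data.frame(gene_id = genes$gene_id,
                     pgc_flag = seq_len(ng) %in% pgc_idx,
                     marker = pgc_marker, stringsAsFactors = FALSE),
    programs = data.frame(gene_id = genes$gene_id, program = unname(program),
                          stringsAsFactors = FALSE)
  )

  structure(
    list(allele_counts = allele_counts, expression = expression,
         gene_lengths = gene_lengths, truth = truth, stages = stages,
         config = config),
    class = "mzt_embryo_sim"
  )
}

.assign_programs <- function(ng, config) {
  n_m <- round(config$frac_maternal * ng)
  n_z <- round(config$frac_zygotic * ng)
  n_p <- round(config$frac_paternal * ng)
  n_c <- round(config$frac_constitutive * ng)
  n_s <- ng - n_m - n_z - n_p - n_c
  if (n_s < 0) stop("program fractions exceed the gene count", call. = FALSE)
  sample(rep(c("maternal", "zygotic", "paternal", "constitutive", "silent"),
             c(n_m, n_z, n_p, n_c, n_s)))
}

# category a perfect allele-resolved classifier would report: constitutive
# genes look maternal before activation and zygotic (biparental) after
.truth_categories <- function(program, lvl, stages, s_act) {
  grid <- expand.grid(gene_id = names(program), stage = stages,
                      cross = c("XX", "XY"), stringsAsFactors = FALSE)
  cat <- program[grid$gene_id]
  s_idx <- match(grid$stage, stages)
  cat[cat == "constitutive"] <-
    ifelse(s_idx[cat == "constitutive"] >= s_act, "zygotic", "maternal")
  silent <- lvl[cbind(match(grid$gene_id, rownames(lvl)), s_idx)] == 0
  cat[silent] <- "silent"
  data.frame(grid, category = unname(cat), stringsAsFactors = FALSE)
}

.draw_allele_counts <- function(markers, program, lvl, cross, config, s_act) {
  nr <- config$n_replicates
  stages <- colnames(lvl)
  prog_m <- program[markers$gene_id]
  rows <- expand.grid(m = seq_len(nrow(markers)), stage = seq_along(stages),
                      rep = seq_len(nr))
  mu <- config$depth * lvl[cbind(match(markers$gene_id[rows$m], rownames(lvl)),
                                 rows$stage)]
  keep <- mu > 0
  rows <- rows[keep, ]; mu <- mu[keep]
  total <- stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  pos <- total > 0
  rows <- rows[pos, ]; total <- total[pos]
  pg <- prog_m[rows$m]
  err <- config$allele_error_rate
  biparental <- pg == "zygotic" | (pg == "constitutive" & rows$stage >= s_act)
  p_mat <- ifelse(biparental, 0.5, ifelse(pg == "paternal", err, 1 - err))
  maternal_reads <- stats::rbinom(length(total), total, p_mat)
  paternal_reads <- total - maternal_reads
  out <- data.frame(
    sample = paste(cross, stages[rows$stage], paste0("r", rows$rep), sep = "_"),
    cross = cross, stage = stages[rows$stage], replicate = rows$rep,
    chrom = markers$chrom[rows$m], pos = markers$pos[rows$m],
    maternal_reads = maternal_reads, paternal_reads = paternal_reads,
    other_reads = 0L, stringsAsFactors = FALSE
  )
  out[order(out$stage, out$replicate, out$chrom, out$pos), ]
}

.draw_expression <- function(genes, program, lvl, pgc_marker, arch, cross, config) {
  nr <- config$n_replicates
  stages <- colnames(lvl)
  mu <- config$expr_mean * lvl
  has_arch <- !is.na(pgc_marker)
  if (any(has_arch)) {
    scale <- config$expr_mean * exp(stats::runif(sum(has_arch), -0.5, 0.5))
    mu[has_arch, ] <- arch[pgc_marker[has_arch], , drop = FALSE] * scale
  }
  mu <- rbind(mu, arch * config$expr_mean)  # marker transcripts themselves
  samples <- as.vector(t(outer(stages, paste0("r", seq_len(nr)), paste,
                               sep = "_")))
  samples <- paste(cross, samples, sep = "_")
  mu_full <- mu[, rep(seq_along(stages), each = nr), drop = FALSE]
  counts <- matrix(
    stats::rnbinom(length(mu_full), mu = mu_full, size = 1 / config$dispersion),
    nrow = nrow(mu_full),
    dimnames = list(rownames(mu), samples)
  )
  counts
}
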
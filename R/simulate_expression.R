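# Synthetic aneuploid heart expression matrices.
#
# The generator emulates an RMA-normalized log2 gene x sample matrix for the
# four genotypes (wt, Ts65Dn, Ms5Yah, Ts65Dn/Ms5Yah): a ~1.5-fold primary
# dosage effect on triplicated genes, ~0.5-fold on monosomic genes,
# multiplicative log-normal measurement noise, a background of unaffected
# genes (a configurable fraction of which carry trans effects), and a
# below-threshold stratum of genes not expressed in adult heart.

EXPR_GENOTYPES <- c("wt", "Ts65Dn", "Ms5Yah", "Ts65Dn/Ms5Yah")

#' Specify a synthetic expression experiment
#'
#' The simulated genome carries a triplicated segment on Mmu16 (the
#' trisomic minichromosome interval), a sub-interval of it deleted in the
#' Ms5Yah monosomy (so restored to two copies in the compound genotype), and
#' a triplicated centromeric Mmu17 segment; all remaining genes are spread
#' over the other chromosomes at two copies in every genotype.
#'
#' @param n_genes total number of genes.
#' @param n_mmu16_tri genes on the triplicated Mmu16 segment.
#' @param n_app_runx1 genes of the Mmu16 segment lying in the deleted
#'   App-Runx1 interval (monosomic in Ms5Yah, restored in the compound).
#' @param n_mmu17_tri genes on the triplicated centromeric Mmu17 segment.
#' @param primary_effect expression ratio for three copies (default 1.5).
#' @param monosomy_effect expression ratio for one copy (default 0.5).
#' @param noise_cv multiplicative measurement noise, as a coefficient of
#'   variation on the linear scale (default 0.1).
#' @param n_replicates arrays per genotype (default 5).
#' @param frac_expressed fraction of genes whose wild-type signal exceeds the
#'   expression threshold (default 0.406).
#' @param fraction_trans_effect fraction of expressed background genes given
#'   a trans (copy-number-independent) effect in each aneuploid genotype.
#' @param trans_effect_range range the trans-effect ratios are drawn from,
#'   uniformly on the log scale.
#' @param seed integer seed.
#' @return an `expression_sim_spec` list.
#' @export
expression_sim_spec <- function(n_genes = 2000,
                                n_mmu16_tri = 100,
                                n_app_runx1 = 40,
                                n_mmu17_tri = 30,
                                primary_effect = 1.5,
                                monosomy_effect = 0.5,
                                noise_cv = 0.1,
                                n_replicates = 5,
                                frac_expressed = 0.406,
                                fraction_trans_effect = 0.01,
                                trans_effect_range = c(0.6, 1.7),
                                seed) {
  if (!(primary_effect > 1 && monosomy_effect < 1 && monosomy_effect > 0)) {
    stop("need primary_effect > 1 > monosomy_effect > 0")
  }
  if (n_app_runx1 > n_mmu16_tri) {
    stop("the App-Runx1 interval is contained in the Mmu16 trisomic segment")
  }
  if (n_genes < n_mmu16_tri + n_mmu17_tri) stop("n_genes too small")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (missing(seed)) stop("seed is required")
  structure(as.list(environment()), class = "expression_sim_spec")
}

#' Simulate an annotated aneuploid expression matrix
#'
#' Per gene g and genotype j, the expected ratio versus wild type is the
#' primary dosage effect for three copies, the monosomy effect for one copy
#' and 1 for two copies; trans-effect genes draw their ratio from the
#' configured distribution regardless of copy number. Observed log2 values
#' are `log2(baseline * ratio)` plus independent Gaussian noise whose SD
#' derives from the linear-scale coefficient of variation
#' (`sd_log2 = sqrt(log(1 + cv^2)) / log(2)`).
#'
#' @param spec an [expression_sim_spec()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"log2"`, per-sample `genotype`, and per-gene annotation: chromosome,
#'   position, region, copy number per genotype (`cn_<genotype>`),
#'   ground-truth ratios (`true_ratio_<genotype>`) and `expressed_truth`.
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  n <- spec$n_genes
  region <- rep("background", n)
  i16 <- seq_len(spec$n_mmu16_tri)
  region[i16] <- "mmu16_tri"
  if (spec$n_app_runx1 > 0) {
    # App-Runx1 interval sits inside the Mmu16 trisomic segment
    region[seq(31, length.out = spec$n_app_runx1)] <- "app_runx1"
  }
  i17 <- seq(spec$n_mmu16_tri + 1, length.out = spec$n_mmu17_tri)
  region[i17] <- "mmu17_tri"

  chrom <- character(n)
  chrom[region %in% c("mmu16_tri", "app_runx1")] <- "16"
  chrom[region == "mmu17_tri"] <- "17"
  bg <- which(region == "background")
  chrom[bg] <- as.character(rep_len(c(1:15, 18, 19, "X"), length(bg)))
  position <- stats::ave(seq_len(n), chrom, FUN = seq_along) * 1e5

  cn <- matrix(2L, n, 4, dimnames = list(NULL, EXPR_GENOTYPES))
  tri <- region %in% c("mmu16_tri", "app_runx1", "mmu17_tri")
  cn[tri, "Ts65Dn"] <- 3L
  cn[region == "app_runx1", "Ms5Yah"] <- 1L
  cn[tri, "Ts65Dn/Ms5Yah"] <- 3L
  cn[region == "app_runx1", "Ts65Dn/Ms5Yah"] <- 2L  # deletion restores 2 copies

  expressed <- stats::runif(n) < spec$frac_expressed
  baseline_log2 <- ifelse(expressed, stats::runif(n, 6, 12),
                          stats::runif(n, 2, 5.5))

  ratio <- matrix(1, n, 4, dimnames = list(NULL, EXPR_GENOTYPES))
  ratio[cn == 3L] <- spec$primary_effect
  ratio[cn == 1L] <- spec$monosomy_effect

  n_trans <- round(spec$fraction_trans_effect * sum(expressed & region == "background"))
  trans_idx <- integer(0)
  if (n_trans > 0) {
    trans_idx <- sample(which(expressed & region == "background"), n_trans)
    lo <- log(spec$trans_effect_range[1]); hi <- log(spec$trans_effect_range[2])
    for (g in setdiff(EXPR_GENOTYPES, "wt")) {
      ratio[trans_idx, g] <- exp(stats::runif(n_trans, lo, hi))
    }
  }

  sd_log2 <- sqrt(log(1 + spec$noise_cv^2)) / log(2)
  samples <- unlist(lapply(EXPR_GENOTYPES, function(g) {
    paste0(gsub("/", "_", g), "_", seq_len(spec$n_replicates))
  }))
  genotype <- rep(EXPR_GENOTYPES, each = spec$n_replicates)
  mat <- matrix(0, n, length(samples), dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    mu <- baseline_log2 + log2(ratio[, genotype[j]])
    mat[, j] <- mu + if (sd_log2 > 0) stats::rnorm(n, 0, sd_log2) else 0
  }

  gene <- sprintf("gene%04d", seq_len(n))
  rownames(mat) <- gene
  rd <- S4Vectors::DataFrame(
    gene = gene, chromosome = chrom, position = position, region = region,
    expressed_truth = expressed, trans_effect = seq_len(n) %in% trans_idx
  )
  for (g in EXPR_GENOTYPES) {
    rd[[paste0("cn_", gsub("/", "_", g))]] <- cn[, g]
    rd[[paste0("true_ratio_", gsub("/", "_", g))]] <- ratio[, g]
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = mat),
    rowData = rd,
    colData = S4Vectors::DataFrame(sample = samples, genotype = genotype,
                                   row.names = samples),
    metadata = list(sim_spec = spec)
  )
}
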
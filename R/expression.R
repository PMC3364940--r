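# Gene-dosage expression analysis: expression-threshold filtering,
# fold-change computation versus wild type, the seven genotype-pattern
# dosage groups, chromosome/region summaries, a per-gene ANOVA screen and
# hierarchical clustering.

DOSAGE_GENOTYPES <- c("Ts65Dn", "Ms5Yah", "Ts65Dn/Ms5Yah")

.se_log2 <- function(se) {
  stopifnot(methods::is(se, "SummarizedExperiment"))
  if ("log2" %in% SummarizedExperiment::assayNames(se)) {
    SummarizedExperiment::assay(se, "log2")
  } else {
    SummarizedExperiment::assay(se, 1)
  }
}

.se_genotype <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  if (!"genotype" %in% names(cd)) stop("colData must carry a genotype column")
  as.character(cd$genotype)
}

#' Filter genes by the wild-type expression threshold
#'
#' Keeps genes whose mean wild-type log2 signal exceeds the threshold
#' (default 5.644, i.e. a raw fluorescence of 50); the rest are flagged
#' `not_expressed`.
#'
#' @param se a `SummarizedExperiment` of log2 values with per-sample
#'   `genotype` annotation.
#' @param threshold_log2 expression threshold on the log2 scale.
#' @param reference_genotype genotype defining expression (default `"wt"`).
#' @return the expressed-gene subset; the full per-gene logical call is in
#'   `metadata(.)$expressed_call` and dropped genes in
#'   `metadata(.)$not_expressed`.
#' @export
filter_expressed <- function(se, threshold_log2 = 5.644,
                             reference_genotype = "wt") {
  gt <- .se_genotype(se)
  if (!any(gt == reference_genotype)) {
    stop("no samples of the reference genotype: ", reference_genotype)
  }
  m <- .se_log2(se)
  keep <- rowMeans(m[, gt == reference_genotype, drop = FALSE]) > threshold_log2
  out <- se[keep, ]
  md <- S4Vectors::metadata(out)
  md$expressed_call <- stats::setNames(keep, rownames(m))
  md$not_expressed <- rownames(m)[!keep]
  S4Vectors::metadata(out) <- md
  out
}

#' Per-gene fold-change ratios versus a reference genotype
#'
#' The ratio for gene g and genotype j is
#' `2^(mean log2(j) - mean log2(reference))`; a pooled-variance Student
#' t-test against the reference is reported per gene and genotype.
#'
#' @param se a `SummarizedExperiment` of log2 values.
#' @param reference_genotype reference label (default `"wt"`).
#' @return data.frame with gene annotation (chromosome/position/region when
#'   present) and, per non-reference genotype `G`, columns `ratio_G`, `p_G`
#'   and `sig_G` (p < 0.05).
#' @export
fold_change <- function(se, reference_genotype = "wt") {
  gt <- .se_genotype(se)
  if (!any(gt == reference_genotype)) {
    stop("missing reference genotype: ", reference_genotype)
  }
  m <- .se_log2(se)
  ref <- m[, gt == reference_genotype, drop = FALSE]
  mu_ref <- rowMeans(ref)
  v_ref <- apply(ref, 1, stats::var)
  n_ref <- ncol(ref)
  out <- data.frame(gene = rownames(m), stringsAsFactors = FALSE)
  rd <- SummarizedExperiment::rowData(se)
  for (col in intersect(c("chromosome", "position", "region"), names(rd))) {
    out[[col]] <- rd[[col]]
  }
  for (gname in setdiff(unique(gt), reference_genotype)) {
    gm <- m[, gt == gname, drop = FALSE]
    mu <- rowMeans(gm)
    key <- gsub("/", "_", gname)
    out[[paste0("ratio_", key)]] <- 2^(mu - mu_ref)
    if (ncol(gm) >= 2 && n_ref >= 2) {
      v <- apply(gm, 1, stats::var)
      df <- n_ref + ncol(gm) - 2
      sp2 <- ((n_ref - 1) * v_ref + (ncol(gm) - 1) * v) / df
      tt <- (mu - mu_ref) / sqrt(sp2 * (1 / n_ref + 1 / ncol(gm)))
      pp <- 2 * stats::pt(-abs(tt), df)
      pp[sp2 == 0 & mu == mu_ref] <- 1
      pp[sp2 == 0 & mu != mu_ref] <- 0
    } else {
      pp <- rep(NA_real_, nrow(m))
    }
    out[[paste0("p_", key)]] <- pp
    out[[paste0("sig_", key)]] <- !is.na(pp) & pp < 0.05
  }
  out
}

#' Map a direction triple to a dosage group
#'
#' Pure function of the (Ts65Dn, Ms5Yah, Ts65Dn/Ms5Yah) direction calls
#' (`"up"`, `"down"`, `"normal"`). Groups are defined by the subset of
#' genotypes deregulated: G1 = Ts65Dn and the compound (trisomy-driven,
#' not compensated), G2 = Ts65Dn and Ms5Yah with the compound normal
#' (dosage-compensated), G3 = Ts65Dn only, G4 = Ms5Yah only, G5 = Ms5Yah
#' and the compound, G6 = all three, G7 = compound only; no deregulation is
#' `"unclassified"`. The 27 possible triples are covered totally and
#' without overlap.
#'
#' @param ts,ms,tsms direction calls for Ts65Dn, Ms5Yah and the compound.
#' @return group label `"G1"`..`"G7"` or `"unclassified"`. Vectorized.
#' @examples
#' dosage_group("up", "down", "normal")  # "G2" (compensated)
#' dosage_group("up", "normal", "up")    # "G1" (persistent)
#' @export
dosage_group <- function(ts, ms, tsms) {
  ok <- c("up", "down", "normal")
  if (!all(c(ts, ms, tsms) %in% ok)) stop("directions must be up/down/normal")
  key <- paste0(as.integer(ts != "normal"), as.integer(ms != "normal"),
                as.integer(tsms != "normal"))
  map <- c("000" = "unclassified", "100" = "G3", "010" = "G4", "001" = "G7",
           "101" = "G1", "110" = "G2", "011" = "G5", "111" = "G6")
  unname(map[key])
}

#' Classify genes into dosage groups from fold-change ratios
#'
#' Direction calls per aneuploid genotype: `up` when ratio > `fc_hi`
#' (default 1.2), `down` when ratio < `fc_lo` (default 0.8), `normal`
#' otherwise; when `require_significance` is set, a call beyond the
#' threshold additionally needs the per-genotype significance flag, so an
#' unstarred excursion is treated as normal. Groups follow [dosage_group()].
#'
#' @param fc a [fold_change()] data.frame (columns `ratio_Ts65Dn`,
#'   `ratio_Ms5Yah`, `ratio_Ts65Dn_Ms5Yah`, and `sig_*` when significance
#'   is required).
#' @param fc_hi,fc_lo fold-change thresholds.
#' @param require_significance require the significance flag in addition to
#'   the threshold (default FALSE).
#' @return `fc` with appended `dir_*` columns and `group`.
#' @export
classify_dosage_group <- function(fc, fc_hi = 1.2, fc_lo = 0.8,
                                  require_significance = FALSE) {
  keys <- c(Ts65Dn = "Ts65Dn", Ms5Yah = "Ms5Yah",
            `Ts65Dn/Ms5Yah` = "Ts65Dn_Ms5Yah")
  need <- paste0("ratio_", keys)
  if (!all(need %in% names(fc))) {
    stop("missing genotype ratio column(s): ",
         paste(setdiff(need, names(fc)), collapse = ", "))
  }
  dirs <- lapply(keys, function(k) {
    r <- fc[[paste0("ratio_", k)]]
    d <- ifelse(r > fc_hi, "up", ifelse(r < fc_lo, "down", "normal"))
    if (require_significance) {
      sigcol <- paste0("sig_", k)
      if (!sigcol %in% names(fc)) stop("missing significance column: ", sigcol)
      d[!fc[[sigcol]]] <- "normal"
    }
    d
  })
  fc$dir_Ts65Dn <- dirs[[1]]
  fc$dir_Ms5Yah <- dirs[[2]]
  fc$dir_Ts65Dn_Ms5Yah <- dirs[[3]]
  fc$group <- dosage_group(dirs[[1]], dirs[[2]], dirs[[3]])
  fc
}

#' Per-chromosome mean expression ratios
#'
#' @param fc a [fold_change()] data.frame carrying a `chromosome` column.
#' @param by optional additional grouping column (e.g. `"region"`).
#' @return data.frame: chromosome (and `by` level), genotype, n, mean
#'   ratio, sem.
#' @export
chromosome_profile <- function(fc, by = NULL) {
  stopifnot("chromosome" %in% names(fc))
  ratio_cols <- grep("^ratio_", names(fc), value = TRUE)
  grp <- if (is.null(by)) fc$chromosome else paste(fc$chromosome, fc[[by]])
  out <- list()
  for (rc in ratio_cols) {
    agg <- tapply(fc[[rc]], grp, function(x) {
      c(n = length(x), mean = mean(x), sem = stats::sd(x) / sqrt(length(x)))
    })
    out[[rc]] <- data.frame(
      group = names(agg), genotype = sub("^ratio_", "", rc),
      n = vapply(agg, `[[`, 0, "n"),
      mean_ratio = vapply(agg, `[[`, 0, "mean"),
      sem = vapply(agg, `[[`, 0, "sem"), row.names = NULL)
  }
  do.call(rbind, out)
}

#' Summary of a trisomic region's expressed genes
#'
#' @param fc a [fold_change()] data.frame.
#' @param rows logical or integer selector of the region's genes (e.g.
#'   `fc$region == "mmu16_tri"`).
#' @param genotype genotype whose ratios are summarized (default Ts65Dn).
#' @param fc_hi up-regulation threshold (default 1.2).
#' @return list: `n_expressed`, `fraction_up` (ratio > fc_hi), `mean_fc`,
#'   `sem`, `range`.
#' @export
trisomic_summary <- function(fc, rows, genotype = "Ts65Dn", fc_hi = 1.2) {
  r <- fc[rows, paste0("ratio_", gsub("/", "_", genotype))]
  if (length(r) == 0) stop("empty region")
  list(n_expressed = length(r),
       fraction_up = mean(r > fc_hi),
       mean_fc = mean(r),
       sem = stats::sd(r) / sqrt(length(r)),
       range = range(r))
}

#' Per-gene one-way ANOVA screen across genotypes
#'
#' Classical fixed-effects one-way ANOVA per gene; genes with p below
#' `alpha` are selected, and Tukey HSD post-hoc pairs are reported for the
#' selected genes. Genes without at least two genotypes with two replicates
#' are skipped (and listed in the `skipped` attribute).
#'
#' @param se a `SummarizedExperiment` of log2 values.
#' @param alpha selection threshold on the ANOVA p-value (default 0.1).
#' @param posthoc compute Tukey HSD pairs for selected genes (default TRUE).
#' @return data.frame gene, F, df1, df2, p, selected; Tukey tables in
#'   `attr(., "tukey")`, skipped genes in `attr(., "skipped")`.
#' @export
anova_screen <- function(se, alpha = 0.1, posthoc = TRUE) {
  gt <- .se_genotype(se)
  m <- .se_log2(se)
  tab <- table(gt)
  usable_groups <- names(tab)[tab >= 2]
  if (length(usable_groups) < 2) stop("need >= 2 genotypes with >= 2 replicates")
  skipped <- character(0)
  if (length(usable_groups) < length(tab)) {
    message("dropping genotypes without replication: ",
            paste(setdiff(names(tab), usable_groups), collapse = ", "))
  }
  sel <- gt %in% usable_groups
  m <- m[, sel, drop = FALSE]
  gt <- gt[sel]
  f <- factor(gt)
  k <- nlevels(f)
  N <- ncol(m)
  # vectorized one-way ANOVA over genes
  gm <- vapply(levels(f), function(l) rowMeans(m[, f == l, drop = FALSE]),
               numeric(nrow(m)))
  ns <- as.vector(table(f))
  grand <- rowMeans(m)
  ssb <- as.vector(sweep(gm, 1, grand)^2 %*% ns)  # sum_j n_j (mean_j - grand)^2
  ssw <- rowSums((m - gm[, as.integer(f), drop = FALSE])^2)
  df1 <- k - 1L; df2 <- N - k
  fstat <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1
  res <- data.frame(gene = rownames(m), F = fstat, df1 = df1, df2 = df2,
                    p = p, selected = !is.na(p) & p < alpha,
                    row.names = NULL)
  if (posthoc && any(res$selected)) {
    tuk <- lapply(which(res$selected), function(i) {
      fit <- stats::aov(m[i, ] ~ f)
      as.data.frame(stats::TukeyHSD(fit)$f)
    })
    names(tuk) <- res$gene[res$selected]
    attr(res, "tukey") <- tuk
  }
  attr(res, "skipped") <- skipped
  res
}

#' Hierarchical clustering of genes and samples
#'
#' Mirrors the array-clustering convention: per-gene mean-centering
#' (expression relative to the mean of all arrays), Euclidean distance,
#' complete linkage, applied to rows (genes) and columns (samples).
#'
#' @param se a `SummarizedExperiment` (or plain matrix) of log2 values.
#' @return list with `gene_hclust`, `sample_hclust`, the leaf orders, and
#'   Newick strings `gene_newick` / `sample_newick`.
#' @export
hierarchical_cluster <- function(se) {
  m <- if (is.matrix(se)) se else .se_log2(se)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 genes and >= 2 samples")
  centered <- m - rowMeans(m)
  gh <- stats::hclust(stats::dist(centered), method = "complete")
  sh <- stats::hclust(stats::dist(t(centered)), method = "complete")
  list(
    gene_hclust = gh, sample_hclust = sh,
    gene_order = rownames(m)[gh$order],
    sample_order = colnames(m)[sh$order],
    gene_newick = ape::write.tree(ape::as.phylo(gh)),
    sample_newick = ape::write.tree(ape::as.phylo(sh))
  )
}
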
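# Litter genotype counts under allele-specific post-natal survival.

#' Specify a litter simulation
#'
#' @param cross label for the cross.
#' @param n_offspring number of conceptuses to draw.
#' @param mendelian_ratios named per-class probabilities at conception
#'   (must sum to 1 within 1e-9).
#' @param survival named per-class relative survival probabilities in (0, 1]
#'   (the reference class conventionally at 1).
#' @param seed integer seed.
#' @return a `litter_sim_spec` list.
#' @export
litter_sim_spec <- function(cross, n_offspring, mendelian_ratios, survival,
                            seed) {
  if (!is.numeric(n_offspring) || n_offspring <= 0) {
    stop("n_offspring must be positive")
  }
  if (abs(sum(mendelian_ratios) - 1) > 1e-9) {
    stop("mendelian_ratios must sum to 1")
  }
  if (is.null(names(mendelian_ratios))) {
    names(mendelian_ratios) <- paste0("class", seq_along(mendelian_ratios))
  }
  if (length(survival) != length(mendelian_ratios)) {
    stop("survival must give one value per class")
  }
  if (any(survival <= 0 | survival > 1)) stop("survival values must be in (0, 1]")
  names(survival) <- names(mendelian_ratios)
  structure(list(cross = cross, n_offspring = as.integer(n_offspring),
                 mendelian_ratios = mendelian_ratios, survival = survival,
                 seed = seed),
            class = "litter_sim_spec")
}

#' Simulate surviving genotype counts for a cross
#'
#' Conceptus classes are drawn multinomially from the Mendelian ratios, then
#' each individual survives independently with its class's relative survival
#' probability; surviving counts per class are returned together with the
#' realized transmission fraction of each class. Under a relative survival
#' s for the carrier class versus 1 for wild type at Mendelian 1:1, the
#' expected carrier fraction among survivors is s / (1 + s).
#'
#' @param spec a [litter_sim_spec()].
#' @return a `genotype_counts` object (see [genotype_counts()]) with the
#'   surviving counts, the Mendelian expected ratios, and a
#'   `realized_fraction` attribute.
#' @export
simulate_litters <- function(spec) {
  stopifnot(inherits(spec, "litter_sim_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)
  conceived <- as.vector(stats::rmultinom(1, spec$n_offspring,
                                          spec$mendelian_ratios))
  survived <- stats::rbinom(length(conceived), conceived, spec$survival)
  counts <- stats::setNames(survived, names(spec$mendelian_ratios))
  gc <- genotype_counts(cross = spec$cross, counts = counts,
                        expected_ratios = spec$mendelian_ratios,
                        source = "simulated")
  attr(gc, "realized_fraction") <- counts / sum(counts)
  gc
}
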
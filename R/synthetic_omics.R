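# Synthetic expression / dependency tables with planted structure: a
# two-component (bimodal) distribution of per-gene mean expression, anchor
# gene sets with known median depletion fold changes, and one planted
# context-dependent gene with the extreme depletion in a designated line.

#' Specify a synthetic omics dataset
#'
#' Per-gene mean log2(TPM+1) expression is drawn from a two-component
#' Gaussian mixture (`high_fraction` of genes from the high component), as
#' observed for the basal expression of candidate morphoregulators across
#' annotated GBM cell lines; per-line values scatter around the gene mean.
#' The dependency table plants `n_anchor` essential and `n_anchor`
#' non-essential anchor genes whose per-line median depletion fold changes
#' equal `essential_anchor_fc` / `nonessential_anchor_fc` when
#' `dependency_noise_sd = 0`, plus one highly expressed, non-core
#' `planted_dependent_gene` carrying the minimum depletion value of its
#' designated line.
#'
#' @param n_genes,n_lines Table dimensions (`n_lines >= 2`).
#' @param low_component,high_component `(mean, sd)` of the two mixture
#'   components, log2(TPM+1).
#' @param high_fraction Probability a gene belongs to the high component.
#' @param line_noise_sd SD of per-line expression around the gene mean.
#' @param essential_anchor_fc,nonessential_anchor_fc Planted anchor medians.
#' @param dependency_noise_sd SD of depletion values around their center.
#' @param n_anchor Genes per anchor set.
#' @param planted_dependent_gene Gene index (1-based) made strongly depleted
#'   in `planted_line`; forced into the high-expression component and kept
#'   out of the core-fitness set.
#' @param planted_line Line index carrying the planted dependency.
#' @param seed Integer seed.
#' @return Object of class `omics_sim_spec`.
#' @export
omics_sim_spec <- function(n_genes = 500L, n_lines = 48L,
                           low_component = c(1, 0.25),
                           high_component = c(6, 1),
                           high_fraction = 0.6,
                           line_noise_sd = 0.25,
                           essential_anchor_fc = -0.8,
                           nonessential_anchor_fc = 0,
                           dependency_noise_sd = 0.1,
                           n_anchor = 20L,
                           planted_dependent_gene = 1L,
                           planted_line = 1L,
                           seed = 1L) {
  check_number(n_genes, "n_genes", min = 1)
  if (n_lines < 2) stopf("`n_lines` must be >= 2")
  if (low_component[2L] <= 0 || high_component[2L] <= 0)
    stopf("component sds must be > 0")
  if (high_fraction <= 0 || high_fraction >= 1)
    stopf("`high_fraction` must be in (0, 1)")
  if (planted_dependent_gene > n_genes || planted_line > n_lines)
    stopf("planted gene/line index out of range")
  structure(list(n_genes = as.integer(n_genes), n_lines = as.integer(n_lines),
                 low_component = low_component, high_component = high_component,
                 high_fraction = high_fraction, line_noise_sd = line_noise_sd,
                 essential_anchor_fc = essential_anchor_fc,
                 nonessential_anchor_fc = nonessential_anchor_fc,
                 dependency_noise_sd = dependency_noise_sd,
                 n_anchor = as.integer(n_anchor),
                 planted_dependent_gene = as.integer(planted_dependent_gene),
                 planted_line = as.integer(planted_line),
                 seed = as.integer(seed)),
            class = "omics_sim_spec")
}

#' Generate synthetic expression and dependency tables
#'
#' @param spec An [omics_sim_spec()].
#' @return List: `expression` (genes x lines, log2(TPM+1), >= 0),
#'   `dependency` (genes x lines depletion fold changes), `core_fitness`
#'   (gene ids: the essential anchors), `anchors`
#'   (`list(essential =, nonessential =)`), and `ground_truth` with the
#'   planted component membership, mixture parameters, dependent gene and
#'   line.
#' @export
generate_omics_tables <- function(spec) {
  stopifnot(inherits(spec, "omics_sim_spec"))
  local_seed(spec$seed, {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    lines <- sprintf("LINE%02d", seq_len(spec$n_lines))

    is_high <- stats::runif(spec$n_genes) < spec$high_fraction
    is_high[spec$planted_dependent_gene] <- TRUE
    mu <- ifelse(is_high,
                 stats::rnorm(spec$n_genes, spec$high_component[1L],
                              spec$high_component[2L]),
                 stats::rnorm(spec$n_genes, spec$low_component[1L],
                              spec$low_component[2L]))
    expr <- matrix(stats::rnorm(spec$n_genes * spec$n_lines, mean = mu,
                                sd = spec$line_noise_sd),
                   spec$n_genes, spec$n_lines,
                   dimnames = list(genes, lines))
    expr[expr < 0] <- 0  # log2(TPM+1) is non-negative

    # anchors: essential set at the front (excluding the planted gene),
    # non-essential set right after
    pool <- setdiff(seq_len(spec$n_genes), spec$planted_dependent_gene)
    ess <- pool[seq_len(spec$n_anchor)]
    non <- pool[spec$n_anchor + seq_len(spec$n_anchor)]
    centers <- rep(0, spec$n_genes)
    centers[ess] <- spec$essential_anchor_fc
    centers[non] <- spec$nonessential_anchor_fc
    dep <- matrix(stats::rnorm(spec$n_genes * spec$n_lines, mean = centers,
                               sd = spec$dependency_noise_sd),
                  spec$n_genes, spec$n_lines,
                  dimnames = list(genes, lines))
    if (spec$dependency_noise_sd == 0) {
      # exact planted medians by construction
      dep[ess, ] <- spec$essential_anchor_fc
      dep[non, ] <- spec$nonessential_anchor_fc
    }
    # planted context-dependent gene: strict minimum of its line
    pl <- spec$planted_line
    dep[spec$planted_dependent_gene, pl] <-
      min(dep[-spec$planted_dependent_gene, pl]) - 0.3

    list(expression = expr, dependency = dep,
         core_fitness = genes[ess],
         anchors = list(essential = genes[ess], nonessential = genes[non]),
         ground_truth = list(
           is_high = stats::setNames(is_high, genes),
           mixture = list(low = spec$low_component,
                          high = spec$high_component,
                          high_fraction = spec$high_fraction),
           planted_dependent_gene = genes[spec$planted_dependent_gene],
           planted_line = lines[pl]))
  })
}
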
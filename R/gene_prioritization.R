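# Data-driven candidate-gene prioritization: gene-list intersection,
# hypergeometric (one-sided Fisher) enrichment, bimodal expression gating
# by a two-component Gaussian mixture, anchored dependency scaling with
# core-fitness exclusion, and the differential-expression signature
# correlation consistency test.

#' Normalize a gene set
#'
#' Upper-cases and whitespace-strips symbols and removes duplicates; no
#' alias mapping is attempted.
#'
#' @param symbols Character vector of gene identifiers.
#' @return Object of class `gene_set` (a character vector).
#' @export
gene_set <- function(symbols) {
  s <- unique(toupper(trimws(as.character(symbols))))
  s <- s[nzchar(s) & !is.na(s)]
  structure(s, class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %d symbol(s)\n", length(x)))
  invisible(x)
}

#' Intersect two gene sets
#'
#' @param a,b `gene_set` objects (or character vectors, normalized first).
#' @return The intersection as a `gene_set`; attribute `coverage` reports
#'   the fraction of each input covered.
#' @export
intersect_gene_sets <- function(a, b) {
  a <- gene_set(a); b <- gene_set(b)
  shared <- gene_set(intersect(a, b))
  attr(shared, "coverage") <- c(
    a = if (length(a)) length(shared) / length(a) else NA_real_,
    b = if (length(b)) length(shared) / length(b) else NA_real_)
  shared
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` for `X ~ Hypergeometric(N, n, k)`: drawing `k` genes from a
#' population of `N` containing `n` successes.  Identical to the one-sided
#' Fisher exact enrichment p-value.  Computed via the exact log-space
#' hypergeometric distribution function.
#'
#' @param N Population size (e.g. 19396 protein-coding genes).
#' @param n Successes in the population (e.g. 3 adducins).
#' @param k Sample size (e.g. 30 selected genes).
#' @param x Successes observed in the sample.
#' @return The p-value in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, n, k, x) {
  for (v in list(N = N, n = n, k = k, x = x))
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stopf("N, n, k, x must be single non-negative integers")
  if (n > N || k > N) stopf("`n` and `k` cannot exceed `N`")
  if (x > min(n, k)) stopf("`x` cannot exceed min(n, k)")
  if (x == 0) return(1)
  stats::phyper(x - 1, m = n, n = N - n, k = k, lower.tail = FALSE)
}

#' Gate genes on a bimodal expression distribution
#'
#' Fits a two-component Gaussian mixture to per-gene mean expression by
#' expectation-maximization (best of `n_restarts` seeded k-means++-style
#' initializations) and gates as "high" the genes whose posterior
#' probability of the higher-mean component exceeds 0.5.  A fixed
#' `manual_threshold` can replace the mixture fit.
#'
#' @param mean_expression Named numeric vector of per-gene mean expression
#'   (>= 10 genes).
#' @param seed Integer seed (initialization only; the fit is deterministic
#'   given the seed).
#' @param n_restarts EM restarts (best likelihood kept).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param manual_threshold If given, gate = values > threshold and no
#'   mixture is fit.
#' @return Object of class `mixture_fit`: `means` (low, high), `sds`,
#'   `weight_high`, `posterior_high` (per gene), `gated_high` (gene ids),
#'   `converged`, `loglik`, `seed`.
#' @export
fit_bimodal_gate <- function(mean_expression, seed = 1L, n_restarts = 10L,
                             max_iter = 500L, tol = 1e-8,
                             manual_threshold = NULL) {
  x <- mean_expression
  if (length(x) < 10L) stopf("need at least 10 genes to fit a mixture")
  if (any(!is.finite(x))) stopf("mean expression must be finite")
  ids <- names(x) %||% as.character(seq_along(x))

  if (!is.null(manual_threshold)) {
    post <- as.numeric(x > manual_threshold)
    return(structure(list(means = c(low = NA_real_, high = NA_real_),
                          sds = c(low = NA_real_, high = NA_real_),
                          weight_high = mean(post),
                          posterior_high = stats::setNames(post, ids),
                          gated_high = ids[post > 0.5],
                          converged = TRUE, loglik = NA_real_,
                          manual_threshold = manual_threshold,
                          seed = seed),
                     class = "mixture_fit"))
  }
  if (stats::sd(x) == 0)
    stopf("all values identical: distribution is degenerate, no gate can be fit")

  em_once <- function(mu) {
    s <- rep(max(stats::sd(x) / 2, 1e-3), 2L)
    w <- c(0.5, 0.5)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      d1 <- w[1L] * stats::dnorm(x, mu[1L], s[1L])
      d2 <- w[2L] * stats::dnorm(x, mu[2L], s[2L])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      g2 <- d2 / tot
      ll <- sum(log(tot))
      if (is.finite(ll) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
      n2 <- sum(g2); n1 <- length(x) - n2
      if (n1 < 1e-8 || n2 < 1e-8) break  # component collapsed
      mu <- c(sum((1 - g2) * x) / n1, sum(g2 * x) / n2)
      s <- sqrt(pmax(c(sum((1 - g2) * (x - mu[1L])^2) / n1,
                       sum(g2 * (x - mu[2L])^2) / n2), 1e-6))
      w <- c(n1, n2) / length(x)
    }
    list(mu = mu, s = s, w = w, g2 = g2, ll = ll, converged = converged)
  }

  best <- local_seed(seed, {
    fits <- lapply(seq_len(n_restarts), function(r) {
      # k-means++-style: first center uniform, second weighted by squared
      # distance to the first
      c1 <- x[sample.int(length(x), 1L)]
      d2 <- (x - c1)^2
      c2 <- if (all(d2 == 0)) c1 + stats::sd(x) else
        x[sample.int(length(x), 1L, prob = d2)]
      em_once(sort(c(c1, c2)))
    })
    fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
  })

  # order components so that "high" is the higher mean
  if (best$mu[1L] > best$mu[2L]) {
    best$mu <- rev(best$mu); best$s <- rev(best$s); best$w <- rev(best$w)
    best$g2 <- 1 - best$g2
  }
  post <- stats::setNames(best$g2, ids)
  structure(list(means = c(low = best$mu[1L], high = best$mu[2L]),
                 sds = c(low = best$s[1L], high = best$s[2L]),
                 weight_high = best$w[2L],
                 posterior_high = post,
                 gated_high = ids[post > 0.5],
                 converged = best$converged, loglik = best$ll,
                 manual_threshold = NULL, seed = seed),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  if (!is.null(x$manual_threshold)) {
    cat(sprintf("<mixture_fit> manual threshold %.3g: %d gene(s) gated high\n",
                x$manual_threshold, length(x$gated_high)))
  } else {
    cat(sprintf(paste0("<mixture_fit> means %.2f / %.2f, sds %.2f / %.2f, ",
                       "pi_high %.2f, %d gated high%s\n"),
                x$means[1L], x$means[2L], x$sds[1L], x$sds[2L], x$weight_high,
                length(x$gated_high),
                if (x$converged) "" else " [EM hit iteration cap]"))
  }
  invisible(x)
}

#' @export
summary.mixture_fit <- function(object, ...) {
  print(object)
  cat(sprintf("log-likelihood: %.3f; converged: %s\n", object$loglik,
              object$converged))
  invisible(object)
}

#' Scale a dependency table to anchored units
#'
#' Per cell line, `s(x) = (x - m_non) / (m_non - m_ess)` where `m_ess` /
#' `m_non` are the line's median depletion fold changes over the essential
#' / non-essential anchor gene sets: 0 marks the non-essential median and
#' -1 the essential (core-fitness) median.
#'
#' @param dependency Genes x lines numeric matrix of depletion fold changes.
#' @param essential_anchors,nonessential_anchors Gene ids present among the
#'   matrix rows.
#' @return Object of class `scaled_dependency`: `scaled` (same shape as
#'   input), `m_ess`, `m_non` (per line).
#' @export
scale_dependency <- function(dependency, essential_anchors,
                             nonessential_anchors) {
  if (!is.matrix(dependency) || is.null(rownames(dependency)))
    stopf("`dependency` must be a matrix with gene rownames")
  ess <- intersect(rownames(dependency), essential_anchors)
  non <- intersect(rownames(dependency), nonessential_anchors)
  if (length(ess) == 0L || length(non) == 0L)
    stopf("both anchor sets must be non-empty and present in the matrix")
  m_ess <- apply(dependency[ess, , drop = FALSE], 2L, stats::median)
  m_non <- apply(dependency[non, , drop = FALSE], 2L, stats::median)
  same <- which(m_ess == m_non)
  if (length(same))
    stopf("essential and non-essential anchor medians coincide in line(s): %s",
          paste(colnames(dependency)[same], collapse = ", "))
  scaled <- sweep(dependency, 2L, m_non, "-")
  scaled <- sweep(scaled, 2L, m_non - m_ess, "/")
  structure(list(scaled = scaled, m_ess = m_ess, m_non = m_non),
            class = "scaled_dependency")
}

#' Prioritize candidate genes
#'
#' The full selection pipeline: (1) per-gene mean expression across lines;
#' (2) bimodal mixture gate keeps highly expressed genes; (3) core-fitness
#' genes are excluded; (4) the dependency table is anchor-scaled; (5)
#' survivors are ranked by their minimum scaled depletion across lines
#' (most negative = strongest dependency first), with a context-specificity
#' score `median(scaled) - min(scaled)` and the arg-min line per gene.
#'
#' @param shared `gene_set` of candidate genes (must be rows of `expr`;
#'   missing genes are reported, not fatal).
#' @param expr Genes x lines expression matrix (log2(TPM+1)).
#' @param dep Genes x lines dependency matrix.
#' @param core_fitness `gene_set` of core-fitness genes to exclude.
#' @param anchors `list(essential =, nonessential =)` anchor gene ids.
#' @param seed Seed for the mixture gate.
#' @param manual_threshold Optional fixed expression gate (see
#'   [fit_bimodal_gate()]).
#' @return Object of class `prioritization`: `report` (ranked data.frame
#'   with gene, mean_expr, gated, core_fitness_flag, min_scaled_dep,
#'   argmin_line, context_score), `missing_genes`, `mixture`
#'   (the `mixture_fit`), `scaling` (the `scaled_dependency`).
#' @export
prioritize_genes <- function(shared, expr, dep, core_fitness, anchors,
                             seed = 1L, manual_threshold = NULL) {
  shared <- gene_set(shared)
  core_fitness <- gene_set(core_fitness)
  present <- intersect(shared, rownames(expr))
  missing <- setdiff(shared, rownames(expr))
  if (length(present) == 0L) stopf("none of the shared genes are in `expr`")

  mean_expr <- rowMeans(expr[present, , drop = FALSE])
  fit <- fit_bimodal_gate(mean_expr, seed = seed,
                          manual_threshold = manual_threshold)
  gated <- fit$gated_high
  sc <- scale_dependency(dep, anchors$essential, anchors$nonessential)

  survivors <- setdiff(gated, core_fitness)
  survivors <- intersect(survivors, rownames(dep))
  report <- if (length(survivors)) {
    s <- sc$scaled[survivors, , drop = FALSE]
    mins <- apply(s, 1L, min)
    argmin <- colnames(s)[apply(s, 1L, which.min)]
    meds <- apply(s, 1L, stats::median)
    df <- data.frame(gene = survivors,
                     mean_expr = mean_expr[survivors],
                     gated = TRUE,
                     core_fitness_flag = FALSE,
                     min_scaled_dep = mins,
                     argmin_line = argmin,
                     context_score = meds - mins)
    df <- df[order(df$min_scaled_dep), ]
    rownames(df) <- NULL
    df
  } else {
    data.frame(gene = character(0), mean_expr = numeric(0),
               gated = logical(0), core_fitness_flag = logical(0),
               min_scaled_dep = numeric(0), argmin_line = character(0),
               context_score = numeric(0))
  }
  structure(list(report = report, missing_genes = missing,
                 gated_high = gated,
                 excluded_core = intersect(gated, core_fitness),
                 mixture = fit, scaling = sc),
            class = "prioritization")
}

#' @export
print.prioritization <- function(x, ...) {
  cat(sprintf("<prioritization> %d candidate(s) ranked (%d gated high, %d core-fitness excluded%s)\n",
              nrow(x$report), length(x$gated_high), length(x$excluded_core),
              if (length(x$missing_genes))
                sprintf(", %d missing from expression", length(x$missing_genes))
              else ""))
  if (nrow(x$report)) print(utils::head(x$report, 10L))
  invisible(x)
}

#' Signature correlation consistency test
#'
#' Tests whether differential-expression signature genes track the focal
#' gene's basal expression across cell lines.  Expression is standardized
#' per gene (zero mean, unit variance); the null distribution is the upper
#' triangle of the all-pairs Pearson correlation matrix; the focal gene's
#' correlations with each signature set are compared with the null by a
#' two-sample t test.
#'
#' @param expr Genes x lines expression matrix.
#' @param focal_gene Row name of the focal gene.
#' @param up_set,down_set `gene_set`s of up-/down-regulated signature genes
#'   (disjoint from the focal gene).
#' @return List with per-set data.frames of correlations, set means, null
#'   mean/sd, and t-test p-values (`p_up`, `p_down`), plus the number of
#'   excluded constant-expression genes.
#' @export
signature_correlation_test <- function(expr, focal_gene, up_set, down_set) {
  if (!focal_gene %in% rownames(expr)) stopf("focal gene not in matrix")
  up_set <- setdiff(gene_set(up_set), focal_gene)
  down_set <- setdiff(gene_set(down_set), focal_gene)
  sds <- apply(expr, 1L, stats::sd)
  n_excluded <- sum(sds == 0)
  if (n_excluded > 0L) {
    warning(sprintf("%d constant-expression gene(s) excluded (correlation undefined)",
                    n_excluded), call. = FALSE)
    expr <- expr[sds > 0, , drop = FALSE]
  }
  if (!focal_gene %in% rownames(expr)) stopf("focal gene has constant expression")
  z <- t(scale(t(expr)))  # per-gene zero mean, unit variance
  cm <- stats::cor(t(z))
  null_scores <- cm[upper.tri(cm)]
  r_focal <- cm[focal_gene, ]
  get_set <- function(s) r_focal[intersect(s, rownames(expr))]
  r_up <- get_set(up_set); r_down <- get_set(down_set)
  tt <- function(r) if (length(r) >= 2L)
    stats::t.test(r, null_scores)$p.value else NA_real_
  list(up = data.frame(gene = names(r_up), r = as.numeric(r_up)),
       down = data.frame(gene = names(r_down), r = as.numeric(r_down)),
       mean_r_up = if (length(r_up)) mean(r_up) else NA_real_,
       mean_r_down = if (length(r_down)) mean(r_down) else NA_real_,
       null_mean = mean(null_scores), null_sd = stats::sd(null_scores),
       p_up = tt(r_up), p_down = tt(r_down),
       n_excluded = n_excluded)
}
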
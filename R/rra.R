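# Gene-level enrichment testing for sort-gate CRISPRa screens.
#
# Guide-level: each guide's sorted-sample count is tested against a negative
# binomial null whose mean is the (plasmid) control abundance and whose
# variance comes from a mean-variance function fitted across guides, giving a
# one-sided enrichment p-value. Gene-level: guides are converted to joint
# percentile ranks and aggregated by a modified robust rank aggregation
# (alpha-RRA): only guides significant at `alpha` count as evidence, the gene
# score rho is the smallest beta order-statistic tail over those guides, and
# its significance is calibrated by permuting guide ranks across genes.
# Benjamini-Hochberg FDR is applied across genes; FDR < 0.1 is the candidate
# receptor call used downstream.

#' Fit a mean-variance model across guides
#'
#' With two or more control replicate columns, regresses
#' log(variance - mean) on log(mean) across guides with variance above their
#' mean, giving the overdispersion law variance(m) = m + exp(a + b log m)
#' (clamped at the Poisson floor variance >= mean). With a single column, or
#' fewer than 10 usable guides, falls back to a Poisson null.
#'
#' @param control_matrix Numeric matrix of normalized counts, guides x
#'   control replicates.
#' @return An object of class `mean_variance_model`: list with `intercept`,
#'   `slope`, `fallback_poisson`, and `var_fn(mu)`.
#' @export
fit_mean_variance <- function(control_matrix) {
  control_matrix <- as.matrix(control_matrix)
  fallback <- function() {
    structure(list(intercept = NA_real_, slope = NA_real_,
                   fallback_poisson = TRUE,
                   var_fn = function(mu) mu),
              class = "mean_variance_model")
  }
  if (ncol(control_matrix) < 2) return(fallback())
  m <- rowMeans(control_matrix)
  v <- apply(control_matrix, 1, stats::var)
  use <- is.finite(m) & is.finite(v) & m > 0 & v > m
  if (sum(use) < 10) {
    warning("fewer than 10 guides usable for the mean-variance regression; ",
            "falling back to Poisson", call. = FALSE)
    return(fallback())
  }
  fit <- stats::lm(log(v[use] - m[use]) ~ log(m[use]))
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  structure(list(intercept = a, slope = b, fallback_poisson = FALSE,
                 var_fn = function(mu) pmax(mu, mu + exp(a + b * log(mu)))),
            class = "mean_variance_model")
}

#' @export
print.mean_variance_model <- function(x, ...) {
  if (x$fallback_poisson) {
    cat("mean-variance model: Poisson fallback (variance = mean)\n")
  } else {
    cat(sprintf(
      "mean-variance model: variance(m) = m + exp(%.3f + %.3f log m)\n",
      x$intercept, x$slope))
  }
  invisible(x)
}

#' One-sided guide enrichment p-values under the fitted null
#'
#' For each guide, p = P(X >= treatment count) under a negative binomial
#' with mean equal to the control abundance (floored at `pseudocount`) and
#' variance from the model; Poisson when the modeled variance does not exceed
#' the mean. Counts are on the normalized scale; the treatment count is
#' rounded up to the next integer for the discrete tail.
#'
#' @param control_mean Numeric vector of normalized control abundances.
#' @param treatment Numeric vector of normalized treatment counts.
#' @param model `mean_variance_model`.
#' @param pseudocount Floor on the null mean (default 1).
#' @param log.p If TRUE, return log p-values. Tail probabilities in strongly
#'   enriched screens underflow double precision; ranking guides must happen
#'   on the log scale.
#' @return Numeric vector of (log) p-values; on the natural scale they lie
#'   in (0, 1].
#' @export
guide_pvalues <- function(control_mean, treatment, model, pseudocount = 1,
                          log.p = FALSE) {
  mu <- pmax(control_mean, pseudocount)
  v <- model$var_fn(mu)
  q <- ceiling(treatment) - 1
  lp <- numeric(length(mu))
  nb <- v > mu * (1 + 1e-12)
  if (any(nb)) {
    size <- mu[nb]^2 / (v[nb] - mu[nb])
    lp[nb] <- stats::pnbinom(q[nb], size = size, mu = mu[nb],
                             lower.tail = FALSE, log.p = TRUE)
  }
  if (any(!nb)) {
    lp[!nb] <- stats::ppois(q[!nb], lambda = mu[!nb],
                            lower.tail = FALSE, log.p = TRUE)
  }
  lp <- pmin(lp, 0)
  if (log.p) lp else exp(lp)
}

# rho for one gene: ranks r (ascending percentiles) with selection flags.
rra_rho <- function(r, selected) {
  k <- length(r)
  ord <- order(r)
  r <- r[ord]; selected <- selected[ord]
  if (!any(selected)) return(1)
  j <- which(selected)
  min(stats::pbeta(r[j], j, k - j + 1))
}

#' Modified robust rank aggregation with a permutation null
#'
#' Percentile ranks are computed jointly over all supplied guides. Ties in
#' p-value (common at the floating-point floor in strongly enriched screens)
#' are broken by a seeded random key that is independent of gene membership:
#' a tie-break correlated with gene identity (e.g. guide ids, which sort
#' same-gene guides adjacently) would hand tied guides of one gene
#' consecutive ranks and fabricate gene-level signal. A guide is "selected" iff its
#' p-value is below `alpha`; a gene with k guides scores
#' rho = min over selected order statistics j of BetaCDF(r_(j); j, k-j+1),
#' or 1 when nothing is selected. The null for a gene with k guides is built
#' by resampling, per permutation, k observed (rank, selected) pairs without
#' replacement from the joint pool — the permutation distribution of rho
#' under guide exchangeability — and is cached per k.
#' p = (1 + #\{null rho <= observed\}) / (1 + n_perm).
#'
#' @param guide_stats data.frame with columns `gene`, `p_enrich`, and
#'   optionally `p_log` (log-scale p-values, preferred for ranking where
#'   tails underflow) and `guide_id` (identity for the seeded tie-break).
#' @param alpha Guide-level selection cutoff in (0, 1] (default 0.05).
#' @param n_perm Permutations per guide-count class (>= 100).
#' @param seed Integer seed for the permutation draws.
#' @param test_genes Genes to score (default: all genes present).
#' @return data.frame with gene, n_guides, n_selected, rra_rho, p_value.
#' @export
alpha_rra <- function(guide_stats, alpha = 0.05, n_perm = 10000, seed = NULL,
                      test_genes = NULL) {
  stopifnot(alpha > 0, alpha <= 1, n_perm >= 100)
  n <- nrow(guide_stats)
  if (n == 0) stop("no guides supplied", call. = FALSE)
  ids <- if ("guide_id" %in% names(guide_stats)) guide_stats$guide_id
         else as.character(seq_len(n))
  # seeded tie-break key, assigned over guides in id order so the result is
  # invariant to input row order
  key <- integer(n)
  key[order(ids)] <- with_seed(child_seed(seed, "ties"), sample.int(n))
  p_log <- if ("p_log" %in% names(guide_stats)) guide_stats$p_log
           else log(guide_stats$p_enrich)
  ord <- order(p_log, key)
  rank_of <- integer(n); rank_of[ord] <- seq_len(n)
  perc <- rank_of / n
  n_sel <- sum(p_log < log(alpha))
  sel_thresh <- n_sel / n  # selection is monotone in rank
  selected <- perc <= sel_thresh

  if (is.null(test_genes)) test_genes <- unique(guide_stats$gene)
  by_gene <- split(seq_len(n), guide_stats$gene)
  by_gene <- by_gene[intersect(test_genes, names(by_gene))]
  missing <- setdiff(test_genes, names(by_gene))
  if (length(missing))
    stop("gene(s) with zero guides: ", join_csv(missing), call. = FALSE)

  obs <- vapply(by_gene, function(idx) rra_rho(perc[idx], selected[idx]),
                numeric(1))

  # Permutation null of rho, cached per guide-count class k. Because the
  # observed percentiles are exactly the grid {1/n, ..., n/n}, resampling k
  # observed (rank, selected) pairs without replacement is the same as
  # sampling k grid points; drawing from the canonical grid keeps the null
  # invariant to guide input order.
  null_cache <- new.env(parent = emptyenv())
  null_for_k <- function(k) {
    key <- as.character(k)
    if (!is.null(null_cache[[key]])) return(null_cache[[key]])
    rho <- with_seed(child_seed(seed, paste0("k", k)), {
      draws <- matrix(0, n_perm, k)
      for (b in seq_len(n_perm)) draws[b, ] <- sample.int(n, k) / n
      if (k > 1) draws <- t(apply(draws, 1, sort))
      B <- matrix(1, n_perm, k)
      for (j in seq_len(k)) {
        bj <- stats::pbeta(draws[, j], j, k - j + 1)
        bj[draws[, j] > sel_thresh] <- 1  # unselected guides carry no evidence
        B[, j] <- bj
      }
      r <- do.call(pmin, as.data.frame(B))
      none <- rowSums(draws <= sel_thresh) == 0
      r[none] <- 1
      sort(r)
    })
    null_cache[[key]] <- rho
    rho
  }

  k_per_gene <- lengths(by_gene)
  pv <- vapply(seq_along(by_gene), function(i) {
    null <- null_for_k(k_per_gene[i])
    (1 + findInterval(obs[i], null)) / (1 + n_perm)
  }, numeric(1))

  out <- data.frame(
    gene = names(by_gene),
    n_guides = as.integer(k_per_gene),
    n_selected = vapply(by_gene, function(idx) sum(selected[idx]), integer(1)),
    rra_rho = unname(obs),
    p_value = pv,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with its monotonicity
#' enforcement.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of FDR-adjusted values.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) stop("empty p-value vector", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
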
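# The end-to-end enrichment test: count table in, ranked gene results out.

#' Gene-level enrichment test for a sort-gate CRISPRa screen
#'
#' Normalizes the count table by total reads, fits the mean-variance null on
#' the control column(s), computes one-sided negative-binomial guide
#' p-values per treatment replicate (combined across replicates by their
#' per-guide median), converts them to joint percentile ranks, aggregates per
#' gene by alpha-RRA with a permutation null, and applies Benjamini-Hochberg
#' FDR. Non-targeting controls stay in the joint ranking pool but are never
#' scored as a gene; excluded genes are dropped before ranking (their
#' inflated counts would distort the pool, which is why a screen excludes
#' them in the first place).
#'
#' @param counts A `count_table` (see [count_reads()], [read_count_table()]).
#' @param control Control sample name(s); the plasmid library in the
#'   published design. Several names are treated as replicates.
#' @param treatments Treatment (sorted-cell) sample name(s).
#' @param exclude_genes Genes removed from the analysis entirely.
#' @param alpha Guide-level selection cutoff for alpha-RRA (default 0.05).
#' @param n_perm Permutations per guide-count class (default 10000).
#' @param seed Integer seed for the permutation null.
#' @param pseudocount Floor on null means (default 1).
#' @param control_label Gene label marking non-targeting controls
#'   (default "non-targeting").
#' @param combine How replicate guide p-values are combined: "median"
#'   (default) or "fisher".
#' @return An object of class `crispra_test` with components `results` (gene
#'   table: gene, n_guides, n_selected, rra_rho, p_value, fdr, rank),
#'   `guide_stats`, `model`, and the call parameters. Methods: `print`,
#'   `summary`, `plot`, `as.data.frame`.
#' @export
screen_test <- function(counts, control, treatments,
                        exclude_genes = character(0),
                        alpha = 0.05, n_perm = 10000, seed = NULL,
                        pseudocount = 1, control_label = "non-targeting",
                        combine = c("median", "fisher")) {
  combine <- match.arg(combine)
  samples <- colnames(counts$counts)
  if (any(!c(control, treatments) %in% samples))
    stop("unknown sample column(s): ",
         join_csv(setdiff(c(control, treatments), samples)), call. = FALSE)
  if (length(intersect(control, treatments)))
    stop("control and treatment name the same column", call. = FALSE)

  norm <- normalize_total(counts)
  keep <- !(norm$guides$gene %in% exclude_genes)
  mat <- norm$normalized[keep, , drop = FALSE]
  guides <- norm$guides[keep, , drop = FALSE]

  model <- fit_mean_variance(mat[, control, drop = FALSE])
  control_mean <- rowMeans(mat[, control, drop = FALSE])

  # log-scale guide p-values: enriched tails underflow double precision
  lpmat <- vapply(treatments, function(tr) {
    guide_pvalues(control_mean, mat[, tr], model, pseudocount = pseudocount,
                  log.p = TRUE)
  }, numeric(nrow(mat)))
  if (is.null(dim(lpmat))) lpmat <- matrix(lpmat, ncol = length(treatments))
  lp_comb <- if (combine == "median" || length(treatments) == 1) {
    apply(lpmat, 1, stats::median)  # median commutes with log
  } else {
    stat <- -2 * rowSums(lpmat)
    stats::pchisq(stat, df = 2 * ncol(lpmat), lower.tail = FALSE,
                  log.p = TRUE)
  }

  gs <- data.frame(guide_id = guides$guide_id, gene = guides$gene,
                   control_mean = control_mean,
                   treatment_count = rowMeans(mat[, treatments, drop = FALSE]),
                   p_enrich = exp(lp_comb), p_log = lp_comb,
                   stringsAsFactors = FALSE)
  ord <- order(gs$p_log, gs$guide_id)
  rk <- integer(nrow(gs)); rk[ord] <- seq_len(nrow(gs))
  gs$percentile_rank <- rk / nrow(gs)

  test_genes <- setdiff(unique(gs$gene), control_label)
  res <- alpha_rra(gs, alpha = alpha, n_perm = n_perm, seed = seed,
                   test_genes = test_genes)
  res$fdr <- bh_fdr(res$p_value)
  ord <- order(res$p_value, res$rra_rho, res$gene)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL

  structure(list(results = res, guide_stats = gs, model = model,
                 params = list(control = control, treatments = treatments,
                               exclude_genes = exclude_genes, alpha = alpha,
                               n_perm = n_perm, seed = seed,
                               pseudocount = pseudocount,
                               control_label = control_label,
                               combine = combine)),
            class = "crispra_test")
}

#' @export
print.crispra_test <- function(x, ...) {
  n_hit <- sum(x$results$fdr < 0.1)
  cat(sprintf(
    "CRISPRa enrichment test: %d genes, %d guides (%s vs %s)\n",
    nrow(x$results), nrow(x$guide_stats),
    join_csv(x$params$control), join_csv(x$params$treatments)))
  cat(sprintf("candidate receptors at FDR < 0.1: %d\n", n_hit))
  if (n_hit > 0) {
    print(utils::head(x$results[, c("gene", "n_guides", "n_selected",
                                    "rra_rho", "p_value", "fdr")], n_hit))
  }
  invisible(x)
}

#' @export
summary.crispra_test <- function(object, fdr_cutoff = 0.1, ...) {
  res <- object$results
  out <- list(
    n_genes = nrow(res),
    n_guides = nrow(object$guide_stats),
    n_candidates = sum(res$fdr < fdr_cutoff),
    candidates = res$gene[res$fdr < fdr_cutoff],
    fdr_cutoff = fdr_cutoff,
    poisson_fallback = object$model$fallback_poisson
  )
  class(out) <- "summary.crispra_test"
  out
}

#' @export
print.summary.crispra_test <- function(x, ...) {
  cat(sprintf("%d genes tested (%d guides); %s guide null\n",
              x$n_genes, x$n_guides,
              if (x$poisson_fallback) "Poisson" else "negative-binomial"))
  cat(sprintf("candidate receptors (FDR < %g): %s\n", x$fdr_cutoff,
              if (x$n_candidates) join_csv(x$candidates) else "none"))
  invisible(x)
}

#' Rank plot of gene enrichment
#'
#' Genes in enriched rank order against -log10 permutation p; candidates at
#' the FDR cutoff are highlighted and labeled.
#'
#' @param x `crispra_test` object.
#' @param fdr_cutoff Candidate threshold (default 0.1).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.crispra_test <- function(x, fdr_cutoff = 0.1, ...) {
  res <- x$results
  hit <- res$fdr < fdr_cutoff
  graphics::plot(res$rank, -log10(res$p_value),
                 xlab = "gene rank", ylab = expression(-log[10] ~ p),
                 pch = 16, col = ifelse(hit, "red", "grey50"), ...)
  if (any(hit)) {
    graphics::text(res$rank[hit], -log10(res$p_value[hit]),
                   labels = res$gene[hit], pos = 4, cex = 0.7, col = "red")
  }
  invisible(x)
}

#' @export
as.data.frame.crispra_test <- function(x, ...) x$results

#' Write gene results to TSV
#' @param x `crispra_test` object.
#' @param path Output path.
#' @export
write_gene_results <- function(x, path) {
  utils::write.table(x$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
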
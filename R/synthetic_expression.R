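# Synthetic TPM expression matrices with planted differential expression.

#' Configuration for a synthetic expression matrix
#'
#' Gene abundances are generated on the log2(TPM+1) scale: a log-normal-ish
#' gene baseline plus i.i.d. Gaussian within-group noise, with a subset of
#' planted genes shifted by `planted_log2fc` in the responder group
#' (alternating up/down). Columns are rescaled to sum to 1e6 (the TPM
#' convention) before output.
#'
#' @param n_genes total genes.
#' @param n_per_group samples per group (responder, nonresponder).
#' @param planted_de_count number of genes with a planted effect
#'   (<= `n_genes`).
#' @param planted_log2fc absolute planted effect on the log2 scale.
#' @param baseline_log2_mean,baseline_log2_sd distribution of gene baseline
#'   abundance on the log2(TPM+1) scale.
#' @param sigma within-group gene SD on the log2 scale (> 0).
#' @param seed integer seed.
#' @return object of class `expr_config`.
#' @export
expr_config <- function(n_genes = 2000L, n_per_group = c(20L, 20L),
                        planted_de_count = 0L, planted_log2fc = 2,
                        baseline_log2_mean = 5, baseline_log2_sd = 1.5,
                        sigma = 0.5, seed = 1L) {
  stopifnot(n_genes >= 10L, length(n_per_group) == 2L, all(n_per_group >= 2L),
            planted_de_count >= 0L, planted_de_count <= n_genes,
            sigma > 0, baseline_log2_sd > 0)
  structure(as.list(environment()), class = "expr_config")
}

#' Generate a synthetic TPM expression matrix with planted truth
#'
#' @param config an [expr_config()].
#' @return list with `tpm` (genes x samples matrix, columns summing to 1e6),
#'   `groups` (factor `responder`/`nonresponder` per sample), and `planted`
#'   (data frame `gene_id`, `log2fc` of the planted effects; signed, positive
#'   meaning higher in responders).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "expr_config"))
  withr::with_seed(config$seed, {
    g <- config$n_genes
    n1 <- config$n_per_group[1L]; n2 <- config$n_per_group[2L]
    genes <- sprintf("G%05d", seq_len(g))
    samples <- sprintf("S%03d", seq_len(n1 + n2))
    groups <- factor(rep(c("responder", "nonresponder"), c(n1, n2)),
                     levels = c("nonresponder", "responder"))
    base <- stats::rnorm(g, config$baseline_log2_mean, config$baseline_log2_sd)
    planted_idx <- if (config$planted_de_count > 0) {
      sort(sample.int(g, config$planted_de_count))
    } else integer(0)
    fc <- numeric(g)
    if (length(planted_idx)) {
      signs <- rep(c(1, -1), length.out = length(planted_idx))
      fc[planted_idx] <- signs * config$planted_log2fc
    }
    L <- matrix(stats::rnorm(g * (n1 + n2), 0, config$sigma), g)
    L <- L + base
    L[, groups == "responder"] <- L[, groups == "responder"] + fc
    tpm <- sweep(2^L, 2L, colSums(2^L), "/") * 1e6
    dimnames(tpm) <- list(genes, samples)
    planted <- data.frame(gene_id = genes[planted_idx],
                          log2fc = fc[planted_idx],
                          stringsAsFactors = FALSE)
    list(tpm = tpm, groups = stats::setNames(groups, samples), planted = planted)
  })
}
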
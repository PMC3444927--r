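# PCIT edge significance: the "judge, jury and executioner" for correlation
# edges.  For every gene trio the three first-order partial correlations
# define a data-driven tolerance; a pair dominated by some third gene is
# dropped.  The decision is relative, so a correlation of 0.6 can be
# significant in one dataset while 0.9 is rejected in another.  The rule is
# the canonical published PCIT procedure, imported, not invented here.

#' First-order partial correlation
#'
#' Correlation between x and y once the influence of z is removed:
#' \deqn{r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}{\sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}}}
#'
#' @param r_xy,r_xz,r_yz Pairwise correlations, all in [-1, 1].
#' @return The partial correlation; `NA` (with a warning) when a denominator
#'   degenerates (|r_xz| = 1 or |r_yz| = 1).
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  if (any(abs(c(r_xy, r_xz, r_yz)) > 1)) stop("correlations must lie in [-1, 1]")
  den <- (1 - r_xz^2) * (1 - r_yz^2)
  out <- ifelse(den > 1e-12, (r_xy - r_xz * r_yz) / sqrt(pmax(den, 0)), NA_real_)
  if (anyNA(out)) warning("degenerate denominator: partial correlation undefined")
  out
}

cor_values <- function(x) {
  if (inherits(x, "rif_cormat") || inherits(x, "rif_dcmat") ||
      inherits(x, "rif_cdemat")) x$values else x
}

#' PCIT significance scan over all gene trios
#'
#' For each trio (x, y, z) the tolerance is the mean of the three
#' |partial / direct| ratios (ratios whose direct correlation is below 1e-12
#' in magnitude are skipped; if all three are skipped the trio is ignored).
#' The x-y association is discarded when, for at least one third gene z,
#' \eqn{|r_{xy}| \le \epsilon |r_{xz}|} and \eqn{|r_{xy}| \le \epsilon |r_{yz}|}.
#' A pair whose partial is undefined in a trio (degenerate denominator) is
#' simply not tested in that trio.  Surviving pairs form the significance
#' adjacency.  The scan is exhaustive and O(n^3); it runs in compiled code
#' and is comfortable up to a few thousand genes on a desktop (at 10,000
#' genes the ~167 billion trios become a genuine scalability concern).
#'
#' @param x An `rif_cormat` (or any symmetric numeric matrix with gene
#'   dimnames); values are treated as correlations.
#' @return Object of class `rif_pcit`: list with `adjacency` (logical,
#'   symmetric; significant edges are a subset of nonzero-correlation
#'   pairs), `discarded` (data frame gene_a, gene_b, correlation, witness --
#'   the third gene that explained the pair away -- and tolerance), `genes`,
#'   and the input matrix under `correlation`.
#' @export
pcit_significant_edges <- function(x) {
  r <- cor_values(x)
  n <- nrow(r)
  if (is.null(n) || n < 3) stop("PCIT undefined below 3 genes")
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-8)))
    stop("correlation matrix must be symmetric")
  genes <- rownames(r)
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  scan <- pcit_scan_cpp(r)
  keep <- scan$keep
  dimnames(keep) <- list(genes, genes)
  idx <- which(upper.tri(keep) & !keep & abs(r) > 0, arr.ind = TRUE)
  discarded <- data.frame(
    gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
    correlation = r[idx],
    witness = genes[scan$witness[idx]],
    tolerance = scan$tolerance[idx],
    stringsAsFactors = FALSE)
  structure(list(adjacency = keep, discarded = discarded, genes = genes,
                 correlation = r),
            class = "rif_pcit")
}

#' @export
print.rif_pcit <- function(x, ...) {
  s <- pcit_scan_report(x)
  cat(sprintf("rif_pcit: %d genes, %s pairs scanned over %s trios; %s kept, %s discarded\n",
              s$n_genes, format(s$n_pairs, big.mark = ","),
              format(s$n_trios, big.mark = ","),
              format(s$n_kept, big.mark = ","), format(s$n_discarded, big.mark = ",")))
  invisible(x)
}

#' Pair and trio counts for an n-gene scan
#'
#' n(n-1)/2 pairs and n(n-1)(n-2)/6 trios, in double precision (the trio
#' count overflows 32-bit integers well below genome scale: 10,000 genes
#' already give ~50 million pairs and ~167 billion trios).
#'
#' @param n Number of genes.
#' @return List with `n_pairs` and `n_trios`.
#' @export
pcit_counts <- function(n) {
  n <- as.numeric(n)
  list(n_pairs = n * (n - 1) / 2, n_trios = n * (n - 1) * (n - 2) / 6)
}

#' Summary of a PCIT scan
#'
#' @param x An `rif_pcit` result, or an `rif_cormat`/matrix (which is then
#'   scanned first).
#' @return List with `n_genes`, `n_pairs`, `n_trios`, `n_kept`,
#'   `n_discarded`, `n_zero` (pairs with zero correlation, never candidate
#'   edges); `n_kept + n_discarded + n_zero = n_pairs`.
#' @export
pcit_scan_report <- function(x) {
  if (!inherits(x, "rif_pcit")) x <- pcit_significant_edges(x)
  n <- length(x$genes)
  cnt <- pcit_counts(n)
  up <- upper.tri(x$adjacency)
  kept <- sum(x$adjacency[up])
  zero <- sum(abs(x$correlation[up]) == 0)
  list(n_genes = n, n_pairs = cnt$n_pairs, n_trios = cnt$n_trios,
       n_kept = kept, n_discarded = cnt$n_pairs - kept - zero, n_zero = zero)
}
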
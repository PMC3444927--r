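# Network construction and diagnostics: co-expression networks from
# PCIT-significant correlations, co-differential co-expression networks from
# PCIT on differential-wiring profiles, significant-degree contrasts,
# module-driver scoring, and topology/abundance checks.

#' Co-expression network from PCIT-significant pairs
#'
#' Runs [coexpression()] and [pcit_significant_edges()] per condition.  In
#' `"single"` mode one condition's surviving pairs become edges weighted by
#' that condition's correlation.  In `"intersection"` mode an edge must be
#' significant in every listed condition (the conservative criterion under
#' which a sign-flipping regulator holds no edge at all); weights are the
#' mean correlation across conditions.
#'
#' @inheritParams coexpression
#' @param conds Character vector of condition labels.
#' @param mode `"single"` (one condition) or `"intersection"`.
#' @return An [rif_network] whose provenance column records the condition(s).
#' @export
coexpression_network <- function(dataset, conds,
                                 mode = c("single", "intersection"),
                                 method = c("spearman", "pearson"),
                                 collapse_replicates = TRUE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (!length(conds)) stop("empty condition list")
  if (mode == "single" && length(conds) != 1)
    stop("single mode takes exactly one condition")
  mats <- lapply(conds, function(cc)
    coexpression(dataset, cc, method, collapse_replicates))
  scans <- lapply(mats, pcit_significant_edges)
  adj <- Reduce(`&`, lapply(scans, `[[`, "adjacency"))
  wsum <- Reduce(`+`, lapply(mats, `[[`, "values")) / length(mats)
  genes <- rownames(dataset$values)
  idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                      weight = wsum[idx],
                      provenance = paste(conds, collapse = "+"),
                      stringsAsFactors = FALSE)
  rif_network(genes, edges)
}

#' Co-differential co-expression network
#'
#' Finds molecules with an *equivalent pattern of differential
#' co-expression* to the DE genes.  Step 1: each gene's differential-wiring
#' profile v_i = (dC_{i,j}) over the DE genes j.  Step 2: the gene x gene
#' similarity of those profiles.  Step 3: PCIT on that similarity matrix;
#' surviving pairs become edges weighted by the profile similarity.  Genes
#' that were not rewired clump into one dense background of mutually similar
#' (near-flat) profiles, while a silent rewired regulator and its co-rewired
#' partners emerge as a tightly linked circuit of near-maximal mutual
#' weight.
#'
#' @param dc An `rif_dcmat` from [differential_coexpression()].
#' @param de_genes DE target genes defining the profiles (n_dE >= 3).
#' @param genes Genes to include as profile owners; default all genes in
#'   `dc` (restricting to an annotated regulator list is also sensible).
#' @param method Profile similarity.  The default `"cosine"` (uncentered
#'   correlation) is sensitive to coordinate *levels* of differential
#'   co-expression: a gene rewired uniformly against every DE target has a
#'   near-constant, far-from-zero profile, which mean-centering would erase
#'   entirely.  Centered `"pearson"`/`"spearman"` compare profile *shapes*
#'   only and are available as options.
#' @param pif_weights Optional named per-gene PIF vector; when supplied,
#'   profile entries are weighted by |PIF| of the target gene.
#' @return An [rif_network] with provenance `"differential"`.  Genes whose
#'   profile is degenerate (zero norm for cosine, zero variance otherwise)
#'   are excluded from the scan and recorded in attribute `undefined`.
#' @export
cdc_network <- function(dc, de_genes, genes = NULL,
                        method = c("cosine", "pearson", "spearman"),
                        pif_weights = NULL) {
  method <- match.arg(method)
  all_genes <- rownames(dc$values)
  if (is.null(genes)) genes <- all_genes
  bad <- setdiff(c(genes, de_genes), all_genes)
  if (length(bad)) stop("gene absent from dC matrix: ", paste(bad, collapse = ", "))
  if (length(de_genes) < 3) stop("need at least 3 DE genes (n_dE >= 3)")
  prof <- dc$values[genes, de_genes, drop = FALSE]
  if (!is.null(pif_weights))
    prof <- sweep(prof, 2, abs(pif_weights[de_genes]), "*")
  flat <- if (method == "cosine") {
    genes[rowSums(prof^2) == 0]
  } else {
    genes[apply(prof, 1, stats::sd) == 0]
  }
  use <- setdiff(genes, flat)
  if (length(flat))
    warning("degenerate differential-wiring profile, excluded: ",
            paste(flat, collapse = ", "))
  if (length(use) < 3) stop("fewer than 3 usable profiles")
  p <- prof[use, , drop = FALSE]
  sim <- if (method == "cosine") {
    tcrossprod(p / sqrt(rowSums(p^2)))
  } else {
    stats::cor(t(p), method = method)
  }
  sim[sim > 1] <- 1   # guard rounding just past the bound
  sim[sim < -1] <- -1
  diag(sim) <- 1
  scan <- pcit_significant_edges(sim)
  idx <- which(upper.tri(scan$adjacency) & scan$adjacency, arr.ind = TRUE)
  edges <- data.frame(gene_a = use[idx[, 1]], gene_b = use[idx[, 2]],
                      weight = sim[idx], provenance = "differential",
                      stringsAsFactors = FALSE)
  net <- rif_network(genes, edges)
  attr(net, "undefined") <- flat
  net
}

#' Significant-degree contrast between two networks
#'
#' The per-gene count of significant co-expressions in each condition and
#' their signed difference -- the alternative "differential hubbing" measure.
#' A regulator whose correlations flip sign but keep magnitude holds a
#' similar significant degree in both conditions, so this contrast misses it
#' even while RIF1 ranks it first.
#'
#' @param net_a,net_b [rif_network]s over the same node universe.
#' @return Data frame with columns `gene`, `degree_a`, `degree_b`,
#'   `difference` (A minus B).
#' @export
degree_contrast <- function(net_a, net_b) {
  if (!setequal(net_a$nodes, net_b$nodes)) stop("node universes differ")
  da <- network_degree(net_a)
  db <- network_degree(net_b)[names(da)]
  data.frame(gene = names(da), degree_a = unname(da), degree_b = unname(db),
             difference = unname(da - db), stringsAsFactors = FALSE)
}

#' Module-driver scoring
#'
#' Which regulator has the highest absolute average correlation to all the
#' genes in a module?  Scores are bounded in [0, 1]; a regulator that is
#' itself a module member skips its self-pair.
#'
#' @param cormat An `rif_cormat` (or correlation matrix with dimnames).
#' @param module_genes Genes of the module.
#' @param regulators Candidate regulators.
#' @return Data frame `regulator`, `score` (mean |r| to module genes),
#'   `rank`, sorted by descending score.
#' @export
module_driver <- function(cormat, module_genes, regulators) {
  r <- cor_values(cormat)
  if (!length(module_genes) || !length(regulators))
    stop("module genes and regulators must be nonempty")
  bad <- setdiff(c(module_genes, regulators), rownames(r))
  if (length(bad)) stop("gene absent from correlation matrix: ",
                        paste(bad, collapse = ", "))
  score <- vapply(regulators, function(g) {
    tgt <- setdiff(module_genes, g)
    if (!length(tgt)) return(NA_real_)
    mean(abs(r[g, tgt]))
  }, numeric(1))
  out <- data.frame(regulator = regulators, score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Discrete power-law fit of a degree distribution
#'
#' Maximum-likelihood exponent with x_min fixed at 1 (a diagnostic for the
#' scale-free shape typical of co-expression networks, not an inferential
#' test), plus the log-log degree histogram.  Networks whose connected nodes
#' all share one degree are flagged degenerate rather than fitted.
#'
#' @param network An [rif_network] with at least 10 nodes of degree >= 1,
#'   or a raw integer degree vector.
#' @return List with `alpha`, `xmin`, `KS_stat`, `degenerate`, `histogram`
#'   (data frame degree/count/log10_degree/log10_count).
#' @export
degree_distribution_fit <- function(network) {
  deg <- if (inherits(network, "rif_network")) network_degree(network)
         else as.numeric(network)
  pos <- deg[deg >= 1]
  if (!length(pos)) stop("all nodes isolated; nothing to fit")
  if (length(pos) < 10) stop("need at least 10 nodes with degree >= 1")
  tab <- table(pos)
  hist <- data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
  hist$log10_degree <- log10(hist$degree)
  hist$log10_count <- log10(hist$count)
  if (length(unique(pos)) == 1) {
    return(list(alpha = NA_real_, xmin = 1, KS_stat = NA_real_,
                degenerate = TRUE, histogram = hist))
  }
  fit <- igraph::fit_power_law(as.numeric(pos), xmin = 1)
  list(alpha = fit$alpha, xmin = 1, KS_stat = fit$KS.stat,
       degenerate = FALSE, histogram = hist)
}

#' Two-component Gaussian mixture fit of mean abundances
#'
#' Transcript abundance distributions are often bimodal: a dominant body of
#' moderately expressed genes plus a heavy shoulder of very abundant
#' structural transcripts.  This fits 1- and 2-component univariate Gaussian
#' mixtures by EM and reports a penalized-likelihood (BIC) comparison.
#'
#' @param abundance Numeric vector of per-gene mean abundances (>= 50 values).
#' @return List with `means`, `sds`, `weights` (2-component fit, means in
#'   increasing order), `bic_one`, `bic_two` (larger is better, mclust
#'   convention) and `prefers_two`.
#' @importFrom mclust Mclust mclustBIC
#' @export
abundance_mixture_fit <- function(abundance) {
  abundance <- as.numeric(abundance)
  if (length(abundance) < 50) stop("need at least 50 genes")
  if (any(!is.finite(abundance))) stop("non-finite abundance values")
  if (stats::sd(abundance) == 0) stop("constant abundance vector")
  fit2 <- Mclust(abundance, G = 2, modelNames = "V", verbose = FALSE)
  fit1 <- Mclust(abundance, G = 1, modelNames = "X", verbose = FALSE)
  ord <- order(fit2$parameters$mean)
  list(means = unname(fit2$parameters$mean[ord]),
       sds = unname(sqrt(fit2$parameters$variance$sigmasq))[ord],
       weights = unname(fit2$parameters$pro[ord]),
       bic_one = unname(fit1$bic), bic_two = unname(fit2$bic),
       prefers_two = unname(fit2$bic > fit1$bic))
}
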
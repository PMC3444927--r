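# Per-gene and per-pair measures: mean expression E, differential expression
# dE, co-expression C, differential co-expression dC, co-differential
# expression CdE, the phenotype impact factor PIF and the regulatory impact
# factors RIF1/RIF2.

#' Per-gene expression profile and mean within one condition
#'
#' When both time points and replicates are annotated, replicates are first
#' averaged within each time point, so that downstream correlations run
#' across time points (set `collapse_replicates = FALSE` to treat every
#' sample as an observation).  The per-gene mean E is the arithmetic mean of
#' the collapsed values.
#'
#' @param dataset An [expression_dataset].
#' @param condition Condition label.
#' @param collapse_replicates Average replicates within time points first?
#' @return List with `profile` (genes x observations matrix) and `E`
#'   (named per-gene mean vector).
#' @export
condition_profile <- function(dataset, condition, collapse_replicates = TRUE) {
  des <- dataset$design
  if (!condition %in% des$condition) stop("unknown condition: ", condition)
  idx <- which(des$condition == condition)
  vals <- dataset$values[, idx, drop = FALSE]
  times <- des$time[idx]
  if (collapse_replicates && !anyNA(times) && anyDuplicated(times)) {
    tp <- sort(unique(times))
    prof <- vapply(tp, function(t) rowMeans(vals[, times == t, drop = FALSE]),
                   numeric(nrow(vals)))
    if (!is.matrix(prof)) prof <- matrix(prof, nrow = nrow(vals))
    dimnames(prof) <- list(rownames(vals), paste0("t", tp))
  } else {
    prof <- vals
  }
  list(profile = prof, E = rowMeans(prof))
}

#' Differential expression dE between two conditions
#'
#' dE_i = E_{i,A} - E_{i,B}.  Sample counts may differ between conditions.
#'
#' @inheritParams condition_profile
#' @param cond_a,cond_b The two condition labels (A minus B).
#' @return Named per-gene numeric vector.
#' @export
differential_expression <- function(dataset, cond_a, cond_b,
                                    collapse_replicates = TRUE) {
  if (identical(cond_a, cond_b)) stop("conditions must differ")
  condition_profile(dataset, cond_a, collapse_replicates)$E -
    condition_profile(dataset, cond_b, collapse_replicates)$E
}

# Correlation with zero-variance columns forced to 0 (unit diagonal kept)
# instead of NA; returns the matrix plus the offending gene names.
cor_guarded <- function(obs, method) {
  sds <- apply(obs, 2, stats::sd)
  flat <- colnames(obs)[sds == 0]
  r <- suppressWarnings(stats::cor(obs, method = method))
  if (length(flat)) {
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  diag(r) <- 1
  list(r = r, undefined = flat)
}

#' Within-condition co-expression matrix
#'
#' Correlation of every gene pair's profile within one condition; Spearman by
#' default, with average ranks for ties.  A zero-variance gene cannot have a
#' defined correlation: its rows/columns are set to 0 and the gene is
#' recorded in the result's `undefined` field rather than failing the run.
#'
#' @inheritParams condition_profile
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Object of class `rif_cormat`: list with `condition`, `method`,
#'   `values` (symmetric, unit diagonal, in [-1, 1]), `n_obs`, `undefined`.
#' @export
coexpression <- function(dataset, condition, method = c("spearman", "pearson"),
                         collapse_replicates = TRUE) {
  method <- match.arg(method)
  prof <- condition_profile(dataset, condition, collapse_replicates)$profile
  if (ncol(prof) < 3) stop("need at least 3 observations per gene in ", condition)
  g <- cor_guarded(t(prof), method)
  structure(list(condition = condition, method = method, values = g$r,
                 n_obs = ncol(prof), undefined = g$undefined),
            class = "rif_cormat")
}

#' @export
print.rif_cormat <- function(x, ...) {
  cat(sprintf("rif_cormat [%s]: %d genes, %s over %d observations",
              x$condition, nrow(x$values), x$method, x$n_obs))
  if (length(x$undefined))
    cat(sprintf("; %d zero-variance genes set to 0", length(x$undefined)))
  cat("\n")
  invisible(x)
}

#' Differential co-expression dC = C_A - C_B
#'
#' The rewiring signal: the elementwise change in a gene pair's correlation
#' between the two conditions, bounded in [-2, 2] with the maximum of 2
#' attained at r_A = +1, r_B = -1.
#'
#' @param cor_a,cor_b `rif_cormat` objects for the two conditions, over the
#'   same genes in the same order.
#' @return Object of class `rif_dcmat`: list with `condition_a`,
#'   `condition_b`, `values` (symmetric, zero diagonal).
#' @export
differential_coexpression <- function(cor_a, cor_b) {
  if (!identical(rownames(cor_a$values), rownames(cor_b$values)))
    stop("gene sets differ between the two correlation matrices")
  structure(list(condition_a = cor_a$condition, condition_b = cor_b$condition,
                 values = cor_a$values - cor_b$values),
            class = "rif_dcmat")
}

#' Co-differential expression CdE over time
#'
#' Builds each gene's per-time-point dE profile (mean expression per time
#' point per condition, then A minus B) and correlates those profiles
#' between genes: genes that are "similarly different" over development.
#' Requires at least 3 time points shared by both conditions.
#'
#' @inheritParams differential_expression
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Object of class `rif_cdemat`: list with `values` (symmetric,
#'   unit diagonal), `de_profiles` (genes x time points), `method`,
#'   `undefined` (genes with a flat dE profile, correlations set to 0).
#' @export
co_differential_expression <- function(dataset, cond_a, cond_b,
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (identical(cond_a, cond_b)) stop("conditions must differ")
  des <- dataset$design
  if (all(is.na(des$time))) stop("dataset has no time annotation")
  ta <- unique(des$time[des$condition == cond_a])
  tb <- unique(des$time[des$condition == cond_b])
  shared <- sort(intersect(ta, tb))
  if (length(shared) < 3) stop("need at least 3 shared time points")
  prof_t <- function(cond, t) {
    rowMeans(dataset$values[, des$condition == cond & des$time == t, drop = FALSE])
  }
  de_prof <- vapply(shared, function(t) prof_t(cond_a, t) - prof_t(cond_b, t),
                    numeric(nrow(dataset$values)))
  dimnames(de_prof) <- list(rownames(dataset$values), paste0("t", shared))
  g <- cor_guarded(t(de_prof), method)
  structure(list(values = g$r, de_profiles = de_prof, method = method,
                 undefined = g$undefined),
            class = "rif_cdemat")
}

#' Phenotype impact factor table
#'
#' PIF_i = A_i * dE_i with A_i = (E_{i,A} + E_{i,B}) / 2: differential
#' expression weighted by overall abundance, so that abundant strongly
#' shifted "output" genes dominate.
#'
#' @inheritParams differential_expression
#' @return Data frame (class `rif_metrics`) with columns `gene`, `E_A`,
#'   `E_B`, `A`, `dE`, `PIF`, in input gene order; conditions kept as
#'   attributes.
#' @export
pif <- function(dataset, cond_a, cond_b, collapse_replicates = TRUE) {
  if (identical(cond_a, cond_b)) stop("conditions must differ")
  e_a <- condition_profile(dataset, cond_a, collapse_replicates)$E
  e_b <- condition_profile(dataset, cond_b, collapse_replicates)$E
  out <- data.frame(gene = names(e_a), E_A = unname(e_a), E_B = unname(e_b),
                    A = unname((e_a + e_b) / 2), dE = unname(e_a - e_b),
                    stringsAsFactors = FALSE)
  out$PIF <- out$A * out$dE
  attr(out, "cond_a") <- cond_a
  attr(out, "cond_b") <- cond_b
  class(out) <- c("rif_metrics", "data.frame")
  out
}

#' Pick differentially expressed genes by |PIF|
#'
#' The DE "target" list fed to [rif()] is caller-supplied in principle; this
#' helper takes the top k genes by absolute PIF.
#'
#' @param metrics A table from [pif()].
#' @param k Number of genes (default 85, a typical DE list size for a
#'   ~10,000-gene two-condition contrast).
#' @return Character vector of gene identifiers.
#' @export
select_de_genes <- function(metrics, k = 85) {
  k <- min(k, nrow(metrics))
  metrics$gene[order(-abs(metrics$PIF))][seq_len(k)]
}

#' Regulatory impact factors RIF1 and RIF2
#'
#' For each candidate regulator i, over the differentially expressed target
#' genes j = 1..n_dE:
#' \deqn{RIF1_i = \frac{1}{n_{dE}} \sum_j PIF_j \, dC_{i,j}^2}
#' \deqn{RIF2_i = \frac{1}{n_{dE}} \sum_j (E_{j,A} r_{A\,i,j})^2 - (E_{j,B} r_{B\,i,j})^2}
#' RIF1 asks which regulator is consistently highly differentially
#' co-expressed with the abundant DE genes; RIF2 asks which regulator's
#' ability to predict the abundance of DE genes changed most.  No
#' significance filter is applied to the individual correlations: modest
#' per-condition correlations with a large change carry the signal.
#'
#' A regulator that is itself a DE gene skips its self-pair (and its n_dE is
#' decremented accordingly).  Scores are reported raw and z-standardized
#' across regulators; rank 1 is the top regulator (RIF1 ranked by raw score
#' descending, RIF2 by |z| descending).
#'
#' @inheritParams differential_expression
#' @param regulators Character vector of candidate regulators (e.g. an
#'   annotated transcription-factor list).  Defaults to all genes, with a
#'   warning: an annotated regulator subset is the intended use.
#' @param de_genes Character vector of DE target genes; defaults to
#'   [select_de_genes()] with `k_de`.
#' @param k_de Size of the default DE list.
#' @param method Correlation method, as in [coexpression()].
#' @param rif2_form `"er_squared"` uses (E * r)^2 terms (default);
#'   `"e_r2"` uses E * r^2.
#' @return Data frame (class `rif_result`) with columns `regulator`,
#'   `RIF1_raw`, `RIF1_z`, `RIF1_rank`, `RIF2_raw`, `RIF2_z`, `RIF2_rank`;
#'   the DE gene list is kept as attribute `de_genes`.
#' @export
rif <- function(dataset, cond_a, cond_b, regulators = NULL, de_genes = NULL,
                k_de = 85, method = c("spearman", "pearson"),
                rif2_form = c("er_squared", "e_r2"),
                collapse_replicates = TRUE) {
  method <- match.arg(method)
  rif2_form <- match.arg(rif2_form)
  if (identical(cond_a, cond_b)) stop("conditions must differ")
  genes <- rownames(dataset$values)
  if (is.null(regulators)) {
    warning("no regulator list supplied; scoring all genes as candidate regulators")
    regulators <- genes
  }
  if (!length(regulators)) stop("empty regulator list")
  bad <- setdiff(regulators, genes)
  if (length(bad)) stop("regulator absent from dataset: ", paste(bad, collapse = ", "))
  pa <- condition_profile(dataset, cond_a, collapse_replicates)
  pb <- condition_profile(dataset, cond_b, collapse_replicates)
  if (is.null(de_genes)) {
    met <- pif(dataset, cond_a, cond_b, collapse_replicates)
    de_genes <- select_de_genes(met, k_de)
  }
  if (!length(de_genes)) stop("empty DE gene list (n_dE = 0)")
  bad <- setdiff(de_genes, genes)
  if (length(bad)) stop("DE gene absent from dataset: ", paste(bad, collapse = ", "))
  de_genes <- unique(de_genes)

  e_a <- pa$E[de_genes]
  e_b <- pb$E[de_genes]
  pif_j <- (e_a + e_b) / 2 * (e_a - e_b)
  r_a <- suppressWarnings(
    stats::cor(t(pa$profile[regulators, , drop = FALSE]),
               t(pa$profile[de_genes, , drop = FALSE]), method = method))
  r_b <- suppressWarnings(
    stats::cor(t(pb$profile[regulators, , drop = FALSE]),
               t(pb$profile[de_genes, , drop = FALSE]), method = method))
  r_a[is.na(r_a)] <- 0  # zero-variance profile: undefined correlation -> 0
  r_b[is.na(r_b)] <- 0
  dc <- r_a - r_b

  self <- outer(regulators, de_genes, "==")
  n_de <- length(de_genes) - rowSums(self)
  if (any(n_de == 0)) stop("a regulator's DE list is empty after self-exclusion")

  t1 <- sweep(dc^2, 2, pif_j, "*")
  t1[self] <- 0
  rif1 <- rowSums(t1) / n_de
  if (rif2_form == "er_squared") {
    t2 <- sweep(r_a, 2, e_a, "*")^2 - sweep(r_b, 2, e_b, "*")^2
  } else {
    t2 <- sweep(r_a^2, 2, e_a, "*") - sweep(r_b^2, 2, e_b, "*")
  }
  t2[self] <- 0
  rif2 <- rowSums(t2) / n_de

  zscore <- function(x) {
    if (length(x) > 1 && stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  }
  z1 <- zscore(rif1)
  z2 <- zscore(rif2)
  out <- data.frame(regulator = regulators,
                    RIF1_raw = unname(rif1), RIF1_z = unname(z1),
                    RIF1_rank = rank(-rif1, ties.method = "first"),
                    RIF2_raw = unname(rif2), RIF2_z = unname(z2),
                    RIF2_rank = rank(-abs(z2), ties.method = "first"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "de_genes") <- de_genes
  attr(out, "cond_a") <- cond_a
  attr(out, "cond_b") <- cond_b
  class(out) <- c("rif_result", "data.frame")
  out
}
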
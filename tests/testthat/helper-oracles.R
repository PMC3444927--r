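# Independent reference implementations used as oracles.  Deliberately
# naive (explicit loops, no shared code with the package internals) so a
# defect in the fast paths cannot hide.

# PCIT by naive triple loop over all trios, following the published rule:
# eps = mean |partial/direct| over the trio (skipping |direct| < 1e-12 and
# undefined partials); a pair is discarded when dominated in >= 1 trio.
naive_pcit <- function(r) {
  n <- nrow(r)
  keep <- (r != 0) & !diag(TRUE, n)
  tiny <- 1e-12
  pc <- function(rab, rac, rbc) {
    den <- (1 - rac^2) * (1 - rbc^2)
    if (den <= tiny) return(NA_real_)
    (rab - rac * rbc) / sqrt(den)
  }
  for (x in seq_len(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    rxy <- r[x, y]; rxz <- r[x, z]; ryz <- r[y, z]
    p <- c(pc(rxy, rxz, ryz), pc(rxz, rxy, ryz), pc(ryz, rxy, rxz))
    d <- c(rxy, rxz, ryz)
    ok <- !is.na(p) & abs(d) >= tiny
    if (!any(ok)) next
    eps <- mean(abs(p[ok] / d[ok]))
    pairs <- rbind(c(x, y, z), c(x, z, y), c(y, z, x))
    for (k in 1:3) {
      if (is.na(p[k])) next
      a <- pairs[k, 1]; b <- pairs[k, 2]; cc <- pairs[k, 3]
      if (abs(r[a, b]) <= eps * abs(r[a, cc]) &&
          abs(r[a, b]) <= eps * abs(r[b, cc]))
        keep[a, b] <- keep[b, a] <- FALSE
    }
  }
  keep
}

# Spearman by explicit rank-then-Pearson, average ranks for ties.
naive_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# RIF1/RIF2 by an explicit regulator x DE-gene double loop from first
# principles (per-gene means and pairwise correlations recomputed here).
naive_rif <- function(dataset, regulators, de_genes, cond_a, cond_b,
                      method = "spearman") {
  prof <- function(cond) {
    des <- dataset$design
    idx <- which(des$condition == cond)
    v <- dataset$values[, idx, drop = FALSE]
    times <- des$time[idx]
    if (anyNA(times) || !anyDuplicated(times)) return(v)
    tp <- sort(unique(times))
    out <- sapply(tp, function(t) rowMeans(v[, times == t, drop = FALSE]))
    rownames(out) <- rownames(dataset$values)
    out
  }
  pa <- prof(cond_a); pb <- prof(cond_b)
  ea <- rowMeans(pa); eb <- rowMeans(pb)
  cfun <- if (method == "spearman") naive_spearman else
    function(x, y) stats::cor(x, y)
  rif1 <- rif2 <- numeric(length(regulators))
  for (i in seq_along(regulators)) {
    rg <- regulators[i]
    tgts <- setdiff(de_genes, rg)
    s1 <- s2 <- 0
    for (j in tgts) {
      ra <- cfun(pa[rg, ], pa[j, ])
      rb <- cfun(pb[rg, ], pb[j, ])
      pif_j <- (ea[j] + eb[j]) / 2 * (ea[j] - eb[j])
      s1 <- s1 + pif_j * (ra - rb)^2
      s2 <- s2 + (ea[j] * ra)^2 - (eb[j] * rb)^2
    }
    rif1[i] <- s1 / length(tgts)
    rif2[i] <- s2 / length(tgts)
  }
  list(rif1 = rif1, rif2 = rif2)
}

# Random correlation matrix (empirical, hence positive semi-definite).
random_cormat <- function(n_genes, n_obs = 12) {
  r <- stats::cor(matrix(stats::rnorm(n_obs * n_genes), n_obs, n_genes))
  dimnames(r) <- list(paste0("g", seq_len(n_genes)), paste0("g", seq_len(n_genes)))
  r
}

# Small deterministic two-condition dataset without time structure.
toy_dataset <- function(values_a, values_b, genes = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values_a)))
  va <- as.matrix(values_a); vb <- as.matrix(values_b)
  colnames(va) <- paste0("a", seq_len(ncol(va)))
  colnames(vb) <- paste0("b", seq_len(ncol(vb)))
  rownames(va) <- rownames(vb) <- genes
  design <- data.frame(
    sample = c(colnames(va), colnames(vb)),
    condition = rep(c("A", "B"), c(ncol(va), ncol(vb))))
  expression_dataset(cbind(va, vb), design)
}

# Wrap a plain correlation matrix as the package's container.
as_cormat <- function(r, condition = "A", method = "spearman") {
  structure(list(condition = condition, method = method, values = r,
                 n_obs = NA_integer_, undefined = character()),
            class = "rif_cormat")
}
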
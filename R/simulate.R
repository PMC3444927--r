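# Synthetic two-condition longitudinal expression with planted ground truth.
# The generator emulates the study shape the method is built for: two
# conditions followed over ~10 time points, a bimodal abundance
# distribution, a block of abundant differentially expressed "structural"
# target genes, and a silent regulator -- equally expressed in both
# conditions -- whose correlation to those targets flips sign between
# conditions.  Correlation is induced through shared latent time profiles,
# which scales linearly and makes the sign flip explicit.

#' Simulation specification
#'
#' Defaults mirror the intended study design at desk scale: 500 genes of
#' which 50 are annotated regulators, 10 time points x 2 replicates per
#' condition, 20 abundant DE targets, one silent regulator with target
#' correlation +0.9 in condition A and -0.9 in condition B, two co-rewired
#' partner regulators, and a bimodal (two-component Gaussian) abundance
#' distribution whose components meet near abundance 7 -- where the silent
#' regulator sits.
#'
#' @param n_genes,n_regulators Total genes and annotated-regulator count
#'   (regulators are the first `n_regulators` genes).
#' @param n_timepoints,n_replicates Time points per condition and replicates
#'   per time point.
#' @param n_de_targets,de_effect DE target count and their dE (condition A
#'   minus B) in abundance units.
#' @param n_silent,n_corewired Planted silent regulators and co-rewired
#'   partner regulators (partners load on the silent profile with
#'   `partner_loading`).
#' @param rho_a,rho_b Target correlation magnitude (|rho| <= 1) of targets to
#'   the silent regulator profile per condition; opposite signs plant the
#'   rewiring.
#' @param partner_loading Loading of partner regulators on the silent
#'   profile.
#' @param n_modules,module_rho Background co-expression modules and
#'   within-module latent loading.
#' @param profile_sd Temporal (biological) variation of a gene around its
#'   abundance.
#' @param noise_sd Replicate (technical) noise.
#' @param abundance_means,abundance_sds,abundance_weights Two-component
#'   abundance mixture (log-intensity scale).
#' @param silent_abundance Mean abundance of the silent regulator(s), equal
#'   in both conditions.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A validated list of class `rif_simspec`.
#' @export
simulation_spec <- function(n_genes = 500, n_regulators = 50,
                            n_timepoints = 10, n_replicates = 2,
                            n_de_targets = 20, de_effect = 2,
                            n_silent = 1, n_corewired = 2,
                            rho_a = 0.9, rho_b = -0.9,
                            partner_loading = 0.8,
                            n_modules = 10, module_rho = 0.7,
                            profile_sd = 1, noise_sd = 0.25,
                            abundance_means = c(5, 9.5),
                            abundance_sds = c(1.2, 1),
                            abundance_weights = c(0.75, 0.25),
                            silent_abundance = 7, seed = 1L) {
  spec <- list(n_genes = n_genes, n_regulators = n_regulators,
               n_timepoints = n_timepoints, n_replicates = n_replicates,
               n_de_targets = n_de_targets, de_effect = de_effect,
               n_silent = n_silent, n_corewired = n_corewired,
               rho_a = rho_a, rho_b = rho_b, partner_loading = partner_loading,
               n_modules = n_modules, module_rho = module_rho,
               profile_sd = profile_sd, noise_sd = noise_sd,
               abundance_means = abundance_means, abundance_sds = abundance_sds,
               abundance_weights = abundance_weights,
               silent_abundance = silent_abundance, seed = as.integer(seed))
  counts <- c(n_genes, n_regulators, n_timepoints, n_replicates,
              n_de_targets, n_modules)
  if (any(counts < 1)) stop("all counts must be positive")
  if (abs(rho_a) > 1 || abs(rho_b) > 1) stop("|rho| must be <= 1")
  if (n_silent + n_corewired > n_regulators)
    stop("silent + co-rewired regulators exceed regulator count")
  if (n_regulators + n_de_targets > n_genes)
    stop("regulators plus DE targets exceed gene count")
  if (noise_sd < 0 || profile_sd <= 0) stop("invalid noise parameters")
  structure(spec, class = "rif_simspec")
}

draw_mixture <- function(n, means, sds, weights) {
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  stats::rnorm(n, means[comp], sds[comp])
}

#' Simulate a two-condition longitudinal dataset with planted rewiring
#'
#' Per condition, each silent regulator follows a latent standard-normal
#' time profile; each DE target mixes that profile with independent noise at
#' loading rho (rho_a in A, rho_b in B), is shifted by +/- de_effect/2 so it
#' is differentially expressed, and draws its abundance from the upper
#' mixture component (abundant structural genes).  The silent regulator's
#' own mean is identical in both conditions, so it carries no DE signal at
#' all.  Partner regulators load on the silent profile and therefore rewire
#' coordinately.  Remaining genes share per-module latent profiles.
#' Replicates add independent technical noise around time-point values.
#'
#' @param spec A [simulation_spec()].
#' @return List with `dataset` (an [expression_dataset]) and `truth`
#'   (list: `silent_regulators`, `corewired`, `regulators`, `de_genes`,
#'   `modules`, `rho_a`, `rho_b`, `de_effect`, `seed`).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "rif_simspec"))
  set.seed(spec$seed)
  g <- sprintf("G%04d", seq_len(spec$n_genes))
  regulators <- g[seq_len(spec$n_regulators)]
  silent <- regulators[seq_len(spec$n_silent)]
  partners <- if (spec$n_corewired > 0)
    regulators[spec$n_silent + seq_len(spec$n_corewired)] else character()
  targets <- g[spec$n_regulators + seq_len(spec$n_de_targets)]
  background <- setdiff(g, c(regulators, targets))
  modules <- if (length(background))
    structure(rep_len(seq_len(spec$n_modules), length(background)),
              names = background) else integer()

  nt <- spec$n_timepoints
  abund <- structure(draw_mixture(spec$n_genes, spec$abundance_means,
                                  spec$abundance_sds, spec$abundance_weights),
                    names = g)
  # abundant structural targets; silent regulator pinned at the mixture nexus
  abund[targets] <- draw_mixture(spec$n_de_targets, spec$abundance_means[2],
                                 spec$abundance_sds[2], 1)
  abund[silent] <- spec$silent_abundance

  conds <- c("A", "B")
  rho <- c(A = spec$rho_a, B = spec$rho_b)
  shift <- c(A = spec$de_effect / 2, B = -spec$de_effect / 2)
  mats <- list()
  design <- list()
  for (cc in conds) {
    u <- matrix(stats::rnorm(spec$n_silent * nt), spec$n_silent, nt,
                dimnames = list(silent, NULL))
    mod_lat <- matrix(stats::rnorm(spec$n_modules * nt), spec$n_modules, nt)
    z <- matrix(NA_real_, spec$n_genes, nt, dimnames = list(g, NULL))
    z[silent, ] <- u
    # targets couple to the first silent regulator's profile
    rr <- rho[[cc]]
    z[targets, ] <- rr * matrix(u[1, ], spec$n_de_targets, nt, byrow = TRUE) +
      sqrt(1 - rr^2) * matrix(stats::rnorm(spec$n_de_targets * nt),
                              spec$n_de_targets, nt)
    if (length(partners)) {
      lam <- spec$partner_loading
      z[partners, ] <- lam * matrix(u[1, ], length(partners), nt, byrow = TRUE) +
        sqrt(1 - lam^2) * matrix(stats::rnorm(length(partners) * nt),
                                 length(partners), nt)
    }
    free <- setdiff(regulators, c(silent, partners))
    z[free, ] <- matrix(stats::rnorm(length(free) * nt), length(free), nt)
    if (length(background)) {
      lam <- spec$module_rho
      z[background, ] <- lam * mod_lat[modules[background], , drop = FALSE] +
        sqrt(1 - lam^2) * matrix(stats::rnorm(length(background) * nt),
                                 length(background), nt)
    }
    level <- abund + ifelse(g %in% targets, shift[[cc]], 0)
    tp_values <- level + spec$profile_sd * z
    reps <- spec$n_replicates
    x <- tp_values[, rep(seq_len(nt), each = reps), drop = FALSE] +
      matrix(stats::rnorm(spec$n_genes * nt * reps, sd = spec$noise_sd),
             spec$n_genes, nt * reps)
    colnames(x) <- sprintf("%s_t%02d_r%d", cc, rep(seq_len(nt), each = reps),
                           rep(seq_len(reps), nt))
    mats[[cc]] <- x
    design[[cc]] <- data.frame(sample = colnames(x), condition = cc,
                               time = rep(seq_len(nt), each = reps),
                               replicate = rep(seq_len(reps), nt),
                               stringsAsFactors = FALSE)
  }
  dataset <- expression_dataset(do.call(cbind, mats), do.call(rbind, design))
  truth <- list(silent_regulators = silent, corewired = partners,
                regulators = regulators, de_genes = targets,
                modules = modules, rho_a = spec$rho_a, rho_b = spec$rho_b,
                de_effect = spec$de_effect, seed = spec$seed)
  list(dataset = dataset, truth = truth)
}

#' Planted-regulator recovery benchmark
#'
#' Runs the full prioritization pipeline on `n_replicates` independently
#' seeded simulations and records, per replicate, the planted silent
#' regulator's RIF1 and RIF2 ranks among the annotated regulators (DE
#' targets chosen by top-|PIF|, as in a real analysis) and -- optionally --
#' its absolute significant-degree contrast next to the gene-wise median.
#'
#' @param spec A [simulation_spec()]; replicate r uses seed `seed + r - 1`.
#' @param n_replicates Number of replicates (>= 1).
#' @param contrast Also build the two PCIT co-expression networks and the
#'   degree contrast?  (The expensive part; skip for rank-only runs.)
#' @param method Correlation method for the pipeline.
#' @return Data frame with one row per replicate: `replicate`, `seed`,
#'   `rif1_rank`, `rif2_rank`, and when `contrast` is on, `silent_abs_dk`,
#'   `median_abs_dk`.  Attribute `top1_rate` gives the fraction of
#'   replicates with RIF1 rank 1.
#' @export
recovery_benchmark <- function(spec, n_replicates = 25, contrast = FALSE,
                               method = "spearman") {
  stopifnot(n_replicates >= 1)
  rows <- lapply(seq_len(n_replicates), function(r) {
    sp <- spec
    sp$seed <- spec$seed + r - 1L
    sim <- simulate_dataset(sp)
    met <- pif(sim$dataset, "A", "B")
    de <- select_de_genes(met, k = spec$n_de_targets)
    rr <- rif(sim$dataset, "A", "B", regulators = sim$truth$regulators,
              de_genes = de, method = method)
    i <- match(sim$truth$silent_regulators[1], rr$regulator)
    out <- data.frame(replicate = r, seed = sp$seed,
                      rif1_rank = rr$RIF1_rank[i], rif2_rank = rr$RIF2_rank[i])
    if (contrast) {
      net_a <- coexpression_network(sim$dataset, "A", "single", method)
      net_b <- coexpression_network(sim$dataset, "B", "single", method)
      dk <- degree_contrast(net_a, net_b)
      j <- match(sim$truth$silent_regulators[1], dk$gene)
      out$silent_abs_dk <- abs(dk$difference[j])
      out$median_abs_dk <- stats::median(abs(dk$difference))
    }
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "top1_rate") <- mean(res$rif1_rank == 1)
  res
}
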
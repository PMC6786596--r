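#' Configuration for the synthetic expression-matrix generator
#'
#' Describes a microarray-style experiment on the log2 scale: per-gene
#' baseline intensities, planted differentially expressed (DE) genes with
#' known signed log2 effects on chosen stress conditions, planted
#' co-expression modules driven by a shared latent factor, independent
#' Gaussian residual noise, and an intensity threshold below which a
#' measurement is flagged absent.
#'
#' Planted DE genes occupy the first `n_de_genes` rows; module members
#' occupy the following `sum(module_sizes)` rows, so the two ground-truth
#' roles never overlap and the realized contrast effect of a DE gene is
#' exactly its configured effect when `noise_sd = 0`.
#'
#' @param n_genes number of genes.
#' @param design an [experiment_design()]; defaults to the 18-library
#'   aluminium time course.
#' @param n_de_genes number of planted DE genes.
#' @param de_log2_effects signed log2 shifts, one per planted gene;
#'   `NULL` cycles through +/-1.5, +/-2.0, +/-2.5, +/-3.0.
#' @param de_conditions target stress condition per planted gene; `NULL`
#'   cycles through the design's stress conditions (those with a matched
#'   control).
#' @param n_modules number of planted co-expression modules.
#' @param module_sizes module sizes; `NULL` gives 10 genes each.
#' @param module_latent_sd standard deviation of each module's shared
#'   per-library latent factor (log2 units).
#' @param noise_sd residual standard deviation (log2 units); 0 gives a
#'   noise-free matrix.
#' @param baseline_mean_range interval the per-gene baseline log2
#'   intensities are drawn from.
#' @param absent_threshold log2 intensity below which a measurement is
#'   flagged absent.
#' @param seed integer random seed; the same configuration and seed give a
#'   bit-identical matrix.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000, design = al_design(),
                              n_de_genes = 50, de_log2_effects = NULL,
                              de_conditions = NULL, n_modules = 3,
                              module_sizes = NULL, module_latent_sd = 1,
                              noise_sd = 0.2,
                              baseline_mean_range = c(4, 12),
                              absent_threshold = 3, seed = 1) {
  if (is.null(module_sizes)) module_sizes <- rep(10L, n_modules)
  cfg <- list(n_genes = as.integer(n_genes), design = design,
              n_de_genes = as.integer(n_de_genes),
              de_log2_effects = de_log2_effects,
              de_conditions = de_conditions,
              n_modules = as.integer(n_modules),
              module_sizes = as.integer(module_sizes),
              module_latent_sd = module_latent_sd, noise_sd = noise_sd,
              baseline_mean_range = baseline_mean_range,
              absent_threshold = absent_threshold, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' @keywords internal
validate_simulation_config <- function(cfg) {
  if (cfg$n_genes < 1) stop("invalid config: n_genes must be positive")
  validate_design(cfg$design)
  if (cfg$n_de_genes < 0 || cfg$n_de_genes > cfg$n_genes) {
    stop("invalid config: n_de_genes must satisfy 0 <= n_de_genes <= n_genes")
  }
  if (length(cfg$module_sizes) != cfg$n_modules) {
    stop("invalid config: module_sizes must have n_modules entries")
  }
  if (cfg$n_modules > 0 && any(cfg$module_sizes < 2)) {
    stop("invalid config: each module needs at least 2 genes")
  }
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    stop("invalid config: sum(module_sizes) exceeds n_genes")
  }
  if (cfg$n_de_genes + sum(cfg$module_sizes) > cfg$n_genes) {
    stop("invalid config: n_de_genes + sum(module_sizes) exceeds n_genes ",
         "(DE genes and module members are disjoint)")
  }
  if (cfg$noise_sd < 0) stop("invalid config: noise_sd must be >= 0")
  if (cfg$module_latent_sd < 0) {
    stop("invalid config: module_latent_sd must be >= 0")
  }
  if (length(cfg$baseline_mean_range) != 2 ||
      cfg$baseline_mean_range[1] > cfg$baseline_mean_range[2]) {
    stop("invalid config: baseline_mean_range must be an interval c(lo, hi)")
  }
  if (!is.null(cfg$de_log2_effects) &&
      length(cfg$de_log2_effects) != cfg$n_de_genes) {
    stop("invalid config: de_log2_effects must have n_de_genes entries")
  }
  stress_conds <- unique(cfg$design$condition[!is.na(cfg$design$control_condition)])
  if (cfg$n_de_genes > 0 && length(stress_conds) == 0) {
    stop("invalid config: design has no stress condition to plant DE genes on")
  }
  if (!is.null(cfg$de_conditions)) {
    if (length(cfg$de_conditions) != cfg$n_de_genes) {
      stop("invalid config: de_conditions must have n_de_genes entries")
    }
    bad <- setdiff(cfg$de_conditions, stress_conds)
    if (length(bad) > 0) {
      stop("invalid config: de_conditions contains non-stress condition: ",
           bad[1])
    }
  }
  invisible(cfg)
}

#' Simulate an expression experiment with known ground truth
#'
#' Each gene's log2 profile is `baseline + DE effect + module latent +
#' noise`: the baseline is uniform over `baseline_mean_range` and constant
#' across libraries; a planted DE gene has its effect added to every
#' library of its target stress condition; module members share one
#' per-library latent draw `N(0, module_latent_sd^2)`; residual noise is
#' independent `N(0, noise_sd^2)`. Present flags are
#' `intensity >= absent_threshold`.
#'
#' @param config a [simulation_config()].
#' @return List with elements `matrix` (an [expression_matrix()]) and
#'   `truth` (data frame: `gene_id`, `role` in de/module/background,
#'   `condition` targeted by the planted effect, `effect`, `module_id`).
#' @examples
#' sim <- simulate_experiment(simulation_config(n_genes = 100, seed = 42))
#' sim$matrix
#' table(sim$truth$role)
#' @export
simulate_experiment <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  d <- config$design
  n_lib <- nrow(d)
  n <- config$n_genes
  gene_ids <- sprintf("g%0*d", nchar(as.character(n)), seq_len(n))

  baseline <- stats::runif(n, config$baseline_mean_range[1],
                           config$baseline_mean_range[2])
  values <- matrix(baseline, n, n_lib,
                   dimnames = list(gene_ids, d$library_id))

  # planted DE effects on the target stress condition's libraries
  stress_conds <- unique(d$condition[!is.na(d$control_condition)])
  effects <- numeric(0)
  de_cond <- character(0)
  if (config$n_de_genes > 0) {
    effects <- config$de_log2_effects
    if (is.null(effects)) {
      mags <- rep(c(1.5, 2.0, 2.5, 3.0), length.out = config$n_de_genes)
      effects <- mags * rep_len(c(1, -1), config$n_de_genes)
    }
    de_cond <- config$de_conditions
    if (is.null(de_cond)) {
      de_cond <- rep_len(stress_conds, config$n_de_genes)
    }
    for (i in seq_len(config$n_de_genes)) {
      libs <- d$library_id[d$condition == de_cond[i]]
      values[i, libs] <- values[i, libs] + effects[i]
    }
  }

  # shared latent factor per module, one draw per library
  module_id <- rep(NA_integer_, n)
  if (config$n_modules > 0) {
    latent <- matrix(stats::rnorm(config$n_modules * n_lib,
                                  sd = config$module_latent_sd),
                     config$n_modules, n_lib)
    start <- config$n_de_genes
    for (m in seq_len(config$n_modules)) {
      idx <- start + seq_len(config$module_sizes[m])
      values[idx, ] <- sweep(values[idx, , drop = FALSE], 2, latent[m, ], "+")
      module_id[idx] <- m
      start <- start + config$module_sizes[m]
    }
  }

  values <- values + matrix(stats::rnorm(n * n_lib, sd = config$noise_sd),
                            n, n_lib)
  present <- values >= config$absent_threshold

  role <- rep("background", n)
  if (config$n_de_genes > 0) role[seq_len(config$n_de_genes)] <- "de"
  role[!is.na(module_id)] <- "module"
  truth <- data.frame(
    gene_id = gene_ids, role = role,
    condition = NA_character_, effect = NA_real_,
    module_id = module_id, stringsAsFactors = FALSE
  )
  if (config$n_de_genes > 0) {
    truth$condition[seq_len(config$n_de_genes)] <- de_cond
    truth$effect[seq_len(config$n_de_genes)] <- effects
  }
  list(matrix = expression_matrix(values, d, present), truth = truth)
}

#' Write simulation ground truth as TSV
#' @param truth the `truth` element of a [simulate_experiment()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
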
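#' Analysis run configuration
#'
#' Declarative configuration for [run_analysis()].  Two input modes:
#' `"diversity"` reads a precomputed long-format diversity table (used
#' e.g. for rescaled species-richness reanalyses); `"otu"` reads an OTU
#' count table + metadata + newick tree and computes rarefied bootstrap
#' Faith's PD first.
#'
#' @param mode `"diversity"` or `"otu"`.
#' @param diversity_path TSV path (mode `"diversity"`).
#' @param otu_path,meta_path,tree_path input paths (mode `"otu"`).
#' @param out_dir output directory.
#' @param seed global seed; every fit derives its own seed from it.
#' @param min_reads,n_timepoints completeness filter (see
#'   [filter_complete()]).
#' @param depth,n_boot rarefaction settings (mode `"otu"`).
#' @param priors a [prior_spec()].
#' @param chains,burnin,iter MCMC protocol per fit.
#' @param bridge_boot bootstrap resamples for the evidence MC SE.
#' @param model2_groups which groups also get the state-transition model:
#'   `"non-placebo"` (default, the study protocol) or a character vector
#'   of group names.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("diversity", "otu"),
                       diversity_path = NULL, otu_path = NULL,
                       meta_path = NULL, tree_path = NULL,
                       out_dir = "results", seed = 1L,
                       min_reads = 1000, n_timepoints = 6,
                       depth = 1000, n_boot = 100,
                       priors = prior_spec(),
                       chains = 4, burnin = 1000, iter = 9000,
                       bridge_boot = 20,
                       model2_groups = "non-placebo") {
  mode <- match.arg(mode)
  paths <- if (mode == "diversity") c(diversity_path) else
    c(otu_path, meta_path, tree_path)
  structure(list(mode = mode, diversity_path = diversity_path,
                 otu_path = otu_path, meta_path = meta_path,
                 tree_path = tree_path, out_dir = out_dir,
                 seed = as.integer(seed), min_reads = min_reads,
                 n_timepoints = n_timepoints, depth = depth,
                 n_boot = n_boot, priors = priors, chains = chains,
                 burnin = burnin, iter = iter, bridge_boot = bridge_boot,
                 model2_groups = model2_groups),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' All fields of [run_config()] are accepted; relative input paths are
#' resolved against the JSON file's directory.
#' @param path JSON config path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$priors)) raw$priors <- do.call(prior_spec, raw$priors)
  base <- dirname(normalizePath(path))
  for (f in c("diversity_path", "otu_path", "meta_path", "tree_path")) {
    if (!is.null(raw[[f]]) && !file.exists(raw[[f]]))
      raw[[f]] <- file.path(base, raw[[f]])
  }
  do.call(run_config, raw)
}

.log_msg <- function(con, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Reads (or receives) per-sample diversity data, converts trajectories to
#' displacement from baseline, fits the recovery-only model to every
#' treatment group x site and additionally the state-transition model to
#' the configured groups (by default all non-placebo groups), estimates
#' both marginal likelihoods by bridge sampling, and tabulates Bayes
#' factors.  Groups that fail (too few subjects, non-convergence) are
#' skipped with a logged reason; model selection is refused for
#' non-converged fits.
#'
#' @param config a [run_config()].
#' @param diversity optional in-memory diversity data.frame overriding the
#'   configured input paths (used by the simulate path and in tests).
#' @return Invisibly, a list: `params` (long summary table mirroring the
#'   per-group parameter-table layout), `bf_table` (one row per
#'   state-transition comparison), `fits` (named list of `posterior_fit`
#'   pairs), `skipped`.  Tables are also written as CSV under
#'   `config$out_dir`, with a JSON diagnostics file and a log.
#' @export
run_analysis <- function(config, diversity = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(log_con))

  if (is.null(diversity)) {
    if (config$mode == "diversity") {
      .log_msg(log_con, "reading diversity table: ", config$diversity_path)
      diversity <- read_diversity_table(config$diversity_path)
    } else {
      .log_msg(log_con, "reading OTU input: ", config$otu_path)
      inp <- read_otu_input(config$otu_path, config$meta_path,
                            config$tree_path)
      diversity <- diversity_table(inp$otu, inp$meta, inp$tree,
                                   depth = config$depth,
                                   n_boot = config$n_boot,
                                   min_reads = config$min_reads,
                                   n_timepoints = config$n_timepoints,
                                   seed = config$seed)
    }
  }
  if (nrow(diversity) == 0) stop("no samples after input processing")
  disp <- to_displacement(diversity)

  cells <- unique(disp[, c("group", "site")])
  cells <- cells[order(cells$site, cells$group), ]
  params <- list(); bf_rows <- list(); fits <- list(); skipped <- list()
  for (i in seq_len(nrow(cells))) {
    grp <- cells$group[i]; site <- cells$site[i]
    d <- disp[disp$group == grp & disp$site == site, ]
    tag <- paste(site, grp, sep = ":")
    n_subj <- length(unique(d$subject))
    if (n_subj < 1 || length(unique(d$time)) < 2) {
      skipped[[tag]] <- "too little data"
      .log_msg(log_con, "skipping ", tag, ": too little data")
      next
    }
    fit_model2 <- if (identical(config$model2_groups, "non-placebo"))
      grp != "placebo" else grp %in% config$model2_groups
    .log_msg(log_con, "fitting ", tag, " (n=", n_subj, ", model 2: ",
             fit_model2, ")")
    seed_i <- (config$seed * 1000L + i * 7L) %% .Machine$integer.max
    mc <- mcmc_config(chains = config$chains, burnin = config$burnin,
                      iter = config$iter, seed = seed_i)
    f1 <- fit_group(d, model = 1, priors = config$priors, mcmc = mc)
    fits[[tag]] <- list(model1 = f1)
    add_summary <- function(fit, model) {
      s <- fit$summary
      data.frame(site = site, group = grp, model = model, s,
                 converged = fit$converged, stringsAsFactors = FALSE)
    }
    params[[length(params) + 1]] <- add_summary(f1, 1)
    if (!fit_model2) next
    mc2 <- mcmc_config(chains = config$chains, burnin = config$burnin,
                       iter = config$iter, seed = seed_i + 1L)
    f2 <- fit_group(d, model = 2, priors = config$priors, mcmc = mc2)
    fits[[tag]]$model2 <- f2
    params[[length(params) + 1]] <- add_summary(f2, 2)
    if (!f1$converged || !f2$converged) {
      skipped[[tag]] <- "non-converged fit: model selection refused"
      .log_msg(log_con, tag, ": non-converged fit, refusing model selection")
      next
    }
    ev1 <- log_marginal_likelihood(f1, n_boot = config$bridge_boot,
                                   seed = seed_i + 2L)
    ev2 <- log_marginal_likelihood(f2, n_boot = config$bridge_boot,
                                   seed = seed_i + 3L)
    bf <- bayes_factor(ev2, ev1)
    .log_msg(log_con, tag, sprintf(": logML1 = %.2f, logML2 = %.2f, BF = %.3g (%s)",
                                   ev1$logml, ev2$logml, bf$bf, bf$label))
    bf_rows[[length(bf_rows) + 1]] <- data.frame(
      group = grp, site = site, logml1 = ev1$logml, logml2 = ev2$logml,
      bf = bf$bf, label = bf$label, stringsAsFactors = FALSE)
  }
  if (length(params) == 0) stop("no group could be fitted")

  params <- do.call(rbind, params)
  bf_table <- if (length(bf_rows) > 0) do.call(rbind, bf_rows) else
    data.frame(group = character(), site = character(), logml1 = numeric(),
               logml2 = numeric(), bf = numeric(), label = character())
  utils::write.csv(params, file.path(config$out_dir, "params_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(bf_table, file.path(config$out_dir, "bf_table.csv"),
                   row.names = FALSE)
  diag <- lapply(fits, function(pair) lapply(pair, function(f)
    list(converged = f$converged, rhat = as.list(f$rhat),
         n_eff = as.list(f$ess))))
  jsonlite::write_json(list(seed = config$seed, diagnostics = diag,
                            skipped = skipped),
                       file.path(config$out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  .log_msg(log_con, "done: ", nrow(bf_table), " model comparisons")
  invisible(list(params = params, bf_table = bf_table, fits = fits,
                 skipped = skipped))
}
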
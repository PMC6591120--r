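#' Default treatment-group archetypes
#'
#' One row per treatment group x body site with the default generating
#' parameters for the synthetic-data module: the published posterior
#' medians of the state-transition model for the four antibiotics, and a
#' flat (no-response) placebo arm.  Subject counts follow the study design
#' (placebo 22 gut / 21 oral; ciprofloxacin 9, clindamycin 9, minocycline
#' 10, amoxicillin 12 in both sites).
#'
#' @return data.frame: `group`, `site`, `n`, `D`, `A`, `phi1`, `phi2`.
#' @export
default_archetypes <- function() {
  gut <- data.frame(
    group = c("placebo", "ciprofloxacin", "clindamycin", "minocycline",
              "amoxicillin"),
    site = "gut",
    n = c(22L, 9L, 9L, 10L, 12L),
    D = c(0, 7.9, 8.45, 2.74, 1.34),
    A = c(0, 0.8, 0.84, -0.23, -0.03),
    phi1 = c(0, -0.2, 0, 0.33, -1.53),
    phi2 = c(0.5, 0.41, 0.56, 1.65, 0.09),
    stringsAsFactors = FALSE)
  oral <- data.frame(
    group = gut$group,
    site = "oral",
    n = c(21L, 9L, 9L, 10L, 12L),
    D = c(0, 2.99, 3.56, 3.38, 4.24),
    A = c(0, -0.63, -0.73, 0.53, -0.13),
    phi1 = c(0, 0.19, 0.66, -0.73, -1.58),
    phi2 = c(0.5, 1.56, 1.61, 1.27, -0.33),
    stringsAsFactors = FALSE)
  rbind(gut, oral)
}

#' Synthetic study design
#'
#' Describes the world the generator emulates: treatment-group archetype
#' parameters, subjects per group, sampling times, observation noise and
#' the across-subject baseline-diversity distribution.
#'
#' @param groups data.frame like [default_archetypes()] (columns `group`,
#'   `site`, `n`, `D`, `A`, `phi1`, `phi2`).
#' @param timepoints named numeric vector of sampling times in months;
#'   entries `<= 0` are baseline.
#' @param sigma observation-noise SD in diversity units (default 0.4).
#' @param baseline_mean named vector of mean baseline diversity per site.
#' @param baseline_sd across-subject SD of baseline diversity.
#' @param read_range uniform range for simulated per-sample read depth;
#'   the default floor 1100 survives the ">1000 reads" filter.
#' @param dropout fraction of samples given sub-threshold depth (in
#'   (0, 1000] reads), for exercising the completeness filter.
#' @param seed integer seed.
#' @return A `study_design` list.
#' @export
study_design <- function(groups = default_archetypes(),
                         timepoints = default_timepoints(),
                         sigma = 0.4,
                         baseline_mean = c(gut = 20, oral = 15),
                         baseline_sd = 2,
                         read_range = c(1100, 20000),
                         dropout = 0, seed = 1L) {
  stopifnot(all(c("group", "site", "n", "D", "A", "phi1", "phi2")
                %in% names(groups)),
            all(groups$n >= 0), sigma >= 0, baseline_sd >= 0,
            !is.unsorted(timepoints), dropout >= 0, dropout < 1)
  structure(list(groups = groups, timepoints = timepoints, sigma = sigma,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 read_range = read_range, dropout = dropout,
                 seed = as.integer(seed)),
            class = "study_design")
}

.design_truth <- function(design) {
  list(groups = design$groups, sigma = design$sigma,
       timepoints = as.list(design$timepoints),
       baseline_mean = as.list(design$baseline_mean),
       baseline_sd = design$baseline_sd, seed = design$seed)
}

#' Generate a long-format per-sample diversity table with known truth
#'
#' Per subject: a baseline diversity is drawn from the site's baseline
#' distribution; each post-baseline observation is
#' `baseline - x_model(t; group params) + Normal(0, sigma)`, where
#' `x_model` is the state-transition displacement model (placebo rows use
#' zero displacement).  Deterministic given the design seed.
#'
#' @param design a [study_design()].
#' @return A `synthetic_dataset` list: `diversity` (data.frame `sample`,
#'   `subject`, `group`, `site`, `timepoint`, `time`, `reads`,
#'   `diversity`) and `truth` (the generating parameters).
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  tp <- design$timepoints
  rows <- list()
  for (g in seq_len(nrow(design$groups))) {
    arch <- design$groups[g, ]
    if (arch$n == 0) next
    zero_resp <- arch$group == "placebo" || (arch$D == 0 && arch$A == 0)
    for (s in seq_len(arch$n)) {
      subject <- sprintf("%s_%s_%02d", substr(arch$site, 1, 1), arch$group, s)
      baseline <- stats::rnorm(1, design$baseline_mean[[arch$site]],
                               design$baseline_sd)
      x <- if (zero_resp) rep(0, length(tp)) else
        model2_displacement(impulse_params(arch$D, arch$phi1, arch$phi2,
                                           arch$A), pmax(tp, 0))
      noise <- stats::rnorm(length(tp), 0, design$sigma)
      noise[tp <= 0] <- 0
      div <- baseline - x + noise
      div[tp <= 0] <- baseline
      reads <- round(stats::runif(length(tp), design$read_range[1],
                                  design$read_range[2]))
      if (design$dropout > 0) {
        drop <- stats::runif(length(tp)) < design$dropout
        reads[drop] <- sample.int(1000, sum(drop), replace = TRUE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        sample = paste0(subject, "_t", seq_along(tp)),
        subject = subject, group = arch$group, site = arch$site,
        timepoint = names(tp), time = unname(tp), reads = reads,
        diversity = div, stringsAsFactors = FALSE)
    }
  }
  diversity <- if (length(rows) == 0) {
    data.frame(sample = character(), subject = character(),
               group = character(), site = character(),
               timepoint = character(), time = numeric(),
               reads = numeric(), diversity = numeric())
  } else do.call(rbind, rows)
  rownames(diversity) <- NULL
  structure(list(diversity = diversity, truth = .design_truth(design)),
            class = "synthetic_dataset")
}

#' Generate an OTU count table and tree realizing a design
#'
#' Exercises the diversity module end-to-end: a random rooted tree with
#' unit-scale branch lengths is drawn, each sample's target diversity is
#' produced as in [generate_dataset()], and reads are drawn from a
#' multinomial over the smallest nested taxon set whose Faith's PD best
#' matches the target (so expected PD tracks the target trajectory;
#' targets are clamped to the range the tree can express).
#'
#' @param design a [study_design()]; baseline means larger than the total
#'   tree PD are clamped, so scale them to the tree (or the tree to them).
#' @param n_taxa number of tips of the random tree (>= 2).
#' @param tree optional `phylo` to use instead of a random tree.
#' @return list: `otu` (taxa x samples count matrix), `meta` (per-sample
#'   metadata incl. `reads`), `tree`, `target` (per-sample target
#'   diversity), `truth`.
#' @export
generate_otu_dataset <- function(design, n_taxa = 64, tree = NULL) {
  stopifnot(inherits(design, "study_design"), n_taxa >= 2)
  ds <- generate_dataset(design)
  div <- ds$diversity
  set.seed(design$seed + 1L)
  if (is.null(tree)) {
    tree <- ape::rtree(n_taxa)
    tree$tip.label <- sprintf("taxon%03d", seq_len(n_taxa))
  }
  tips <- tree$tip.label
  # nested taxon sets in a fixed shuffled order; cumulative PD lookup
  ord <- sample(tips)
  cum_pd <- vapply(seq_along(ord), function(m) faith_pd(tree, ord[seq_len(m)]),
                   numeric(1))
  otu <- matrix(0L, nrow = length(tips), ncol = nrow(div),
                dimnames = list(tips, div$sample))
  for (i in seq_len(nrow(div))) {
    m <- which.min(abs(cum_pd - div$diversity[i]))
    present <- ord[seq_len(m)]
    p <- stats::runif(m, 0.5, 1.5)
    otu[present, i] <- stats::rmultinom(1, div$reads[i], p / sum(p))[, 1]
  }
  meta <- div[, c("sample", "subject", "group", "site", "timepoint",
                  "time", "reads")]
  list(otu = otu, meta = meta, tree = tree, target = div$diversity,
       truth = ds$truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits the same TSV format the diversity module reads, plus a
#' ground-truth JSON.  For OTU datasets also writes the count TSV and the
#' newick tree.
#'
#' @param dataset result of [generate_dataset()] or
#'   [generate_otu_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (!is.null(dataset$diversity)) {
    p <- file.path(dir, "diversity.tsv")
    utils::write.table(dataset$diversity, p, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(dataset$otu)) {
    p <- file.path(dir, "otu.tsv")
    utils::write.table(data.frame(taxon = rownames(dataset$otu),
                                  dataset$otu, check.names = FALSE),
                       p, sep = "\t", row.names = FALSE, quote = FALSE)
    m <- file.path(dir, "metadata.tsv")
    utils::write.table(dataset$meta, m, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    tr <- file.path(dir, "tree.nwk")
    ape::write.tree(dataset$tree, tr)
    paths <- c(paths, p, m, tr)
  }
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(dataset$truth, tj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tj))
}
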
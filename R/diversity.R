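#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths of the minimal subtree connecting the observed
#' taxa, by default including the path up to the root (the common
#' convention when PD is compared across samples sharing one tree).
#'
#' @param tree a rooted `phylo` tree (ape) with non-negative edge lengths.
#' @param present_taxa character vector of observed taxon labels; must all
#'   be tip labels of `tree`.  An empty set has PD 0.
#' @param include_root include the branches from the spanning subtree's
#'   crown up to the tree root (default `TRUE`).
#' @return Faith's PD in branch-length units.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):1,C:3):0;")
#' faith_pd(tr, c("A", "C"))  # 1 + 1 + 3 = 5
#' @export
faith_pd <- function(tree, present_taxa, include_root = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  present_taxa <- unique(as.character(present_taxa))
  if (length(present_taxa) == 0) return(0)
  unknown <- setdiff(present_taxa, tree$tip.label)
  if (length(unknown) > 0)
    stop("taxa not in tree: ", paste(unknown, collapse = ", "))

  n_tip <- length(tree$tip.label)
  # mark, for every edge, whether its child subtends a present tip
  subtends <- logical(n_tip + tree$Nnode)
  subtends[match(present_taxa, tree$tip.label)] <- TRUE
  edge <- tree$edge
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    if (subtends[po[i, 2]]) subtends[po[i, 1]] <- TRUE
  }
  keep <- subtends[edge[, 2]]
  if (!include_root) {
    # drop edges on the chain from the root down to the crown (MRCA) of the
    # present set: those have a child that subtends ALL present tips and is
    # an ancestor of every present tip
    n_present <- integer(n_tip + tree$Nnode)
    n_present[match(present_taxa, tree$tip.label)] <- 1L
    for (i in seq_len(nrow(po)))
      n_present[po[i, 1]] <- n_present[po[i, 1]] + n_present[po[i, 2]]
    keep <- keep & n_present[edge[, 2]] < length(present_taxa)
  }
  sum(tree$edge.length[keep])
}

#' Rarefied bootstrap Faith's PD for one sample
#'
#' Repeatedly subsamples a fixed number of reads without replacement from a
#' sample's taxon counts and computes Faith's PD of the taxa present in
#' each rarefied subsample, making PD comparable across samples of unequal
#' depth.
#'
#' @param counts named integer vector of per-taxon read counts (names are
#'   taxon labels resolvable in `tree`).
#' @param tree a rooted `phylo` tree.
#' @param depth rarefaction depth (reads per bootstrap); the sample must
#'   have at least this many reads, otherwise an error — such samples
#'   should already have been removed by [filter_complete()].
#' @param n_boot number of bootstrap subsamples (study convention: 100).
#' @param seed optional integer seed for reproducibility.
#' @param include_root passed to [faith_pd()].
#' @return List with `mean`, `sd` (across bootstraps) and `n_boot`.
#' @export
bootstrap_pd <- function(counts, tree, depth = 1000, n_boot = 100,
                         seed = NULL, include_root = TRUE) {
  stopifnot(n_boot >= 1, depth >= 1)
  counts <- counts[counts > 0]
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named by taxon")
  total <- sum(counts)
  if (total < depth)
    stop(sprintf("sample has %d reads, fewer than rarefaction depth %d",
                 total, depth))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  taxa <- names(counts)
  pd <- numeric(n_boot)
  if (total == depth) {
    # subsampling without replacement at full depth always returns the
    # whole sample
    pd[] <- faith_pd(tree, taxa, include_root)
  } else {
    reads <- rep.int(seq_along(taxa), counts)
    for (b in seq_len(n_boot)) {
      picked <- unique(reads[sample.int(total, depth)])
      pd[b] <- faith_pd(tree, taxa[picked], include_root)
    }
  }
  list(mean = mean(pd), sd = stats::sd(pd), n_boot = n_boot)
}

#' Retain subjects with a complete, sufficiently deep sample series
#'
#' Study filter: a subject (per body site) is kept only if it has all
#' `n_timepoints` samples and every one strictly exceeds `min_reads` reads.
#' Idempotent.
#'
#' @param meta data.frame with at least columns `subject`, `site`,
#'   `timepoint` and `reads` (one row per sample).
#' @param min_reads threshold; samples must have **more** than this many
#'   reads (default 1000, i.e. ">1,000 reads").
#' @param n_timepoints required number of samples per subject x site
#'   (default 6).
#' @return The rows of `meta` belonging to surviving subject x site series.
#' @export
filter_complete <- function(meta, min_reads = 1000, n_timepoints = 6) {
  stopifnot(all(c("subject", "site", "timepoint", "reads") %in% names(meta)))
  if (nrow(meta) == 0) return(meta)
  key <- interaction(meta$subject, meta$site, drop = TRUE)
  ok <- vapply(split(meta, key), function(d) {
    nrow(d) == n_timepoints &&
      length(unique(d$timepoint)) == n_timepoints &&
      all(d$reads > min_reads)
  }, logical(1))
  meta[key %in% names(ok)[ok], , drop = FALSE]
}

#' Convert per-subject diversity trajectories to displacement series
#'
#' Displacement is defined per subject relative to the mean baseline
#' diversity: `x(t) = baseline - diversity(t)`, so a drop in diversity is a
#' *positive* displacement.  Baseline rows (time <= 0) define the
#' equilibrium and are excluded from the output (their displacement is 0
#' by construction and would anchor the fit with a zero residual).
#'
#' @param div data.frame with columns `subject`, `site`, `group`, `time`
#'   (months; baseline rows have `time <= 0`), `diversity`, and optionally
#'   `diversity_sd` (bootstrap SD, carried through).
#' @return A `displacement_series` data.frame: `subject`, `site`, `group`,
#'   `time`, `x` (+ `x_sd` when input had `diversity_sd`), plus a `baseline`
#'   column with each subject's equilibrium diversity.
#' @export
to_displacement <- function(div) {
  stopifnot(all(c("subject", "site", "group", "time", "diversity")
                %in% names(div)))
  key <- interaction(div$subject, div$site, drop = TRUE)
  out <- lapply(split(div, key), function(d) {
    base_rows <- d$time <= 0
    if (!any(base_rows))
      stop("subject ", d$subject[1], " (", d$site[1], ") has no baseline sample")
    baseline <- mean(d$diversity[base_rows])
    d <- d[!base_rows, , drop = FALSE]
    d <- d[order(d$time), , drop = FALSE]
    res <- data.frame(subject = d$subject, site = d$site, group = d$group,
                      time = d$time, x = baseline - d$diversity,
                      baseline = baseline, stringsAsFactors = FALSE)
    if ("diversity_sd" %in% names(d)) res$x_sd <- d$diversity_sd
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("displacement_series", "data.frame")
  out
}

#' Default mapping of study timepoint labels to months
#'
#' Baseline is time 0 (start of the 10-day course); "end of course" is
#' 0.33 months, then 1, 2, 4, and 12 months *after treatment end*.
#' @return Named numeric vector of times in months.
#' @export
default_timepoints <- function() {
  c(baseline = 0, end_course = 0.33, m1 = 1.33, m2 = 2.33,
    m4 = 4.33, m12 = 12.33)
}

#' Compute a per-sample diversity table from an OTU table and tree
#'
#' Runs [filter_complete()] then [bootstrap_pd()] on every surviving
#' sample.
#'
#' @param otu numeric matrix of read counts, taxa in rows (rownames =
#'   taxon labels), samples in columns (colnames = sample IDs).
#' @param meta per-sample metadata data.frame: `sample`, `subject`,
#'   `group`, `site`, `timepoint` (label), `time` (months), `reads`
#'   (if absent, computed as column sums of `otu`).
#' @param tree rooted `phylo` tree covering the taxa.
#' @param depth,n_boot,include_root rarefaction settings, see
#'   [bootstrap_pd()].
#' @param min_reads,n_timepoints filtering, see [filter_complete()].
#' @param seed integer seed controlling all bootstrap resampling.
#' @return Long-format data.frame: `sample`, `subject`, `group`, `site`,
#'   `timepoint`, `time`, `reads`, `diversity` (bootstrap mean PD),
#'   `diversity_sd`.
#' @export
diversity_table <- function(otu, meta, tree, depth = 1000, n_boot = 100,
                            min_reads = 1000, n_timepoints = 6,
                            include_root = TRUE, seed = 1L) {
  stopifnot(is.matrix(otu), !is.null(rownames(otu)), !is.null(colnames(otu)))
  if (!("reads" %in% names(meta)))
    meta$reads <- colSums(otu)[match(meta$sample, colnames(otu))]
  meta <- filter_complete(meta, min_reads, n_timepoints)
  if (nrow(meta) == 0) {
    return(data.frame(sample = character(), subject = character(),
                      group = character(), site = character(),
                      timepoint = character(), time = numeric(),
                      reads = numeric(), diversity = numeric(),
                      diversity_sd = numeric()))
  }
  set.seed(seed)
  pd <- lapply(meta$sample, function(s) {
    cnt <- otu[, s]
    names(cnt) <- rownames(otu)
    bootstrap_pd(cnt, tree, depth = depth, n_boot = n_boot,
                 include_root = include_root)
  })
  data.frame(sample = meta$sample, subject = meta$subject,
             group = meta$group, site = meta$site,
             timepoint = meta$timepoint, time = meta$time,
             reads = meta$reads,
             diversity = vapply(pd, `[[`, numeric(1), "mean"),
             diversity_sd = vapply(pd, `[[`, numeric(1), "sd"),
             stringsAsFactors = FALSE)
}

#' Read an OTU table, sample metadata and tree from disk
#'
#' @param otu_path TSV of counts, taxa x samples, first column taxon label.
#' @param meta_path TSV with columns `sample`, `subject`, `group`, `site`,
#'   `timepoint`, `time` and optionally `reads`.
#' @param tree_path newick file.
#' @return list(otu = matrix, meta = data.frame, tree = phylo).
#' @export
read_otu_input <- function(otu_path, meta_path, tree_path) {
  raw <- utils::read.delim(otu_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  otu <- as.matrix(raw[, -1, drop = FALSE])
  rownames(otu) <- raw[[1]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  tree <- ape::read.tree(tree_path)
  list(otu = otu, meta = meta, tree = tree)
}

#' Read a precomputed long-format diversity table
#'
#' Input mode for reanalyses where diversity (e.g. rescaled species
#' richness) is already computed: a TSV with columns `subject`, `group`,
#' `site`, `time`, `diversity` and optionally `diversity_sd`, `reads`.
#' @param path TSV path.
#' @return data.frame ready for [to_displacement()].
#' @export
read_diversity_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "site", "time", "diversity")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("diversity table missing columns: ", paste(miss, collapse = ", "))
  d
}
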
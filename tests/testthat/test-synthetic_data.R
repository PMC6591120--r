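test_that("empty designs give empty tables", {
  des <- one_group_design(n = 0)
  expect_equal(nrow(generate_dataset(des)$diversity), 0)
})

test_that("noise-free placebo is flat at each subject's baseline", {
  des <- one_group_design(group = "placebo", n = 5, D = 0, A = 0,
                          sigma = 0, seed = 3)
  div <- generate_dataset(des)$diversity
  for (s in split(div, div$subject))
    expect_true(all(s$diversity == s$diversity[1]))
})

test_that("noise-free trajectories equal the closed-form model exactly", {
  des <- one_group_design(n = 1, sigma = 0, seed = 6)  # gut clindamycin
  div <- generate_dataset(des)$diversity
  p <- impulse_params(8.45, 0, 0.56, A = 0.84)
  post <- div[div$time > 0, ]
  expect_equal(post$diversity,
               div$diversity[div$time <= 0] - model2_displacement(p, post$time),
               tolerance = 1e-12)
  # round trip through to_displacement recovers the model curve
  disp <- to_displacement(div)
  expect_equal(disp$x, model2_displacement(p, disp$time), tolerance = 1e-12)
})

test_that("generation is deterministic given the seed", {
  d1 <- generate_dataset(study_design(seed = 17))
  d2 <- generate_dataset(study_design(seed = 17))
  expect_identical(d1, d2)
  d3 <- generate_dataset(study_design(seed = 18))
  expect_false(identical(d1$diversity$diversity, d3$diversity$diversity))
})

test_that("default design matches the study shape", {
  div <- generate_dataset(study_design(seed = 1))$diversity
  counts <- aggregate(subject ~ group + site, div,
                      function(s) length(unique(s)))
  expect_equal(counts$subject[counts$group == "placebo" &
                              counts$site == "gut"], 22)
  expect_equal(counts$subject[counts$group == "placebo" &
                              counts$site == "oral"], 21)
  expect_equal(counts$subject[counts$group == "ciprofloxacin" &
                              counts$site == "gut"], 9)
  expect_equal(counts$subject[counts$group == "minocycline" &
                              counts$site == "gut"], 10)
  expect_equal(counts$subject[counts$group == "amoxicillin" &
                              counts$site == "gut"], 12)
  expect_equal(sort(unique(div$time)), unname(default_timepoints()))
  expect_true(all(div$reads > 1000))  # defaults survive the filter
})

test_that("otu datasets exercise the diversity module end-to-end", {
  des <- one_group_design(n = 4, sigma = 0, seed = 5,
                          baseline_mean = c(gut = 8, oral = 6),
                          baseline_sd = 0.5)
  ds <- generate_otu_dataset(des, n_taxa = 48)
  expect_setequal(rownames(ds$otu), ds$tree$tip.label)
  expect_equal(colnames(ds$otu), ds$meta$sample)
  tab <- diversity_table(ds$otu, ds$meta, ds$tree, depth = 1000,
                         n_boot = 25, seed = 2)
  expect_equal(nrow(tab), nrow(ds$meta))
  disp <- to_displacement(tab)
  # strong perturbation: clearly positive displacement at the first two
  # post-treatment timepoints
  early <- disp$x[disp$time < 2]
  expect_gt(mean(early), 0.5)
})

test_that("dropout samples are removed by the completeness filter", {
  des <- one_group_design(n = 6, seed = 8, dropout = 0.2)
  ds <- generate_otu_dataset(des, n_taxa = 32)
  kept <- filter_complete(ds$meta)
  dropped <- setdiff(ds$meta$subject, kept$subject)
  expect_gt(length(dropped), 0)
  for (s in dropped)
    expect_true(any(ds$meta$reads[ds$meta$subject == s] <= 1000))
  for (s in unique(kept$subject))
    expect_true(all(kept$reads[kept$subject == s] > 1000))
})

test_that("identical compositions give a near-flat displacement series", {
  des <- one_group_design(group = "placebo", n = 3, D = 0, A = 0,
                          sigma = 0, seed = 12,
                          baseline_mean = c(gut = 7, oral = 6),
                          baseline_sd = 0)
  ds <- generate_otu_dataset(des, n_taxa = 32)
  tab <- diversity_table(ds$otu, ds$meta, ds$tree, depth = 1000,
                         n_boot = 40, seed = 3)
  disp <- to_displacement(tab)
  expect_lt(max(abs(disp$x)), 0.5)  # only multinomial/bootstrap jitter
})

test_that("write_synthetic_dataset round-trips through the readers", {
  des <- one_group_design(n = 2, seed = 4)
  dir <- file.path(tempdir(), "synthds")
  on.exit(unlink(dir, recursive = TRUE))
  write_synthetic_dataset(generate_dataset(des), dir)
  div <- read_diversity_table(file.path(dir, "diversity.tsv"))
  expect_equal(nrow(div), 2 * 6)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$groups$D, 8.45)
  ds2 <- generate_otu_dataset(des, n_taxa = 16)
  write_synthetic_dataset(ds2, dir)
  inp <- read_otu_input(file.path(dir, "otu.tsv"),
                        file.path(dir, "metadata.tsv"),
                        file.path(dir, "tree.nwk"))
  expect_equal(dim(inp$otu), dim(ds2$otu))
  expect_equal(sum(inp$otu), sum(ds2$otu))
  expect_equal(length(inp$tree$tip.label), 16)
})
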
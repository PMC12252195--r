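test_that("zero-noise single-copy family reproduces the consensus exactly", {
  sp <- family_spec(n_species = 1, copy_number_probs = c("1" = 1, "2" = 0, ">2" = 0),
                    substitution_rate = 0, seed = 11)
  fam <- gen_family(sp)
  expect_length(fam$sequences, 1)
  expect_identical(fam$sequences, fam$clean_sequences)
})

test_that("generated sequences carry exactly tm_count TM segments and planted motifs", {
  fam <- gen_family(family_spec(n_species = 15, seed = 5))
  for (ann in fam$topology) expect_identical(ann$n_tm, 7L)
  # planted motifs occur at the recorded positions
  for (i in seq_len(nrow(fam$motifs))) {
    row <- fam$motifs[i, ]
    hits <- scan_motif(fam$sequences[[row$sequence_id]], row$pattern)
    expect_true(row$start %in% hits)
  }
  # topology tiles the sequences: per-sequence domain lengths sum to length
  tab <- domain_length_table(fam$topology)
  totals <- tapply(tab$length, tab$sequence_id, sum)
  expect_equal(as.vector(totals[names(fam$sequences)]),
               as.vector(nchar(fam$sequences)))
})

test_that("planted loop lengths recover the spec medians at large n", {
  fam <- gen_family(family_spec(n_species = 300, seed = 23))
  tab <- domain_length_table(fam$topology)
  expect_gte(sum(tab$domain == "ECL3"), 500)
  expect_equal(median(tab$length[tab$domain == "ECL3"]), 8)
  expect_equal(median(tab$length[tab$domain == "ECL2"]), 16)
  expect_true(all(tab$length[tab$domain == "ECL3"] >= 6 &
                    tab$length[tab$domain == "ECL3"] <= 12))
})

test_that("family FASTA output is byte-identical for a fixed seed", {
  sp <- family_spec(n_species = 8, seed = 99)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_family_fasta(gen_family(sp)$sequences, f1)
  write_family_fasta(gen_family(sp)$sequences, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_fasta(f1)
  expect_identical(back, gen_family(sp)$sequences)
})

test_that("invalid family specs are rejected", {
  expect_error(family_spec(copy_number_probs = c("1" = 0.6, "2" = 0.3, ">2" = 0.2)),
               class = "pmtr_config_error")
  expect_error(family_spec(tm_length_range = c(20, 20)),
               class = "pmtr_config_error")
  expect_error(family_spec(substitution_rate = 1.5),
               class = "pmtr_config_error")
})

test_that("cascade fixture realizes its category sizes and survives re-testing", {
  spec <- cascade_fixture_spec(10, 2, 1, 1, 1, seed = 17)
  fx <- gen_cascade_fixture(spec)
  expect_equal(table(fx$truth$category)[["retained"]], 5)
  # brute-force re-test of every record against the stage rules
  oracle <- oracle_cascade_labels(fx$hits, fx$predictions)
  expect_identical(oracle, fx$truth$category)

  fx0 <- gen_cascade_fixture(cascade_fixture_spec(5, 0, 0, 0, 0, seed = 2))
  expect_true(all(fx0$truth$category == "retained"))

  expect_error(cascade_fixture_spec(10, 8, 8, 0, 0),
               class = "pmtr_config_error")
  expect_error(cascade_fixture_spec(10, 0, 0, 0, 6),
               class = "pmtr_config_error")
})

test_that("cascade fixture generation is deterministic per seed", {
  s <- cascade_fixture_spec(40, 5, 2, 3, 4, seed = 31)
  expect_identical(gen_cascade_fixture(s), gen_cascade_fixture(s))
})

test_that("pose ensemble honors site distributions and determinism", {
  sites <- list(pose_site_spec(c(0, 0, 0), 2, -7.32, 0.4, FALSE, 1000),
                pose_site_spec(c(40, 0, 0), 2, -6.2, 0.5, TRUE, 500))
  pe <- gen_pose_ensemble(sites, seed = 13)
  expect_length(pe$poses, 1500)
  expect_equal(as.integer(table(pe$truth$site)), c(1000L, 500L))
  aff1 <- vapply(pe$poses[pe$truth$site == 1], `[[`, 0, "affinity")
  # CLT bound: sample mean within 3*sd/sqrt(n) of the generating mean
  expect_lt(abs(mean(aff1) - (-7.32)), 3 * 0.4 / sqrt(1000))
  aff2 <- vapply(pe$poses[pe$truth$site == 2], `[[`, 0, "affinity")
  expect_gt(mean((aff2 - mean(aff2))^3), 0)  # right skew
  expect_identical(gen_pose_ensemble(sites, seed = 13), pe)
  expect_error(pose_site_spec(c(0, 0, 0), n_runs = 0),
               class = "pmtr_config_error")
  expect_error(gen_pose_ensemble(list(pose_site_spec(c(0, 0, 0), 2),
                                      pose_site_spec(c(1, 0, 0), 2)),
                                 seed = 1),
               class = "pmtr_config_error")
})

test_that("pose files round-trip through the writer and parser", {
  sites <- list(pose_site_spec(c(0, 0, 0), 2, -7.3, 0.4, FALSE, 5),
                pose_site_spec(c(40, 0, 0), 2, -6.2, 0.5, TRUE, 5))
  pe <- gen_pose_ensemble(sites, seed = 3)
  f <- tempfile(fileext = ".pdbqt")
  write_pose_file(pe$poses, f)
  back <- parse_poses(f)
  expect_length(back, 10)
  expect_identical(vapply(back, `[[`, "", "run_id"),
                   vapply(pe$poses, `[[`, "", "run_id"))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$affinity, pe$poses[[i]]$affinity, tolerance = 1e-2)
    expect_equal(ligand_center(back[[i]]), ligand_center(pe$poses[[i]]),
                 tolerance = 1e-2)
    expect_identical(back[[i]]$atoms$element, pe$poses[[i]]$atoms$element)
  }
  # same seed twice -> byte-identical pose file
  f2 <- tempfile(fileext = ".pdbqt")
  write_pose_file(gen_pose_ensemble(sites, seed = 3)$poses, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("tunnel profiles hit their spec extremes exactly", {
  tn <- gen_tunnel(tunnel_spec(length = 8.2, bottleneck = 1.5,
                               energy_max = -0.5, seed = 7))
  expect_equal(min(tn$tunnel$radius), 1.5, tolerance = 1e-9)
  expect_equal(max(tn$transport$energy), -0.5, tolerance = 1e-12)
  expect_equal(tn$tunnel$arc_length[length(tn$tunnel$arc_length)], 8.2)

  flat <- gen_tunnel(tunnel_spec(bottleneck = 2, entry_radius = 2, seed = 1))
  expect_equal(bottleneck(flat$tunnel), 2)
  expect_true(all(flat$tunnel$radius == 2))

  # randomized specs: brute-force scan of the emitted samples matches spec
  set.seed(42)
  for (i in 1:10) {
    b <- runif(1, 1, 2); e <- b + runif(1, 0, 2)
    es <- runif(1, -4, -2); em <- runif(1, -1, -0.2)
    sp <- tunnel_spec(length = runif(1, 5, 15), bottleneck = b,
                      bottleneck_position = runif(1, 0.2, 0.8),
                      entry_radius = e, energy_at_site = es, energy_max = em,
                      n_samples = sample(10:40, 1), seed = i)
    tn <- gen_tunnel(sp)
    expect_equal(min(tn$tunnel$radius), sp$bottleneck, tolerance = 1e-9)
    expect_equal(max(tn$transport$energy), sp$energy_max, tolerance = 1e-9)
    expect_equal(tunnel_length(tn$tunnel), sp$length)
  }
  expect_error(tunnel_spec(bottleneck = 3, entry_radius = 2),
               class = "pmtr_config_error")
})
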
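test_that("threshold filter applies inclusive E-value and length bounds", {
  hits <- data.frame(target_id = c("a", "b", "c", "d"),
                     evalue = c(1e-100, 1e-19, 1e-150, 1e-101),
                     length = c(300, 300, 199, 401))
  p1 <- filter_by_threshold(hits, 1e-100, 200, 400)
  expect_identical(p1$target_id, "a")   # boundary E-value retained
  p2 <- filter_by_threshold(hits, 1e-20, 200, 400)
  expect_false("b" %in% p2$target_id)   # above cutoff excluded
  expect_false(any(c("c", "d") %in% p2$target_id))  # outside length window

  rnd <- random_hits(100, seed = 3)
  got <- filter_by_threshold(rnd, 1e-20, 200, 400)
  want <- rnd[sapply(seq_len(nrow(rnd)), function(i)
    rnd$evalue[i] <= 1e-20 && rnd$length[i] >= 200 && rnd$length[i] <= 400), ]
  expect_identical(got$target_id, want$target_id)

  bad <- data.frame(target_id = "z", evalue = -1, length = 300)
  expect_error(filter_by_threshold(bad, 1e-20, 200, 400),
               class = "pmtr_data_error")
})

test_that("best_hit_per_species returns each species' minimum E-value hit", {
  hits <- data.frame(target_id = c("a1", "a2", "b1", "b2"),
                     species = c("A", "A", "B", "B"),
                     evalue = c(1e-50, 1e-60, 1e-80, 1e-70),
                     length = 300)
  got <- best_hit_per_species(hits)
  expect_setequal(got$target_id, c("a2", "b1"))

  one <- hits[1, , drop = FALSE]
  expect_identical(best_hit_per_species(one)$target_id, "a1")

  rnd <- random_hits(50, n_species = 7, seed = 9)
  got <- best_hit_per_species(rnd)
  for (sp in unique(rnd$species)) {
    grp <- rnd[rnd$species == sp, ]
    expect_identical(got$target_id[got$species == sp],
                     grp$target_id[order(grp$evalue, grp$target_id)][1])
  }
})

test_that("remove_partial keeps only methionine-initiated sequences", {
  hits <- data.frame(target_id = c("m", "p"), evalue = 1e-30, length = 4,
                     sequence = c("MSTV", "STVK"))
  expect_identical(remove_partial(hits)$target_id, "m")
  empty <- data.frame(target_id = "e", evalue = 1e-30, length = 0,
                      sequence = "")
  expect_error(remove_partial(empty), class = "pmtr_data_error")
})

test_that("topology consensus requires the agreement quorum of exactly-7TM calls", {
  mk_pred <- function(id, tms) {
    do.call(rbind, lapply(seq_along(tms), function(p)
      pmtrkit:::fabricate_topology(id, paste0("pred", p), 300, tms[p])))
  }
  hits <- data.frame(target_id = "x", evalue = 1e-30, length = 300)
  expect_identical(
    topology_consensus_filter(hits, mk_pred("x", c(7, 7, 6)))$target_id, "x")
  expect_equal(
    nrow(topology_consensus_filter(hits, mk_pred("x", c(6, 6, 7)))), 0)
  expect_error(topology_consensus_filter(hits, mk_pred("x", 7)),
               class = "pmtr_data_error")
  expect_error(topology_consensus_filter(hits, mk_pred("other", c(7, 7))),
               class = "pmtr_data_error")
})

test_that("deduplicate keeps the lowest-E-value representative per sequence", {
  hits <- data.frame(target_id = c("w1", "w2", "u"),
                     evalue = c(1e-120, 1e-150, 1e-40),
                     length = 4, sequence = c("MAAA", "MAAA", "MCCC"))
  got <- deduplicate(hits)
  expect_setequal(got$target_id, c("w2", "u"))

  distinct <- data.frame(target_id = c("a", "b"), evalue = 1e-30, length = 4,
                         sequence = c("MAAA", "MCCC"))
  expect_identical(deduplicate(distinct), distinct)

  set.seed(4)
  n <- 40
  groups <- sample(10, n, replace = TRUE)
  rnd <- data.frame(target_id = sprintf("r%02d", 1:n),
                    evalue = 10^runif(n, -100, -30), length = 8,
                    sequence = sprintf("MSEQ%04d", groups))
  got <- deduplicate(rnd)
  want <- unlist(lapply(split(seq_len(n), rnd$sequence), function(ix) {
    rnd$target_id[ix][order(rnd$evalue[ix], rnd$target_id[ix])][1]
  }))
  expect_setequal(got$target_id, want)
})

test_that("run_cascade reproduces planted category sizes and conserves ids", {
  fx <- gen_cascade_fixture(cascade_fixture_spec(253, 47, 1, 13, 18, seed = 8))
  res <- run_cascade(fx$hits, fx$predictions)
  cts <- res$report$counts
  expect_equal(cts$after_threshold, 206)
  expect_equal(cts$final, 253 - 47 - 1 - 13 - 18)
  expect_equal(cts$excluded_partial, 1)
  expect_equal(cts$excluded_tm, 13)
  expect_equal(cts$excluded_redundant, 18)
  # conservation: every input id in exactly one bucket
  all_ids <- unlist(res$report$ids, use.names = FALSE)
  expect_setequal(all_ids, fx$hits$target_id)
  expect_equal(length(all_ids), length(unique(all_ids)))
  expect_equal(cts$final,
               cts$initial - cts$excluded_threshold - cts$excluded_partial -
                 cts$excluded_tm - cts$excluded_redundant)
  # report buckets agree with the generator's ground truth
  truth_split <- split(fx$truth$target_id, fx$truth$category)
  expect_setequal(res$report$ids$retained, truth_split$retained)
  expect_setequal(res$report$ids$excluded_tm, truth_split$excluded_tm)
})

test_that("cascade is idempotent and permutation-invariant on the retained set", {
  fx <- gen_cascade_fixture(cascade_fixture_spec(60, 8, 3, 5, 6, seed = 21))
  res <- run_cascade(fx$hits, fx$predictions)
  again <- run_cascade(res$hits, fx$predictions)
  expect_setequal(again$hits$target_id, res$hits$target_id)
  expect_equal(again$report$counts$final, res$report$counts$final)

  set.seed(1)
  perm <- sample(nrow(fx$hits))
  res_p <- run_cascade(fx$hits[perm, ], fx$predictions)
  expect_setequal(res_p$hits$target_id, res$hits$target_id)
})

test_that("relaxing thresholds never shrinks the retained set", {
  fx <- gen_cascade_fixture(cascade_fixture_spec(60, 10, 2, 4, 5, seed = 33))
  strict <- run_cascade(fx$hits, fx$predictions, cascade_config())
  relaxed <- run_cascade(fx$hits, fx$predictions,
                         cascade_config(phase2_max_evalue = 1e-5,
                                        min_length = 100, max_length = 500))
  expect_true(all(strict$hits$target_id %in% relaxed$hits$target_id))
})

test_that("empty input yields an all-zero report with undefined retention", {
  empty <- data.frame(target_id = character(), evalue = numeric(),
                      length = integer())
  res <- run_cascade(empty, data.frame())
  expect_equal(res$report$counts$final, 0)
  expect_true(is.na(res$report$retention_fraction))
})

test_that("hit TSV and tblout readers parse their dialects", {
  fx <- gen_cascade_fixture(cascade_fixture_spec(12, 2, 1, 1, 1, seed = 5))
  f <- tempfile(fileext = ".tsv")
  write_hit_tsv(fx$hits, f)
  back <- read_hit_tsv(f)
  expect_identical(back$target_id, fx$hits$target_id)
  expect_equal(back$evalue, fx$hits$evalue)

  tb <- tempfile(fileext = ".tbl")
  writeLines(c("# comment line",
               "seqA -  query - 1.2e-120 300.0 0.1 ignored",
               "seqB -  query - 3.4e-21  200.0 0.2 ignored"), tb)
  parsed <- read_tblout(tb)
  expect_identical(parsed$target_id, c("seqA", "seqB"))
  expect_equal(parsed$evalue, c(1.2e-120, 3.4e-21))
})
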
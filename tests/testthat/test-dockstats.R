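test_that("parse_poses reads multi-model files and flags broken models", {
  f <- tempfile()
  writeLines(c(
    "MODEL 1",
    "REMARK VINA RESULT:   -7.100    0.000    0.000",
    "HETATM    1 C    LIG A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL 2",
    "REMARK VINA RESULT:   -6.300    0.000    0.000",
    "HETATM    1 N    LIG A   1       4.000   5.000   6.000  1.00  0.00           N",
    "ENDMDL"), f)
  poses <- parse_poses(f)
  expect_length(poses, 2)
  expect_equal(vapply(poses, `[[`, 0, "affinity"), c(-7.1, -6.3))
  expect_equal(poses[[2]]$atoms$x, 4)
  expect_identical(poses[[2]]$atoms$element, "N")

  empty <- tempfile(); writeLines(character(), empty)
  expect_length(parse_poses(empty), 0)

  broken <- tempfile()
  writeLines(c("MODEL 1",
               "HETATM    1 C    LIG A   1       1.000   2.000   3.000  1.00  0.00           C",
               "ENDMDL"), broken)
  expect_error(parse_poses(broken), class = "pmtr_parse_error")
})

test_that("best_pose_per_run keeps each run's minimum-affinity pose", {
  mk <- function(run, rank, aff)
    list(run_id = run, model_rank = rank, affinity = aff,
         atoms = data.frame(element = "C", x = 0, y = 0, z = 0))
  ens <- best_pose_per_run(list(mk("r1", 1, -6.5), mk("r1", 2, -7.0),
                                mk("r2", 1, -5.0)))
  expect_equal(ens$n_runs, 2)
  expect_equal(ens$poses[[1]]$affinity, -7.0)

  # ties resolved by lowest model rank
  tie <- best_pose_per_run(list(mk("r", 2, -7), mk("r", 1, -7)))
  expect_equal(tie$poses[[1]]$model_rank, 1)

  # group-min oracle on random runs
  set.seed(3)
  poses <- lapply(1:60, function(i)
    mk(paste0("run", sample(10, 1)), i, round(runif(1, -9, -4), 3)))
  ens <- best_pose_per_run(poses)
  runs <- vapply(poses, `[[`, "", "run_id")
  affs <- vapply(poses, `[[`, 0, "affinity")
  for (p in ens$poses)
    expect_equal(p$affinity, min(affs[runs == p$run_id]))
})

test_that("ligand_center averages atom coordinates", {
  one <- list(atoms = data.frame(element = "C", x = 1, y = 2, z = 3))
  expect_equal(ligand_center(one), c(1, 2, 3))
  two <- list(atoms = data.frame(element = c("C", "C"),
                                 x = c(0, 2), y = 0, z = 0))
  expect_equal(ligand_center(two), c(1, 0, 0))
  set.seed(1)
  a <- data.frame(element = "C", x = rnorm(17), y = rnorm(17), z = rnorm(17))
  expect_equal(ligand_center(list(atoms = a)),
               c(sum(a$x) / 17, sum(a$y) / 17, sum(a$z) / 17),
               tolerance = 1e-12)
  expect_error(ligand_center(list(atoms = a[0, ])), class = "pmtr_data_error")
})

test_that("DBSCAN separates distant blobs and floors sparse sets to noise", {
  set.seed(9)
  blob <- function(center, n) sweep(matrix(rnorm(3 * n, 0, 2), ncol = 3), 2,
                                    center, `+`)
  centers <- rbind(blob(c(0, 0, 0), 500), blob(c(40, 0, 0), 500))
  labels <- cluster_sites(centers, eps = 7, min_pts = 20)
  expect_equal(sort(unique(labels)), c(1, 2))
  expect_equal(sum(labels == 0), 0)
  expect_true(all(labels[1:500] == labels[1]))
  expect_true(all(labels[501:1000] == labels[501]))

  few <- matrix(0, nrow = 10, ncol = 3)
  expect_true(all(cluster_sites(few, eps = 7, min_pts = 20) == 0))
})

test_that("cluster_sites equals the brute-force DBSCAN oracle", {
  set.seed(17)
  for (rep in 1:12) {
    n <- sample(30:200, 1)
    k <- sample(1:3, 1)
    pts <- do.call(rbind, lapply(seq_len(k), function(j)
      sweep(matrix(rnorm(3 * ceiling(n / k), 0, runif(1, 1, 6)), ncol = 3),
            2, runif(3, -30, 30), `+`)))[seq_len(n), , drop = FALSE]
    eps <- runif(1, 2, 10)
    mp <- sample(3:25, 1)
    expect_identical(cluster_sites(pts, eps, mp), oracle_dbscan(pts, eps, mp))
  }
})

test_that("silhouette search recovers separable structure and reports failures", {
  set.seed(2)
  two <- rbind(matrix(rnorm(150, 0, 1), ncol = 3),
               sweep(matrix(rnorm(150, 0, 1), ncol = 3), 2, c(40, 0, 0), `+`))
  best <- optimize_clustering(two, eps_grid = c(3, 7), minpts_grid = c(5, 20))
  expect_false(is.null(best))
  expect_equal(length(unique(best$labels[best$labels != 0])), 2)
  expect_gt(best$silhouette, 0.9)   # perfectly separated equal blobs

  single <- matrix(rnorm(150, 0, 2), ncol = 3)
  expect_null(optimize_clustering(single, eps_grid = 7, minpts_grid = 10))
})

test_that("site statistics use the exact t interval and order sites by affinity", {
  flat <- affinity_ensemble(rep(-7, 10))
  st <- site_affinity_stats(flat, rep(1L, 10))
  expect_equal(st$mean_affinity, -7)
  expect_equal(st$ci_lo, -7)
  expect_equal(st$ci_hi, -7)

  set.seed(12)
  x <- rnorm(25, -7.3, 0.4)
  st <- site_affinity_stats(affinity_ensemble(x), rep(1L, 25))
  expect_equal(c(st$ci_lo, st$ci_hi), oracle_t_interval(x), tolerance = 1e-9)

  big <- rnorm(1000, -7.32, 0.4)
  st <- site_affinity_stats(affinity_ensemble(big), rep(1L, 1000))
  expect_lt(abs((st$ci_hi - st$ci_lo) / 2 - 1.96 * 0.4 / sqrt(1000)), 0.01)
  expect_true(st$ci_lo < -7.32 && -7.32 < st$ci_hi)

  # two clusters: site 1 must be the lower (stronger) mean
  lab <- rep(c(1L, 2L), each = 20)
  aff <- c(rnorm(20, -6.2, 0.1), rnorm(20, -7.3, 0.1))
  st2 <- site_affinity_stats(affinity_ensemble(aff), lab)
  expect_equal(st2$site, c(1, 2))
  expect_lt(st2$mean_affinity[1], st2$mean_affinity[2])
  expect_equal(st2$cluster_label[1], 2)

  # singleton cluster: undefined CI
  st3 <- site_affinity_stats(affinity_ensemble(c(-7, -7, -6)),
                             c(1L, 1L, 2L))
  expect_true(is.na(st3$ci_lo[st3$n == 1]))
})

test_that("nominal 95% intervals cover the true mean at the nominal rate", {
  set.seed(555)
  n_rep <- 2000
  covered <- 0
  for (r in seq_len(n_rep)) {
    x <- rnorm(20, -7.32, 0.4)
    m <- mean(x); half <- qt(0.975, 19) * sd(x) / sqrt(20)
    if (m - half <= -7.32 && -7.32 <= m + half) covered <- covered + 1
  }
  # sanity of the closed form used by site_affinity_stats, at 2000 ensembles
  expect_gt(covered / n_rep, 0.93)
  expect_lt(covered / n_rep, 0.97)
})

test_that("ligand efficiency and affinity classes follow their definitions", {
  expect_equal(ligand_efficiency(-7.32, melatonin()), 7.32 / 17)
  expect_equal(round(ligand_efficiency(-7.32, 17), 4), 0.4306)
  expect_equal(ligand_efficiency(0, 17), 0)
  expect_equal(round(ligand_efficiency(-6.20, 17), 4), 0.3647)
  expect_error(ligand_info("x", 0), class = "pmtr_data_error")

  expect_identical(classify_affinity(c(-7.32, -7, -6.5, -6, -5.9)),
                   c("strong", "strong", "intermediate", "intermediate",
                     "weak"))
  # linearity of LE and partition of the real line
  dg <- seq(-10, 0, by = 0.25)
  expect_equal(ligand_efficiency(2 * dg, 17), 2 * ligand_efficiency(dg, 17))
  expect_true(all(classify_affinity(dg) %in%
                    c("strong", "intermediate", "weak")))
})

test_that("compare_sites separates far-apart sites and is calibrated under the null", {
  set.seed(77)
  a <- rnorm(1000, -7.32, 0.05)
  b <- rnorm(1000, -6.20, 0.05)
  hits <- sum(vapply(1:100, function(s)
    compare_sites(a, b, n_sample = 5, seed = s)$p_value < 0.05, logical(1)))
  expect_gte(hits, 99)   # 22-sigma separation: essentially always detected

  same <- compare_sites(rep(-7, 10), rep(-7, 10), n_sample = 5, seed = 1)
  expect_equal(same$p_value, 1)
  expect_identical(same$letters, c("a", "a"))

  expect_error(compare_sites(1:3, 1:10, n_sample = 5),
               class = "pmtr_data_error")

  # type-I error under identical distributions
  null_a <- rnorm(2000, -7, 0.3)
  rej <- sum(vapply(1:1000, function(s) {
    compare_sites(null_a[1:1000], null_a[1001:2000], n_sample = 5,
                  seed = s)$p_value < 0.05
  }, logical(1)))
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lte(rej / 1000, 0.05 + 2 * se)
})

test_that("end-to-end docking analysis recovers planted two-site structure", {
  sites <- list(pose_site_spec(c(0, 0, 0), 2, -7.32, 0.4, FALSE, 500),
                pose_site_spec(c(40, 0, 0), 2, -6.20, 0.5, TRUE, 500))
  pe <- gen_pose_ensemble(sites, seed = 41)
  res <- analyze_docking_sites(pe$poses, eps = 7, min_pts = 20)
  expect_equal(nrow(res$sites), 2)
  expect_lt(res$sites$mean_affinity[1], res$sites$mean_affinity[2])
  expect_true(res$sites$ci_lo[1] < -7.32 && -7.32 < res$sites$ci_hi[1])
  expect_identical(res$sites$affinity_class, c("strong", "intermediate"))
  # cluster membership matches the generator's ground truth
  run_site <- pe$truth$site[match(vapply(res$ensemble$poses, `[[`, "", "run_id"),
                                  pe$truth$run_id)]
  expect_equal(length(unique(res$labels[run_site == 1])), 1)
  expect_equal(length(unique(res$labels[run_site == 2])), 1)
})
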
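# Probabilistic docking-ensemble analysis: pose ingestion from multi-model
# Vina-style files, best-pose-per-run extraction, ligand-center DBSCAN site
# clustering with silhouette-based parameter search, per-site affinity
# statistics with confidence intervals, ligand efficiency, affinity classes
# and a seeded small-sample site comparison.

#' Ligand descriptor
#'
#' @param name Ligand name.
#' @param heavy_atom_count Number of non-hydrogen atoms.
#' @return List of class `ligand_info`.
#' @export
ligand_info <- function(name, heavy_atom_count) {
  if (heavy_atom_count < 1) data_error("heavy_atom_count must be >= 1")
  structure(list(name = name, heavy_atom_count = as.integer(heavy_atom_count)),
            class = "ligand_info")
}

#' Melatonin descriptor
#'
#' Melatonin (C13H16N2O2) has 17 heavy atoms: 13 C + 2 N + 2 O.
#'
#' @return A `ligand_info` for melatonin.
#' @export
melatonin <- function() ligand_info("melatonin", 17L)

#' Parse a multi-model pose file
#'
#' Reads MODEL/ENDMDL blocks in the AutoDock-Vina PDBQT dialect.  The binding
#' affinity of each model is taken from its `REMARK VINA RESULT:` line
#' (kcal/mol); atom coordinates are read from the fixed PDB columns of
#' ATOM/HETATM records.  An optional `REMARK RUN:` line carries the docking
#' run id; without one, each model is its own run and the model number within
#' a run increments `model_rank`.
#'
#' @param path Path to the pose file.
#' @return List of poses, each a list with `run_id`, `model_rank`, `affinity`
#'   and `atoms` (data.frame `element`, `x`, `y`, `z`).
#' @export
parse_poses <- function(path) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (!length(model_starts)) return(list())
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    parse_error("unbalanced MODEL/ENDMDL blocks")
  poses <- vector("list", length(model_starts))
  rank_counter <- new.env(parent = emptyenv())
  for (i in seq_along(model_starts)) {
    block <- lines[model_starts[i]:model_ends[i]]
    aff_line <- grep("^REMARK VINA RESULT:", block, value = TRUE)
    if (!length(aff_line))
      parse_error(paste0("model ", i, " lacks a 'REMARK VINA RESULT:' line"))
    aff <- as.numeric(strsplit(trimws(sub("^REMARK VINA RESULT:", "",
                                          aff_line[1])), "\\s+")[[1]][1])
    if (!is.finite(aff))
      parse_error(paste0("model ", i, ": non-numeric affinity"))
    run_line <- grep("^REMARK RUN:", block, value = TRUE)
    run_id <- if (length(run_line))
      trimws(sub("^REMARK RUN:", "", run_line[1])) else paste0("run", i)
    atom_lines <- grep("^(ATOM|HETATM)", block, value = TRUE)
    if (!length(atom_lines))
      parse_error(paste0("model ", i, " has no atom records"))
    x <- as.numeric(substr(atom_lines, 31, 38))
    y <- as.numeric(substr(atom_lines, 39, 46))
    z <- as.numeric(substr(atom_lines, 47, 54))
    el <- trimws(substr(atom_lines, 77, 78))
    rank <- (get0(run_id, envir = rank_counter, ifnotfound = 0L)) + 1L
    assign(run_id, rank, envir = rank_counter)
    poses[[i]] <- list(run_id = run_id, model_rank = rank, affinity = aff,
                       atoms = data.frame(element = el, x = x, y = y, z = z))
  }
  poses
}

#' Best pose per docking run
#'
#' Keeps, for each run, the pose with the lowest (most favorable) binding
#' affinity; ties are broken by the lowest model rank.
#'
#' @param poses List of poses as returned by [parse_poses()].
#' @return A `pose_ensemble`: list with `poses` (one per run, in order of
#'   first appearance of the run) and `n_runs`.
#' @export
best_pose_per_run <- function(poses) {
  if (!length(poses))
    return(structure(list(poses = list(), n_runs = 0L),
                     class = "pose_ensemble"))
  run_ids <- vapply(poses, `[[`, "", "run_id")
  best <- list()
  for (rid in unique(run_ids)) {
    grp <- poses[run_ids == rid]
    aff <- vapply(grp, `[[`, 0, "affinity")
    rank <- vapply(grp, function(p) as.numeric(p$model_rank), 0)
    ord <- order(aff, rank)
    best[[length(best) + 1]] <- grp[[ord[1]]]
  }
  structure(list(poses = best, n_runs = length(best)), class = "pose_ensemble")
}

#' Ligand center of a pose
#'
#' The unweighted arithmetic mean of the atom coordinates (the paper-style
#' "center of mass", which averages ligand coordinates without mass
#' weighting).  A mass-weighted variant is available via `weights`.
#'
#' @param pose A pose (list with `atoms`).
#' @param weights Optional per-atom weights (e.g. atomic masses).
#' @return Numeric length-3 vector (x, y, z) in Angstrom.
#' @export
ligand_center <- function(pose, weights = NULL) {
  a <- pose$atoms
  if (is.null(a) || nrow(a) == 0) data_error("pose with zero atoms")
  if (is.null(weights)) {
    c(mean(a$x), mean(a$y), mean(a$z))
  } else {
    w <- weights / sum(weights)
    c(sum(w * a$x), sum(w * a$y), sum(w * a$z))
  }
}

#' Ligand centers of an ensemble
#'
#' @param ensemble A `pose_ensemble`.
#' @return n-by-3 matrix of pose centers.
#' @export
ensemble_centers <- function(ensemble) {
  m <- t(vapply(ensemble$poses, ligand_center, numeric(3)))
  colnames(m) <- c("x", "y", "z")
  m
}

#' DBSCAN clustering of pose centers
#'
#' Density-based clustering: a point is a core point iff it has at least
#' `min_pts` neighbors within `eps` (counting itself); clusters are the
#' connected components of core points (linked when within `eps`), plus
#' border points.  Non-core points with no core neighbor are noise (label 0).
#' The procedure is deterministic for a given input order: components are
#' numbered by their smallest member index and every border point joins the
#' cluster of its lowest-index core neighbor.
#'
#' @param centers n-by-3 (or n-by-d) numeric matrix.
#' @param eps Neighborhood radius in Angstrom.
#' @param min_pts Minimum neighborhood size for a core point.
#' @return Integer label vector (0 = noise).
#' @export
cluster_sites <- function(centers, eps = 7, min_pts = 20) {
  if (eps <= 0) config_error("eps must be positive")
  if (min_pts < 1) config_error("min_pts must be >= 1")
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (n == 0) return(integer())
  d <- as.matrix(stats::dist(centers))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    # expand the component of core points reachable from i
    frontier <- i
    labels[i] <- cl
    while (length(frontier)) {
      nxt <- integer()
      for (p in frontier) {
        reach <- which(nb[p, ] & core & labels == 0L)
        labels[reach] <- cl
        nxt <- c(nxt, reach)
      }
      frontier <- nxt
    }
  }
  # border points: lowest-index core neighbor decides the cluster
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    cn <- which(nb[i, ] & core)
    if (length(cn)) labels[i] <- labels[cn[1]]
  }
  labels
}

#' Silhouette-guided DBSCAN parameter search
#'
#' Evaluates every (eps, min_pts) grid point, skips those yielding fewer than
#' two clusters, and returns the pair maximizing the mean silhouette width
#' over non-noise points.  Ties favor the smallest eps, then the smallest
#' min_pts.
#'
#' @param centers Point matrix as in [cluster_sites()].
#' @param eps_grid Numeric vector of eps values.
#' @param minpts_grid Integer vector of min_pts values.
#' @return List with `eps`, `min_pts`, `silhouette`, `labels`; or `NULL` when
#'   no grid point produces at least two clusters.
#' @export
optimize_clustering <- function(centers, eps_grid = c(3, 5, 7, 9),
                                minpts_grid = c(5, 10, 20)) {
  if (!length(eps_grid) || !length(minpts_grid))
    config_error("parameter grids must be non-empty")
  centers <- as.matrix(centers)
  best <- NULL
  for (eps in sort(eps_grid)) {
    for (mp in sort(minpts_grid)) {
      labels <- cluster_sites(centers, eps, mp)
      keep <- labels != 0L
      if (length(unique(labels[keep])) < 2) next
      sil <- cluster::silhouette(labels[keep],
                                 stats::dist(centers[keep, , drop = FALSE]))
      ms <- mean(sil[, "sil_width"])
      if (is.null(best) || ms > best$silhouette) {
        best <- list(eps = eps, min_pts = mp, silhouette = ms, labels = labels)
      }
    }
  }
  best
}

#' Per-site affinity statistics
#'
#' For every cluster (noise excluded): member count, centroid, mean binding
#' affinity and a two-sided Student-t confidence interval of the mean.
#' Clusters are renamed site 1, site 2, ... by ascending mean affinity, so
#' site 1 is always the strongest-binding site.  Clusters with fewer than two
#' members get an undefined (NA) interval.
#'
#' @param ensemble A `pose_ensemble`.
#' @param labels Cluster labels aligned with `ensemble$poses`.
#' @param confidence Confidence level (default 0.95).
#' @return data.frame with `site`, `cluster_label`, `n`, `centroid_x/y/z`,
#'   `mean_affinity`, `ci_lo`, `ci_hi`.
#' @export
site_affinity_stats <- function(ensemble, labels, confidence = 0.95) {
  if (length(labels) != ensemble$n_runs)
    data_error("labels do not align with the ensemble poses")
  aff <- vapply(ensemble$poses, `[[`, 0, "affinity")
  centers <- ensemble_centers(ensemble)
  rows <- lapply(sort(unique(labels[labels != 0L])), function(cl) {
    sel <- labels == cl
    a <- aff[sel]
    m <- mean(a)
    if (sum(sel) >= 2) {
      half <- qt((1 + confidence) / 2, df = sum(sel) - 1) * sd(a) / sqrt(sum(sel))
      lo <- m - half; hi <- m + half
    } else {
      lo <- NA_real_; hi <- NA_real_
    }
    data.frame(cluster_label = cl, n = sum(sel),
               centroid_x = mean(centers[sel, 1]),
               centroid_y = mean(centers[sel, 2]),
               centroid_z = mean(centers[sel, 3]),
               mean_affinity = m, ci_lo = lo, ci_hi = hi)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(site = integer(), cluster_label = integer(),
                      n = integer(), centroid_x = numeric(),
                      centroid_y = numeric(), centroid_z = numeric(),
                      mean_affinity = numeric(), ci_lo = numeric(),
                      ci_hi = numeric()))
  out <- out[order(out$mean_affinity), , drop = FALSE]
  out <- cbind(site = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Ligand efficiency
#'
#' `LE = -dG / HA`: the negated free energy of binding per heavy atom of the
#' ligand.
#'
#' @param dg Free energy of binding in kcal/mol (vectorized).
#' @param ligand A `ligand_info` or a heavy-atom count.
#' @return Ligand efficiency in kcal/mol per heavy atom.
#' @export
ligand_efficiency <- function(dg, ligand = melatonin()) {
  ha <- if (inherits(ligand, "ligand_info")) ligand$heavy_atom_count
        else as.integer(ligand)
  if (is.na(ha) || ha < 1) data_error("heavy-atom count must be >= 1")
  -dg / ha
}

#' Affinity class of a binding score
#'
#' Classes follow the conventional color thresholds: strong for dG <= -7
#' kcal/mol, intermediate for -7 < dG <= -6, weak otherwise.
#'
#' @param dg Binding free energy in kcal/mol (vectorized).
#' @return Character vector in `{"strong","intermediate","weak"}`.
#' @export
classify_affinity <- function(dg) {
  if (any(!is.finite(dg))) data_error("non-finite binding affinity")
  ifelse(dg <= -7, "strong", ifelse(dg <= -6, "intermediate", "weak"))
}

#' Small-sample comparison of two binding sites
#'
#' Draws `n_sample` affinities per site without replacement (seeded), runs a
#' two-sided two-sample t-test (Welch by default) and assigns compact-letter
#' labels: the sites share a letter iff the difference is not significant at
#' `alpha`.  When both drawn samples are constant, the statistic degenerates;
#' equal constants give p = 1, different constants p = 0.
#'
#' @param affinities_site1,affinities_site2 Numeric vectors of per-run
#'   affinities.
#' @param n_sample Sample size drawn from each site.
#' @param alpha Significance level.
#' @param seed Integer seed for the sampling.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return List with `t`, `p_value`, `letters` (length 2), and the drawn
#'   `sample1`, `sample2`.
#' @export
compare_sites <- function(affinities_site1, affinities_site2, n_sample = 5,
                          alpha = 0.05, seed = 1L, var_equal = FALSE) {
  if (length(affinities_site1) < n_sample || length(affinities_site2) < n_sample)
    data_error("insufficient values to draw the requested sample")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  s1 <- sample(affinities_site1, n_sample)
  s2 <- sample(affinities_site2, n_sample)
  if (sd(s1) == 0 && sd(s2) == 0) {
    p <- if (isTRUE(all.equal(mean(s1), mean(s2)))) 1 else 0
    tval <- if (p == 1) 0 else Inf
  } else {
    tt <- t.test(s1, s2, alternative = "two.sided", var.equal = var_equal)
    p <- tt$p.value
    tval <- unname(tt$statistic)
  }
  letters <- if (p < alpha) c("a", "b") else c("a", "a")
  list(t = tval, p_value = p, letters = letters, sample1 = s1, sample2 = s2)
}

#' End-to-end docking-site analysis
#'
#' Convenience wrapper: best pose per run, ligand centers, DBSCAN site
#' clustering and per-site affinity statistics with ligand efficiency and
#' affinity class.
#'
#' @param poses List of poses (see [parse_poses()]).
#' @param eps,min_pts DBSCAN parameters.
#' @param ligand A `ligand_info` for the ligand-efficiency column.
#' @param confidence Confidence level of the per-site intervals.
#' @return List with `ensemble`, `labels`, and `sites` (the stats table plus
#'   `ligand_efficiency` and `affinity_class` columns).
#' @export
analyze_docking_sites <- function(poses, eps = 7, min_pts = 20,
                                  ligand = melatonin(), confidence = 0.95) {
  ensemble <- best_pose_per_run(poses)
  centers <- ensemble_centers(ensemble)
  labels <- cluster_sites(centers, eps = eps, min_pts = min_pts)
  sites <- site_affinity_stats(ensemble, labels, confidence = confidence)
  if (nrow(sites)) {
    sites$ligand_efficiency <- ligand_efficiency(sites$mean_affinity, ligand)
    sites$affinity_class <- classify_affinity(sites$mean_affinity)
  }
  list(ensemble = ensemble, labels = labels, sites = sites)
}
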
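# Independent reference implementations used to cross-check the package.
# Each oracle deliberately takes a different computational route from the
# implementation it verifies.

# DBSCAN by iterated label propagation over the core-core adjacency matrix
# (fixpoint iteration rather than BFS expansion).
oracle_dbscan <- function(centers, eps, min_pts) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (n == 0) return(integer())
  d <- as.matrix(dist(centers))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  lab <- ifelse(core, seq_len(n), 0L)
  repeat {
    old <- lab
    for (i in which(core)) {
      friends <- which(nb[i, ] & core)
      lab[friends] <- min(lab[friends])
    }
    if (identical(old, lab)) break
  }
  # renumber components by smallest member index
  comp_ids <- sort(unique(lab[lab > 0]))
  out <- integer(n)
  for (k in seq_along(comp_ids)) out[lab == comp_ids[k]] <- k
  for (i in which(!core)) {
    cn <- which(nb[i, ] & core)
    out[i] <- if (length(cn)) out[cn[1]] else 0L
  }
  out
}

# Exhaustive overlapping motif matcher via a PCRE lookahead built
# independently from the pattern text.
oracle_motif_scan <- function(sequence, pattern_text,
                              h = "[AVLIMFWC]") {
  rx <- gsub("x", ".", pattern_text, fixed = TRUE)
  rx <- gsub("h", h, rx, fixed = TRUE)
  m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer() else as.integer(m)
}

# Textbook two-sided t confidence interval.
oracle_t_interval <- function(x, conf = 0.95) {
  as.numeric(t.test(x, conf.level = conf)$conf.int)
}

# Re-derive the cascade category of each fixture record by independently
# applying the stage rules in order.
oracle_cascade_labels <- function(hits, predictions, cfg = cascade_config()) {
  tm7 <- with(predictions, tapply(grepl("^TM", label),
                                  interaction(sequence_id, predictor, drop = TRUE),
                                  sum))
  sevens <- sapply(hits$target_id, function(id) {
    sum(tm7[grep(paste0("^", id, "\\."), names(tm7))] == cfg$required_tm)
  })
  out <- character(nrow(hits))
  passed_prev <- rep(FALSE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (hits$evalue[i] > cfg$phase2_max_evalue ||
        hits$length[i] < cfg$min_length || hits$length[i] > cfg$max_length) {
      out[i] <- "excluded_threshold"
    } else if (substr(hits$sequence[i], 1, 1) != "M") {
      out[i] <- "excluded_partial"
    } else if (sevens[i] < cfg$min_predictor_agreement) {
      out[i] <- "excluded_tm"
    } else {
      passed_prev[i] <- TRUE
      out[i] <- "survivor"  # redundancy resolved below
    }
  }
  surv <- which(passed_prev)
  for (i in surv) {
    same <- surv[hits$sequence[surv] == hits$sequence[i]]
    best <- same[order(hits$evalue[same], hits$target_id[same])][1]
    out[i] <- if (i == best) "retained" else "excluded_redundant"
  }
  out
}

# small random hit table
random_hits <- function(n, n_species = 7, seed = 1) {
  set.seed(seed)
  data.frame(
    target_id = sprintf("h%03d", seq_len(n)),
    species = sprintf("sp%02d", sample.int(n_species, n, replace = TRUE)),
    evalue = 10^runif(n, -160, -5),
    length = sample(150:450, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# pose list with one single-atom pose per affinity value (for CI checks)
affinity_ensemble <- function(affinities) {
  poses <- lapply(seq_along(affinities), function(i) {
    list(run_id = paste0("r", i), model_rank = 1L, affinity = affinities[i],
         atoms = data.frame(element = "C", x = 0, y = 0, z = 0))
  })
  best_pose_per_run(poses)
}
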
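# Seeded synthetic-data generators.  Every input the pipeline consumes can be
# produced here with known ground truth: 7TM protein families with planted
# conserved motifs and clade-structured copy numbers, screening-cascade hit
# tables with controlled exclusion categories, two-site docking pose
# ensembles, and tunnel radius/energy profiles.  Defaults are calibrated to
# the statistics of the PMTR family: ~47.1% of species with two receptor
# copies, 34.5% with one and 18.4% with more than two; ECL3 lengths with
# median 8 (range 6-12) and ECL2 the longest loop with median 16.
#
# All randomness flows from the single integer seed of each spec through one
# RNG stream per generated artifact; the caller's RNG state is left intact.

default_loop_params <- function() {
  list(NTD  = list(median = 35, range = c(12, 60)),
       ICL1 = list(median = 6,  range = c(4, 10)),
       ECL1 = list(median = 7,  range = c(5, 11)),
       ICL2 = list(median = 8,  range = c(5, 12)),
       ECL2 = list(median = 16, range = c(10, 26)),
       ICL3 = list(median = 12, range = c(8, 18)),
       ECL3 = list(median = 8,  range = c(6, 12)),
       CTD  = list(median = 45, range = c(26, 68)))
}

#' Synthetic 7TM family specification
#'
#' @param n_species Number of species in the family.
#' @param copy_number_probs Named numeric vector over `"1"`, `"2"`, `">2"`;
#'   must sum to 1.  The `">2"` category is realized uniformly over 3-6
#'   copies (6 is the maximum copy number observed in the family).
#' @param tm_count Number of transmembrane helices per receptor.
#' @param tm_length_range Integer pair: TM helix length bounds.
#' @param loop_length_params Named list of `list(median=, range=c(min,max))`
#'   per non-TM domain (NTD, ICL1-3, ECL1-3, CTD); see
#'   `pmtrkit:::default_loop_params()` for the calibrated defaults.
#' @param planted_motifs List of `list(pattern=, domain=)`: each motif is
#'   realized once for the family and planted in every sequence within the
#'   named domain.
#' @param substitution_rate Per-residue substitution probability applied to
#'   each sequence copy (planted motifs and the initial methionine are
#'   protected).
#' @param seed Integer RNG seed.
#' @return List of class `family_spec`.
#' @export
family_spec <- function(n_species = 87,
                        copy_number_probs = c("1" = 0.345, "2" = 0.471,
                                              ">2" = 0.184),
                        tm_count = 7, tm_length_range = c(18, 25),
                        loop_length_params = default_loop_params(),
                        planted_motifs = list(
                          list(pattern = "YYSEM[KR]D", domain = "CTD"),
                          list(pattern = "LEhS", domain = "TM3")),
                        substitution_rate = 0.02, seed = 1L) {
  if (abs(sum(copy_number_probs) - 1) > 1e-9)
    config_error("copy_number_probs must sum to 1")
  if (!all(names(copy_number_probs) %in% c("1", "2", ">2")))
    config_error("copy_number_probs must be named '1', '2', '>2'")
  if (tm_count < 1) config_error("tm_count must be >= 1")
  if (tm_length_range[1] >= tm_length_range[2])
    config_error("tm_length_range must be non-degenerate")
  for (nm in names(loop_length_params)) {
    p <- loop_length_params[[nm]]
    if (p$range[1] > p$median || p$median > p$range[2])
      config_error(paste0(nm, ": median must lie within range"))
    if (p$range[1] >= p$range[2])
      config_error(paste0(nm, ": range must be non-degenerate"))
  }
  if (substitution_rate < 0 || substitution_rate > 1)
    config_error("substitution_rate must be in [0, 1]")
  structure(list(n_species = n_species,
                 copy_number_probs = copy_number_probs,
                 tm_count = tm_count,
                 tm_length_range = tm_length_range,
                 loop_length_params = loop_length_params,
                 planted_motifs = planted_motifs,
                 substitution_rate = substitution_rate,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# integer length with exact median: median + symmetric triangular offset
# (sum of two discrete uniforms), clamped to the range.  Symmetry puts less
# than half the mass on each side of the median and clamping preserves that,
# so the population median equals `med` exactly and empirical medians of
# large samples recover it.
sample_length <- function(med, range, n = 1) {
  d <- max(med - range[1], range[2] - med)
  h <- ceiling(d / 2)
  off <- (sample.int(2 * h + 1, n, replace = TRUE) - (h + 1)) +
         (sample.int(2 * h + 1, n, replace = TRUE) - (h + 1))
  pmin(pmax(med + off, range[1]), range[2])
}

# deterministic realization of a motif pattern: first residue of each
# set/class element, 'A' for wildcards
realize_motif <- function(pattern) {
  p <- compile_pattern(pattern)
  paste(vapply(p$elements, function(e) {
    if (e$type == "wildcard") "A" else e$residues[1]
  }, ""), collapse = "")
}

# domain order of a tm_count-helix receptor with extracellular NTD
family_domain_order <- function(tm_count) {
  doms <- "NTD"
  for (k in seq_len(tm_count)) {
    doms <- c(doms, paste0("TM", k))
    if (k < tm_count) {
      loop_i <- ceiling(k / 2)
      doms <- c(doms, if (k %% 2 == 1) paste0("ICL", loop_i)
                      else paste0("ECL", loop_i))
    }
  }
  c(doms, "CTD")
}

#' Generate a synthetic 7TM receptor family
#'
#' Builds a family template (per-domain consensus residues at the maximum
#' domain length, with planted motifs realized once for the family), then
#' emits sequences per species with clade-structured copy numbers.  Each
#' sequence samples its own domain lengths, takes the corresponding template
#' prefixes and applies per-residue substitutions.  Ground-truth topology and
#' motif positions are recorded per sequence; `clean_sequences` are the
#' pre-substitution consensus realizations (identical to `sequences` when
#' `substitution_rate = 0`).
#'
#' @param spec A [family_spec()].
#' @return List with `sequences` (named character vector),
#'   `clean_sequences`, `topology` (named list of `topology_annotation`),
#'   `motifs` (data.frame `sequence_id`, `pattern`, `domain`, `start`) and
#'   `species` (data.frame `sequence_id`, `species`, `copies`).
#' @export
gen_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(spec$seed, {
    doms <- family_domain_order(spec$tm_count)
    # family template: consensus residues per domain at maximal length
    max_len <- vapply(doms, function(d) {
      if (grepl("^TM", d)) spec$tm_length_range[2]
      else spec$loop_length_params[[d]]$range[2]
    }, 1)
    template <- lapply(doms, function(d) {
      sample(AA20, max_len[[d]], replace = TRUE)
    })
    names(template) <- doms
    template$NTD[1] <- "M"
    # realize and plant motifs in the template at fixed offsets: near the
    # distal end for the CTD, at the domain start otherwise (so they survive
    # any sampled length >= the domain range minimum)
    motif_offsets <- list()  # per motif: (domain, offset from domain start)
    for (mi in seq_along(spec$planted_motifs)) {
      pm <- spec$planted_motifs[[mi]]
      inst <- seq_chars(realize_motif(pm$pattern))
      dmin <- if (grepl("^TM", pm$domain)) spec$tm_length_range[1]
              else spec$loop_length_params[[pm$domain]]$range[1]
      if (length(inst) > dmin)
        config_error(paste0("motif '", pm$pattern,
                            "' does not fit the minimum length of ", pm$domain))
      off <- if (pm$domain == "CTD") dmin - length(inst) + 1L
             else if (pm$domain == "NTD") 2L else 1L
      template[[pm$domain]][seq.int(off, off + length(inst) - 1L)] <- inst
      motif_offsets[[mi]] <- list(domain = pm$domain, offset = off,
                                  length = length(inst),
                                  pattern = pm$pattern)
    }
    # copy numbers per species
    cats <- sample(names(spec$copy_number_probs), spec$n_species,
                   replace = TRUE, prob = spec$copy_number_probs)
    copies <- ifelse(cats == "1", 1L,
                     ifelse(cats == "2", 2L, sample(3:6, spec$n_species,
                                                    replace = TRUE)))
    seqs <- character(); clean <- character()
    topo <- list(); motif_rows <- list(); sp_rows <- list()
    for (s in seq_len(spec$n_species)) {
      for (cp in seq_len(copies[s])) {
        sid <- sprintf("sp%03d_c%d", s, cp)
        lens <- vapply(doms, function(d) {
          if (grepl("^TM", d))
            sample_length(round(mean(spec$tm_length_range)),
                          spec$tm_length_range)
          else {
            p <- spec$loop_length_params[[d]]
            sample_length(p$median, p$range)
          }
        }, 1)
        chars <- unlist(lapply(doms, function(d) template[[d]][seq_len(lens[[d]])]))
        clean_seq <- paste(chars, collapse = "")
        ends <- cumsum(lens)
        starts <- ends - lens + 1L
        ann <- topology_annotation(segment_df(doms, starts, ends),
                                  sequence_id = sid)
        # protected positions: initial M and planted motifs
        protected <- 1L
        for (mo in motif_offsets) {
          dstart <- starts[match(mo$domain, doms)]
          mstart <- dstart + mo$offset - 1L
          protected <- c(protected, seq.int(mstart, mstart + mo$length - 1L))
          motif_rows[[length(motif_rows) + 1]] <-
            data.frame(sequence_id = sid, pattern = mo$pattern,
                       domain = mo$domain, start = mstart)
        }
        if (spec$substitution_rate > 0) {
          hit <- which(runif(length(chars)) < spec$substitution_rate)
          hit <- setdiff(hit, protected)
          if (length(hit))
            chars[hit] <- sample(AA20, length(hit), replace = TRUE)
        }
        seqs[sid] <- paste(chars, collapse = "")
        clean[sid] <- clean_seq
        topo[[sid]] <- ann
        sp_rows[[length(sp_rows) + 1]] <-
          data.frame(sequence_id = sid, species = sprintf("species_%03d", s),
                     copies = copies[s])
      }
    }
    list(sequences = seqs, clean_sequences = clean, topology = topo,
         motifs = do.call(rbind, motif_rows),
         species = do.call(rbind, sp_rows))
  })
}

#' Write family sequences as FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}

#' Screening-cascade fixture specification
#'
#' Sizes of the exclusion categories a synthetic hit table must realize:
#' `n_fail_threshold` hits violating the E-value/length window, `n_partial`
#' sequences lacking the initial methionine, `n_fail_tm` failing the 7TM
#' two-predictor consensus, and `n_redundant` exact duplicates of retained
#' entries.
#'
#' @param n_total Total candidate count.
#' @param n_fail_threshold,n_partial,n_fail_tm,n_redundant Category sizes.
#' @param seed Integer RNG seed.
#' @return List of class `cascade_fixture_spec`.
#' @export
cascade_fixture_spec <- function(n_total, n_fail_threshold, n_partial,
                                 n_fail_tm, n_redundant, seed = 1L) {
  counts <- c(n_fail_threshold, n_partial, n_fail_tm, n_redundant)
  if (any(counts < 0) || n_total < 0)
    config_error("all counts must be non-negative")
  if (n_total < sum(counts))
    config_error("n_total smaller than the sum of exclusion categories")
  if (n_redundant > n_total - sum(counts))
    config_error("more redundant entries than retained entries to duplicate")
  structure(list(n_total = n_total, n_fail_threshold = n_fail_threshold,
                 n_partial = n_partial, n_fail_tm = n_fail_tm,
                 n_redundant = n_redundant, seed = as.integer(seed)),
            class = "cascade_fixture_spec")
}

random_protein <- function(len, start_met = TRUE) {
  chars <- sample(AA20, len, replace = TRUE)
  if (start_met) chars[1] <- "M"
  paste(chars, collapse = "")
}

# fabricated per-predictor segment table reporting n_tm TM segments for a
# protein of length len
fabricate_topology <- function(sequence_id, predictor, len, n_tm) {
  tm_len <- 19L; loop_len <- 6L; ctd_len <- 28L
  body <- n_tm * tm_len + max(n_tm - 1, 0) * loop_len + ctd_len
  ntd_len <- max(len - body, 1L)
  labels <- "NTD"; lens <- ntd_len
  for (k in seq_len(n_tm)) {
    labels <- c(labels, paste0("TM", k)); lens <- c(lens, tm_len)
    if (k < n_tm) {
      loop_i <- ceiling(k / 2)
      labels <- c(labels, if (k %% 2 == 1) paste0("ICL", loop_i)
                          else paste0("ECL", loop_i))
      lens <- c(lens, loop_len)
    }
  }
  labels <- c(labels, "CTD")
  lens <- c(lens, max(len - sum(lens), 1L))
  ends <- cumsum(lens); starts <- ends - lens + 1L
  data.frame(sequence_id = sequence_id, predictor = predictor,
             label = labels, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Generate a screening-cascade fixture
#'
#' Emits a hit table, three-predictor topology tables and ground-truth
#' category labels realizing exactly the category sizes of the spec.
#' Retained hits pass every stage (E-value at most 1e-25, length 200-400,
#' initial methionine, 7 TM segments from all three predictors, unique
#' sequences); each exclusion category violates exactly its own rule.
#' Redundant entries are exact sequence duplicates of retained entries with a
#' strictly worse E-value, so deduplication keeps the original.
#'
#' @param spec A [cascade_fixture_spec()].
#' @return List with `hits`, `predictions` (long-form topology table) and
#'   `truth` (data.frame `target_id`, `category`).
#' @export
gen_cascade_fixture <- function(spec) {
  stopifnot(inherits(spec, "cascade_fixture_spec"))
  with_seed(spec$seed, {
    n_retained <- spec$n_total - spec$n_fail_threshold - spec$n_partial -
      spec$n_fail_tm - spec$n_redundant
    categories <- c(rep("retained", n_retained),
                    rep("excluded_threshold", spec$n_fail_threshold),
                    rep("excluded_partial", spec$n_partial),
                    rep("excluded_tm", spec$n_fail_tm),
                    rep("excluded_redundant", spec$n_redundant))
    n <- length(categories)
    ids <- sprintf("cand%04d", seq_len(n))
    species <- sprintf("species_%03d", sample.int(max(1, ceiling(n / 2)), n,
                                                  replace = TRUE))
    lens <- sample(200:400, n, replace = TRUE)
    evalues <- 10^runif(n, -150, -25)
    seqs <- vapply(lens, random_protein, "")
    pred_rows <- vector("list", n)
    predictors <- c("phobius", "deeptmhmm", "tmbed")
    retained_idx <- which(categories == "retained")
    dup_cursor <- 0L
    for (i in seq_len(n)) {
      cat_i <- categories[i]
      tm_per_pred <- c(7L, 7L, 7L)
      if (cat_i == "excluded_threshold") {
        # alternate between E-value and length violations of the window
        if (i %% 2 == 0) evalues[i] <- 10^runif(1, -15, -5)
        else {
          lens[i] <- sample(c(120:199, 401:480), 1)
          seqs[i] <- random_protein(lens[i])
        }
      } else if (cat_i == "excluded_partial") {
        chars <- seq_chars(seqs[i])
        chars[1] <- sample(setdiff(AA20, "M"), 1)
        seqs[i] <- paste(chars, collapse = "")
      } else if (cat_i == "excluded_tm") {
        tm_per_pred <- c(6L, 6L, 7L)  # only one predictor sees 7 TMs
      } else if (cat_i == "excluded_redundant") {
        dup_cursor <- dup_cursor + 1L
        src <- retained_idx[dup_cursor]
        seqs[i] <- seqs[src]
        lens[i] <- lens[src]
        evalues[i] <- min(evalues[src] * 10, 1e-21)
      }
      pred_rows[[i]] <- do.call(rbind, lapply(seq_along(predictors), function(p)
        fabricate_topology(ids[i], predictors[p], lens[i], tm_per_pred[p])))
    }
    list(hits = data.frame(target_id = ids, species = species,
                           evalue = evalues, length = lens, sequence = seqs,
                           stringsAsFactors = FALSE),
         predictions = do.call(rbind, pred_rows),
         truth = data.frame(target_id = ids, category = categories,
                            stringsAsFactors = FALSE))
  })
}

#' Docking-site specification for the pose-ensemble generator
#'
#' @param center Length-3 site center (Angstrom).
#' @param center_sd Isotropic spread of pose centers around the site.
#' @param affinity_mean,affinity_sd Mean and spread of the per-run best
#'   binding affinities (kcal/mol).
#' @param skew Right-skew the affinity distribution (the superficial-pocket
#'   signature: a tail toward higher, less favorable, energies).
#' @param n_runs Number of docking runs at this site.
#' @return List of class `pose_site_spec`.
#' @export
pose_site_spec <- function(center, center_sd = 2, affinity_mean = -7,
                           affinity_sd = 0.4, skew = FALSE, n_runs = 500) {
  if (n_runs < 1) config_error("n_runs must be >= 1")
  if (center_sd <= 0) config_error("center_sd must be positive")
  if (length(center) != 3) config_error("center must have 3 coordinates")
  structure(list(center = as.numeric(center), center_sd = center_sd,
                 affinity_mean = affinity_mean, affinity_sd = affinity_sd,
                 skew = isTRUE(skew), n_runs = as.integer(n_runs)),
            class = "pose_site_spec")
}

melatonin_elements <- function() c(rep("C", 13), "N", "N", "O", "O")

#' Generate a two-site (or k-site) docking pose ensemble
#'
#' One best pose per simulated run.  Symmetric sites draw affinities from a
#' normal law; skewed sites from a gamma law standardized to the requested
#' mean and spread, giving the right-skewed shape of superficial pockets.
#' Each pose carries 17 heavy atoms (melatonin's C13 N2 O2 composition) whose
#' coordinate mean equals the drawn pose center exactly.
#'
#' @param sites List of [pose_site_spec()]s.
#' @param seed Integer RNG seed.
#' @return List with `poses` (parse-compatible pose list) and `truth`
#'   (data.frame `run_id`, `site`).
#' @export
gen_pose_ensemble <- function(sites, seed = 1L) {
  if (!length(sites)) config_error("at least one site spec required")
  # site centers must be separated well beyond typical clustering radii
  if (length(sites) > 1) {
    for (i in seq_along(sites)) for (j in seq_along(sites)) {
      if (i < j) {
        d <- sqrt(sum((sites[[i]]$center - sites[[j]]$center)^2))
        if (d <= 2 * max(sites[[i]]$center_sd, sites[[j]]$center_sd))
          config_error("site centers closer than twice the pose spread")
      }
    }
  }
  with_seed(seed, {
    poses <- list(); truth <- list()
    elements <- melatonin_elements()
    n_atoms <- length(elements)
    for (si in seq_along(sites)) {
      s <- sites[[si]]
      aff <- if (s$skew) {
        g <- rgamma(s$n_runs, shape = 4, rate = 1)      # mean 4, sd 2
        s$affinity_mean + s$affinity_sd * (g - 4) / 2
      } else {
        rnorm(s$n_runs, s$affinity_mean, s$affinity_sd)
      }
      for (r in seq_len(s$n_runs)) {
        ctr <- s$center + rnorm(3, 0, s$center_sd)
        offs <- matrix(rnorm(3 * n_atoms, 0, 1.5), ncol = 3)
        offs <- sweep(offs, 2, colMeans(offs))          # mean-free offsets
        atoms <- data.frame(element = elements,
                            x = ctr[1] + offs[, 1],
                            y = ctr[2] + offs[, 2],
                            z = ctr[3] + offs[, 3])
        rid <- sprintf("s%d_r%04d", si, r)
        poses[[length(poses) + 1]] <-
          list(run_id = rid, model_rank = 1L, affinity = aff[r], atoms = atoms)
        truth[[length(truth) + 1]] <- data.frame(run_id = rid, site = si)
      }
    }
    list(poses = poses, truth = do.call(rbind, truth))
  })
}

#' Write poses as a multi-model Vina-style file
#'
#' One MODEL/ENDMDL block per pose with a `REMARK VINA RESULT:` affinity
#' line, a `REMARK RUN:` id line and fixed-column HETATM records.
#'
#' @param poses Pose list (as from [gen_pose_ensemble()] or [parse_poses()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_file <- function(poses, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(poses)) {
    p <- poses[[i]]
    writeLines(sprintf("MODEL %d", i), con)
    writeLines(sprintf("REMARK VINA RESULT: %8.3f %8.3f %8.3f",
                       p$affinity, 0, 0), con)
    writeLines(paste0("REMARK RUN: ", p$run_id), con)
    a <- p$atoms
    for (j in seq_len(nrow(a))) {
      writeLines(sprintf(
        "HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        j, a$element[j], a$x[j], a$y[j], a$z[j], a$element[j]), con)
    }
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Tunnel specification for the profile generator
#'
#' @param length Tunnel length in Angstrom.
#' @param bottleneck Minimum radius in Angstrom.
#' @param bottleneck_position Fractional position of the bottleneck along the
#'   tunnel, in (0, 1).
#' @param entry_radius Radius at the tunnel opening; must be at least
#'   `bottleneck`.
#' @param energy_at_site Binding energy at the site end (kcal/mol).
#' @param energy_max Highest binding energy along the trajectory; must be at
#'   least `energy_at_site`.
#' @param n_samples Number of profile samples (>= 3).
#' @param seed Integer RNG seed for the profile jitter.
#' @return List of class `tunnel_spec`.
#' @export
tunnel_spec <- function(length = 8.2, bottleneck = 1.5,
                        bottleneck_position = 0.4, entry_radius = 2.5,
                        energy_at_site = -3.0, energy_max = -0.5,
                        n_samples = 25, seed = 1L) {
  if (bottleneck > entry_radius)
    config_error("bottleneck must not exceed entry_radius")
  if (n_samples < 3) config_error("n_samples must be >= 3")
  if (bottleneck_position <= 0 || bottleneck_position >= 1)
    config_error("bottleneck_position must lie in (0, 1)")
  if (energy_at_site > energy_max)
    config_error("energy_at_site must not exceed energy_max")
  if (length <= 0 || bottleneck <= 0)
    config_error("length and bottleneck must be positive")
  structure(list(length = length, bottleneck = bottleneck,
                 bottleneck_position = bottleneck_position,
                 entry_radius = entry_radius,
                 energy_at_site = energy_at_site, energy_max = energy_max,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "tunnel_spec")
}

#' Generate a tunnel radius profile and its transport profile
#'
#' The radius profile narrows from the entry radius to exactly the spec
#' bottleneck at the sample nearest the requested fractional position (with
#' a small upward-only jitter elsewhere, so the minimum is exact).  The
#' transport energy rises to exactly `energy_max` at the bottleneck and
#' relaxes to exactly `energy_at_site` at the site end (downward-only jitter
#' elsewhere, so the maximum and the final energy are exact).
#'
#' @param spec A [tunnel_spec()].
#' @return List with `tunnel` (a `tunnel_profile`) and `transport` (a
#'   `transport_profile`).
#' @export
gen_tunnel <- function(spec) {
  stopifnot(inherits(spec, "tunnel_spec"))
  with_seed(spec$seed, {
    s <- seq(0, spec$length, length.out = spec$n_samples)
    ib <- which.min(abs(s - spec$bottleneck_position * spec$length))
    if (ib == spec$n_samples) ib <- spec$n_samples - 1L
    if (ib == 1L) ib <- 2L
    dmax <- max(abs(s - s[ib]))
    g <- if (dmax > 0) abs(s - s[ib]) / dmax else rep(0, spec$n_samples)
    radius <- spec$bottleneck + (spec$entry_radius - spec$bottleneck) * g
    span_r <- spec$entry_radius - spec$bottleneck
    if (span_r > 0) {
      jit <- runif(spec$n_samples, 0, 0.05 * span_r)
      jit[ib] <- 0
      radius <- radius + jit
    }
    span_e <- spec$energy_max - spec$energy_at_site
    e0 <- spec$energy_max - 0.25 * span_e
    energy <- numeric(spec$n_samples)
    energy[seq_len(ib)] <- e0 + (spec$energy_max - e0) *
      (s[seq_len(ib)] / s[ib])
    post <- seq.int(ib, spec$n_samples)
    energy[post] <- spec$energy_max + (spec$energy_at_site - spec$energy_max) *
      (s[post] - s[ib]) / (s[spec$n_samples] - s[ib])
    if (span_e > 0) {
      ejit <- runif(spec$n_samples, 0, 0.05 * span_e)
      ejit[c(ib, spec$n_samples)] <- 0
      energy <- energy - ejit
    }
    list(tunnel = tunnel_profile(s, radius),
         transport = transport_profile(s, energy))
  })
}

#' Taxonomic composition of the HMM training set
#'
#' The per-taxon counts of the curated sequences used to build the screening
#' profile HMM: asterids 4, basal angiosperms 1, basal eudicots 2, fabids 3,
#' malvids 2, vitales 1, monocots 3 (16 sequences in total).
#'
#' @return data.frame with `taxon` and `n_sequences`.
#' @export
hmm_training_composition <- function() {
  data.frame(taxon = c("asterids", "basal angiosperms", "basal eudicots",
                       "fabids", "malvids", "vitales", "monocots"),
             n_sequences = c(4L, 1L, 2L, 3L, 2L, 1L, 3L),
             stringsAsFactors = FALSE)
}
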
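# Pipeline orchestration: run screening, topology statistics, numbering,
# motif prevalence, docking-site statistics and tunnel relevance from one
# configuration (real input files or synthetic specs) and collect a single
# structured report.

#' Pipeline run configuration
#'
#' Each stage runs when its entry is non-NULL; stages with no inputs are
#' reported as skipped.  Synthetic stages require the top-level `seed`.
#'
#' @param cascade Either a [cascade_fixture_spec()] or a list with file
#'   paths `hits` (TSV) and `topology` (TSV).
#' @param cascade_cfg A [cascade_config()].
#' @param family A [family_spec()] for the topology/motif stages, or `NULL`.
#' @param motif_patterns Character vector of motif patterns scanned over the
#'   family sequences.
#' @param pose_sites List of [pose_site_spec()]s, or a path to a pose file.
#' @param eps,min_pts DBSCAN parameters for the docking stage.
#' @param ligand A `ligand_info`.
#' @param tunnel A [tunnel_spec()] or a list with paths `tunnel`,
#'   `transport`.
#' @param ligand_geom A [ligand_geometry()].
#' @param seed Integer seed forwarded to synthetic stages.
#' @return List of class `run_config`.
#' @export
run_config <- function(cascade = NULL, cascade_cfg = cascade_config(),
                       family = NULL,
                       motif_patterns = c("YYSEM[KR]D", "LEhS"),
                       pose_sites = NULL, eps = 7, min_pts = 20,
                       ligand = melatonin(), tunnel = NULL,
                       ligand_geom = ligand_geometry(), seed = 1L) {
  structure(list(cascade = cascade, cascade_cfg = cascade_cfg,
                 family = family, motif_patterns = motif_patterns,
                 pose_sites = pose_sites, eps = eps, min_pts = min_pts,
                 ligand = ligand, tunnel = tunnel,
                 ligand_geom = ligand_geom, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  # version-stable serialization of the de-classed config
  saveRDS(rapply(unclass(config), unclass, how = "replace"), tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order (screen, topology, motifs,
#' docking, tunnels) and assembles an `analysis_report`.  A fixed seed makes
#' the whole report reproducible; the provenance block records the config
#' hash, seed and package version.
#'
#' @param config A [run_config()].
#' @return List of class `analysis_report` with one element per stage
#'   (`NULL` elements are explicitly marked skipped in `$stages`) and a
#'   `provenance` block.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list()
  stages <- list()

  if (!is.null(config$cascade)) {
    fx <- if (inherits(config$cascade, "cascade_fixture_spec")) {
      gen_cascade_fixture(config$cascade)
    } else {
      list(hits = read_hit_tsv(config$cascade$hits),
           predictions = read_topology_tsv(config$cascade$topology),
           truth = NULL)
    }
    cas <- run_cascade(fx$hits, fx$predictions, config$cascade_cfg)
    report$cascade <- cas$report
    stages$cascade <- "run"
  } else stages$cascade <- "skipped"

  fam <- NULL
  if (!is.null(config$family)) {
    fam <- gen_family(config$family)
    tab <- domain_length_table(fam$topology)
    domains <- unique(tab$domain)
    med <- vapply(domains, function(d) median(tab$length[tab$domain == d]), 0)
    report$domain_lengths <- data.frame(domain = domains,
                                        median_length = unname(med))
    stages$topology <- "run"
  } else stages$topology <- "skipped"

  if (!is.null(fam) && length(config$motif_patterns)) {
    report$motifs <- do.call(rbind, lapply(config$motif_patterns, function(p) {
      pv <- prevalence(fam$sequences, p)
      data.frame(pattern = p, n_sequences = length(fam$sequences),
                 n_matching = pv$count,
                 n_non_matching = length(pv$non_matching))
    }))
    stages$motifs <- "run"
  } else stages$motifs <- "skipped"

  if (!is.null(config$pose_sites)) {
    poses <- if (is.character(config$pose_sites)) {
      parse_poses(config$pose_sites)
    } else {
      gen_pose_ensemble(config$pose_sites, seed = config$seed)$poses
    }
    dock <- analyze_docking_sites(poses, eps = config$eps,
                                  min_pts = config$min_pts,
                                  ligand = config$ligand)
    report$docking <- dock$sites
    stages$docking <- "run"
  } else stages$docking <- "skipped"

  if (!is.null(config$tunnel)) {
    tn <- if (inherits(config$tunnel, "tunnel_spec")) gen_tunnel(config$tunnel)
          else list(tunnel = read_tunnel_tsv(config$tunnel$tunnel),
                    transport = read_transport_tsv(config$tunnel$transport))
    ts <- transport_summary(tn$transport)
    rel <- is_relevant(tn$tunnel, tn$transport, config$ligand_geom)
    report$tunnel <- list(length_A = tunnel_length(tn$tunnel),
                          bottleneck_A = bottleneck(tn$tunnel),
                          throughput = throughput(tn$tunnel),
                          e_max = ts$e_max, e_at_site = ts$e_at_site,
                          relevant = rel$relevant, reasons = rel$reasons)
    stages$tunnel <- "run"
  } else stages$tunnel <- "skipped"

  report$stages <- stages
  report$provenance <- list(
    config_hash = config_hash(config), seed = config$seed,
    package_version = as.character(utils::packageVersion("pmtrkit")))
  structure(report, class = "analysis_report")
}

#' Write / read an analysis report as JSON
#'
#' The JSON round-trips: reading back yields the same stage tables and
#' counts.
#'
#' @param report An `analysis_report`.
#' @param path File path.
#' @return `path` (writer) or the report list (reader).
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  if (!is.null(x$cascade)) x$cascade <- unclass(x$cascade)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
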
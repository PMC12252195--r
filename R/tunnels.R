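# Tunnel geometry/energy summarization and the biological-relevance filter
# for ligand access to the internal binding site.  A tunnel profile samples
# the sphere radius along the tunnel axis (arc length from the surface); a
# transport profile samples the ligand binding energy along the same axis.

#' Construct a tunnel profile
#'
#' @param arc_length Strictly increasing arc lengths in Angstrom, starting
#'   at 0.
#' @param radius Positive radii in Angstrom, one per sample.
#' @param tunnel_id,receptor_id Identifiers.
#' @return List of class `tunnel_profile`.
#' @export
tunnel_profile <- function(arc_length, radius, tunnel_id = "t1",
                           receptor_id = NA_character_) {
  if (length(arc_length) < 3) data_error("tunnel profile needs >= 3 samples")
  if (length(radius) != length(arc_length))
    data_error("arc_length and radius differ in length")
  if (arc_length[1] != 0) data_error("arc_length must start at 0")
  if (is.unsorted(arc_length, strictly = TRUE))
    data_error("arc_length must be strictly increasing")
  if (any(radius <= 0)) data_error("radii must be positive")
  structure(list(arc_length = arc_length, radius = radius,
                 tunnel_id = tunnel_id, receptor_id = receptor_id),
            class = "tunnel_profile")
}

#' Construct a transport (energy) profile
#'
#' Direction is surface-to-site: the last sample sits at the binding site.
#'
#' @param arc_length Strictly increasing arc lengths in Angstrom.
#' @param energy Finite binding energies in kcal/mol, one per sample.
#' @return List of class `transport_profile`.
#' @export
transport_profile <- function(arc_length, energy) {
  if (length(arc_length) != length(energy))
    data_error("arc_length and energy differ in length")
  if (is.unsorted(arc_length, strictly = TRUE))
    data_error("arc_length must be strictly increasing")
  if (any(!is.finite(energy))) data_error("energies must be finite")
  structure(list(arc_length = arc_length, energy = energy),
            class = "transport_profile")
}

#' Tunnel length
#'
#' The arc length of the last sample (distance from the surface opening to
#' the site end of the tunnel).
#'
#' @param profile A `tunnel_profile`.
#' @return Length in Angstrom.
#' @export
tunnel_length <- function(profile) {
  profile$arc_length[length(profile$arc_length)]
}

#' Bottleneck radius
#'
#' The minimum sphere radius along the tunnel.
#'
#' @param profile A `tunnel_profile`.
#' @return Radius in Angstrom.
#' @export
bottleneck <- function(profile) min(profile$radius)

#' Tunnel throughput score
#'
#' A (0, 1] permissiveness score: `exp(-k * integral ds / r(s)^2)`, the
#' trapezoidal integral of the inverse squared radius along the tunnel,
#' damped by the scale constant `k`.  Wider or shorter tunnels score higher:
#' the score is strictly decreasing in length at fixed radius and strictly
#' increasing in radius at fixed length.  For a constant radius `r` over
#' length `L` the closed form is `exp(-k * L / r^2)`.  The default scale
#' `k = 0.1` per Angstrom puts typical single-ligand protein tunnels
#' (lengths of a few to ~15 Angstrom, radii 1-3 Angstrom) in the mid range
#' of (0, 1).
#'
#' @param profile A `tunnel_profile`.
#' @param scale Damping constant `k`.
#' @return Throughput in (0, 1].
#' @export
throughput <- function(profile, scale = 0.1) {
  if (any(profile$radius == 0)) data_error("zero radius sample")
  cost <- pracma::trapz(profile$arc_length, 1 / profile$radius^2)
  exp(-scale * cost)
}

#' Transport-profile summary
#'
#' The energy maximum along the trajectory (Emax, the least favorable point),
#' its position, and the energy at the binding site (last sample).
#'
#' @param transport A `transport_profile`.
#' @return List with `e_max`, `e_max_position` (arc length of the maximum;
#'   first occurrence on ties) and `e_at_site`.
#' @export
transport_summary <- function(transport) {
  i <- which.max(transport$energy)
  list(e_max = transport$energy[i],
       e_max_position = transport$arc_length[i],
       e_at_site = transport$energy[length(transport$energy)])
}

#' Ligand geometry thresholds
#'
#' @param min_cross_section_radius Minimum tunnel bottleneck radius the
#'   ligand can squeeze through (Angstrom).  The default, 1.4, sits strictly
#'   below the narrowest bottleneck observed for melatonin-accessible tunnels
#'   (1.5 Angstrom).
#' @param max_length Optional maximum tunnel length the ligand will traverse
#'   (`Inf` disables the criterion).
#' @return List of class `ligand_geometry`.
#' @export
ligand_geometry <- function(min_cross_section_radius = 1.4,
                            max_length = Inf) {
  if (min_cross_section_radius <= 0 || max_length <= 0)
    config_error("ligand geometry thresholds must be positive")
  structure(list(min_cross_section_radius = min_cross_section_radius,
                 max_length = max_length),
            class = "ligand_geometry")
}

#' Biological relevance of a tunnel
#'
#' A tunnel is relevant iff (1) its bottleneck radius is at least the
#' ligand's minimum cross-section radius and its length lies within
#' `[min_length, ligand$max_length]` (i.e. the tunnel can accommodate the
#' ligand), and (2) the highest binding energy along the transport
#' trajectory (Emax) is negative.
#'
#' @param profile A `tunnel_profile`.
#' @param transport The matching `transport_profile`.
#' @param ligand A `ligand_geometry`.
#' @param min_length Minimum acceptable tunnel length (default 0, i.e. no
#'   lower bound).
#' @return List with `relevant` (logical) and `reasons` (character vector of
#'   failed criteria; empty when relevant).
#' @export
is_relevant <- function(profile, transport, ligand = ligand_geometry(),
                        min_length = 0) {
  reasons <- character()
  if (bottleneck(profile) < ligand$min_cross_section_radius)
    reasons <- c(reasons, "bottleneck below ligand radius")
  len <- tunnel_length(profile)
  if (len < min_length) reasons <- c(reasons, "tunnel shorter than minimum length")
  if (len > ligand$max_length) reasons <- c(reasons, "tunnel longer than ligand maximum")
  if (transport_summary(transport)$e_max >= 0)
    reasons <- c(reasons, "positive Emax")
  list(relevant = length(reasons) == 0, reasons = reasons)
}

#' Read / write tunnel and transport TSVs
#'
#' Tunnel TSV columns: `arc_length_A`, `radius_A` and optionally `tunnel_id`;
#' transport TSV columns: `arc_length_A`, `energy_kcal_mol`.
#'
#' @param path File path.
#' @param tunnel_id,receptor_id Identifiers for the constructed profile.
#' @return The corresponding profile object (readers) or `path` (writers).
#' @export
read_tunnel_tsv <- function(path, tunnel_id = "t1",
                            receptor_id = NA_character_) {
  df <- read.table(path, sep = "\t", header = TRUE)
  if (!all(c("arc_length_A", "radius_A") %in% names(df)))
    parse_error("tunnel TSV needs columns arc_length_A and radius_A")
  if ("tunnel_id" %in% names(df)) tunnel_id <- df$tunnel_id[1]
  tunnel_profile(df$arc_length_A, df$radius_A, tunnel_id, receptor_id)
}

#' @rdname read_tunnel_tsv
#' @export
read_transport_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  if (!all(c("arc_length_A", "energy_kcal_mol") %in% names(df)))
    parse_error("transport TSV needs columns arc_length_A and energy_kcal_mol")
  transport_profile(df$arc_length_A, df$energy_kcal_mol)
}

#' @rdname read_tunnel_tsv
#' @param profile A `tunnel_profile` (tunnel writer).
#' @export
write_tunnel_tsv <- function(profile, path) {
  write.table(data.frame(tunnel_id = profile$tunnel_id,
                         arc_length_A = profile$arc_length,
                         radius_A = profile$radius),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_tunnel_tsv
#' @param transport A `transport_profile` (transport writer).
#' @export
write_transport_tsv <- function(transport, path) {
  write.table(data.frame(arc_length_A = transport$arc_length,
                         energy_kcal_mol = transport$energy),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tunnel relevance report as JSON
#'
#' @param profile A `tunnel_profile`.
#' @param transport The matching `transport_profile`.
#' @param ligand A `ligand_geometry`.
#' @param path Output path.
#' @return The report list, invisibly; also written to `path`.
#' @export
write_relevance_json <- function(profile, transport,
                                 ligand = ligand_geometry(), path) {
  ts <- transport_summary(transport)
  rel <- is_relevant(profile, transport, ligand)
  report <- list(tunnel_id = profile$tunnel_id,
                 receptor_id = profile$receptor_id,
                 length_A = tunnel_length(profile),
                 bottleneck_A = bottleneck(profile),
                 throughput = throughput(profile),
                 e_max = ts$e_max, e_at_site = ts$e_at_site,
                 relevant = rel$relevant, reasons = rel$reasons)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(report)
}
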
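#' Generate a two-transect environmental/spatial site table
#'
#' Emulates a deep-sea sampling design with two intersecting transects: a
#' bathymetric transect (sites `HGI`..`HGVI`, water depth increasing from
#' 1284 m to 3535 m) and a latitudinal transect (`N4`..`N1`, `HGIV`,
#' `S1`..`S3`) running at a nearly constant depth of ~2500 m. The central
#' site `HGIV` belongs to both transects. Chloroplastic pigment equivalents
#' (CPE, a phytodetritus proxy) decrease with water depth by construction;
#' porosity decreases weakly with depth; particulate protein tracks CPE.
#'
#' @param n_sites total number of distinct sites (>= 4; default 13, the
#'   6 + 8 two-transect layout sharing one central site).
#' @param seed integer seed; the table is deterministic given the seed.
#' @return A `data.frame` with columns `site_id`, `depth` (m), `cpe`
#'   (ug cm^-3), `porosity` (% volume), `protein` (arbitrary units),
#'   `easting` (m), `northing` (m) and `transect`
#'   (`"bathymetric"`, `"latitudinal"` or `"both"` for the shared site).
#'   Row order is the display order used throughout: bathymetric sites by
#'   increasing depth, then latitudinal sites from north to south.
#' @export
generate_env_table <- function(n_sites = 13L, seed = 1L) {
  if (!is.numeric(n_sites) || n_sites < 4)
    stop("invalid design: need at least 4 sites to place two transects")
  n_sites <- as.integer(n_sites)
  set.seed(seed)

  depth_range    <- c(1284, 3535)
  cpe_range      <- c(18.86, 44.26)
  porosity_range <- c(51.8, 72.3)
  easting_range  <- c(512100, 565125)
  northing_range <- c(8727035, 8850377)

  if (n_sites == 13L) {
    bath_ids <- c("HGI", "HGII", "HGIII", "HGIV", "HGV", "HGVI")
    lat_ids  <- c("N4", "N3", "N2", "N1", "HGIV", "S1", "S2", "S3")
  } else {
    n_bath <- max(3L, ceiling((n_sites + 1L) / 2L))
    n_lat  <- n_sites + 1L - n_bath
    if (n_lat < 2L) { n_lat <- 2L; n_bath <- n_sites - 1L }
    bath_ids <- paste0("B", seq_len(n_bath))
    shared   <- bath_ids[ceiling(n_bath / 2)]
    lat_only <- paste0("L", seq_len(n_lat - 1L))
    half     <- ceiling((n_lat - 1L) / 2L)
    lat_ids  <- c(lat_only[seq_len(half)], shared,
                  lat_only[setdiff(seq_len(n_lat - 1L), seq_len(half))])
  }
  shared_id <- intersect(bath_ids, lat_ids)
  stopifnot(length(shared_id) == 1L)
  site_ids <- c(bath_ids, setdiff(lat_ids, shared_id))

  n_bath <- length(bath_ids)
  # monotone depth profile along the bathymetric transect; jitter kept small
  # relative to the station spacing so monotonicity is preserved
  bath_depth <- seq(depth_range[1], depth_range[2], length.out = n_bath)
  spacing <- diff(depth_range) / (n_bath - 1)
  jit <- stats::runif(n_bath, -0.2, 0.2) * spacing
  jit[c(1, n_bath)] <- 0
  bath_depth <- sort(bath_depth + jit)

  shared_depth <- bath_depth[match(shared_id, bath_ids)]
  lat_other <- setdiff(lat_ids, shared_id)
  # latitudinal transect sits on the ~2500 m isobath of the shared site
  lat_depth <- pmin(pmax(shared_depth + stats::rnorm(length(lat_other), 0, 60),
                         depth_range[1]), depth_range[2])

  depth <- c(bath_depth, lat_depth)
  names(depth) <- c(bath_ids, lat_other)
  depth <- depth[site_ids]

  # CPE declines with depth (food supply attenuates through the water column)
  z <- (depth - depth_range[1]) / diff(depth_range)
  cpe <- cpe_range[2] - z * diff(cpe_range) +
    stats::rnorm(n_sites, 0, 0.04 * diff(cpe_range))
  cpe <- pmin(pmax(cpe, cpe_range[1]), cpe_range[2])

  porosity <- porosity_range[2] - z * 0.45 * diff(porosity_range) +
    stats::rnorm(n_sites, 0, 0.10 * diff(porosity_range))
  porosity <- pmin(pmax(porosity, porosity_range[1]), porosity_range[2])

  protein <- 120 + 4 * (cpe - mean(cpe)) + stats::rnorm(n_sites, 0, 6)

  # bathymetric stations spread west-east, latitudinal stations north-south
  easting <- northing <- numeric(n_sites)
  names(easting) <- names(northing) <- site_ids
  e_seq <- seq(easting_range[1], easting_range[2], length.out = n_bath)
  n_mid <- mean(northing_range)
  easting[bath_ids]  <- e_seq
  northing[bath_ids] <- n_mid + stats::rnorm(n_bath, 0, 2000)
  n_lat_all <- length(lat_ids)
  n_seq <- seq(northing_range[2], northing_range[1], length.out = n_lat_all)
  shared_pos <- match(shared_id, lat_ids)
  off <- n_seq - n_seq[shared_pos]
  northing[lat_other] <- northing[shared_id] + off[-shared_pos]
  northing <- pmin(pmax(northing, northing_range[1]), northing_range[2])
  easting[lat_other] <- easting[shared_id] + stats::rnorm(length(lat_other), 0, 1500)
  easting <- pmin(pmax(easting, easting_range[1]), easting_range[2])

  transect <- ifelse(site_ids %in% shared_id, "both",
                     ifelse(site_ids %in% bath_ids, "bathymetric", "latitudinal"))

  out <- data.frame(
    site_id  = site_ids,
    depth    = unname(depth),
    cpe      = unname(cpe),
    porosity = unname(porosity),
    protein  = unname(protein),
    easting  = unname(easting[site_ids]),
    northing = unname(northing[site_ids]),
    transect = transect,
    stringsAsFactors = FALSE
  )
  # fixed display order: bathymetric shallow->deep, then latitudinal north->south
  ord <- c(bath_ids, lat_ids[-shared_pos])
  out <- out[match(ord, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Site display order of an environmental table
#'
#' @param env a table from [generate_env_table()].
#' @return character vector of site ids in transect display order.
#' @export
site_order <- function(env) env$site_id
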
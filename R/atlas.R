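#' Build a synthetic spherical parcellation atlas
#'
#' Lays out `n_per_hemisphere` parcel centroids per hemisphere on the unit
#' sphere by a deterministic Fibonacci lattice along the x axis: the left
#' hemisphere takes the lattice points with x < 0 and the right hemisphere is
#' its mirror image (x -> -x). This stands in for a surface parcellation of
#' roughly equal-sized cortical parcels (e.g. a 308-parcel subdivision of the
#' Desikan-Killiany atlas with 154 parcels per hemisphere).
#'
#' Two system-label schemes are attached so system-level aggregation can be
#' exercised: `yeo7`-style labels from `n_systems` contiguous latitude bands
#' (equal-count bands of the z coordinate) and a fixed five-class
#' `veconomo`-style scheme from bands of the y coordinate. Mirrored parcels
#' share labels.
#'
#' @param n_per_hemisphere parcels per hemisphere (>= 4).
#' @param n_systems number of latitude-band systems for the `yeo7` scheme.
#' @param seed integer seed, kept for interface uniformity; the lattice is
#'   deterministic so the same arguments always give the same atlas.
#' @return tibble of class `parcel_atlas` with columns `region_id` (1-based,
#'   contiguous; left hemisphere first), `hemisphere` ("L"/"R"), unit-norm
#'   centroid coordinates `cx`, `cy`, `cz`, and label columns `yeo7`,
#'   `veconomo`.
#' @examples
#' atlas <- make_atlas(16, n_systems = 4)
#' nrow(atlas)
#' @export
make_atlas <- function(n_per_hemisphere, n_systems = 7, seed = 1) {
  n <- check_positive_int(n_per_hemisphere, "n_per_hemisphere")
  n_systems <- check_positive_int(n_systems, "n_systems")
  if (n < 4) {
    stop_msntx("`n_per_hemisphere` must be at least 4.", "invalid_argument")
  }
  m <- 2L * n
  i <- seq_len(m) - 1L
  golden <- pi * (3 - sqrt(5))
  x <- 1 - (2 * i + 1) / m
  r <- sqrt(pmax(0, 1 - x^2))
  phi <- i * golden
  y <- r * cos(phi)
  z <- r * sin(phi)
  # lattice x values are antisymmetric around 0: the last n points have x < 0
  left <- which(x < 0)
  stopifnot(length(left) == n)
  lx <- x[left]; ly <- y[left]; lz <- z[left]

  band <- function(v, k) {
    if (k == 1L) return(rep(1L, length(v)))
    cut(rank(v, ties.method = "first"), breaks = k, labels = FALSE)
  }
  yeo <- paste0("system_", band(lz, n_systems))
  vec <- paste0("class_", band(ly, min(5L, n)))

  out <- tibble::tibble(
    region_id = seq_len(m),
    hemisphere = rep(c("L", "R"), each = n),
    cx = c(lx, -lx),
    cy = c(ly, ly),
    cz = c(lz, lz),
    yeo7 = c(yeo, yeo),
    veconomo = c(vec, vec)
  )
  class(out) <- c("parcel_atlas", class(out))
  out
}

#' Extract centroid coordinates from an atlas
#'
#' @param atlas a `parcel_atlas` tibble.
#' @param hemisphere optional "L" or "R" to subset.
#' @return numeric matrix (n x 3) with region_ids as rownames.
#' @export
atlas_centroids <- function(atlas, hemisphere = NULL) {
  if (!is.null(hemisphere)) atlas <- atlas[atlas$hemisphere == hemisphere, ]
  m <- as.matrix(atlas[, c("cx", "cy", "cz")])
  rownames(m) <- atlas$region_id
  m
}

#' Write / read an atlas as TSV
#'
#' @param atlas a `parcel_atlas` tibble.
#' @param path file path.
#' @return `path`, invisibly (writer); a `parcel_atlas` tibble (reader).
#' @export
write_atlas <- function(atlas, path) {
  readr::write_tsv(atlas, path)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  out$region_id <- as.integer(out$region_id)
  class(out) <- c("parcel_atlas", class(out))
  out
}
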
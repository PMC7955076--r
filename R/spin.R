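#' Generate spatial permutations ("spins") of a parcellation
#'
#' Draws uniform random 3D rotations (normalized-quaternion method), applies
#' each to the left-hemisphere parcel centroids, and maps the rotated
#' centroids back to the original parcels by one-to-one greedy matching in
#' ascending distance order (ties broken toward the lower region index).
#' With `hemisphere_scope = "both_mirrored"` the x-mirrored rotation is
#' applied to the right hemisphere and matching is done within hemisphere,
#' yielding permutations over all regions; with `"left_only"` (the default,
#' matching analyses restricted to left-hemisphere expression coverage) only
#' left-hemisphere maps are permuted.
#'
#' The resulting null preserves each map's values and spatial autocorrelation
#' while breaking its alignment with other maps, which is what makes spin
#' p-values valid for smooth cortical maps.
#'
#' @param atlas a `parcel_atlas`.
#' @param n_spins number of rotations.
#' @param seed integer seed governing the full rotation stream.
#' @param hemisphere_scope "left_only" or "both_mirrored".
#' @return object of class `spin_set`: list with `permutations`
#'   (n_spins x n_regions integer matrix of indices into `region_id`),
#'   `region_id`, `n_spins`, `seed`, `scope`.
#' @export
generate_spins <- function(atlas, n_spins, seed = 1,
                           hemisphere_scope = c("left_only", "both_mirrored")) {
  n_spins <- check_positive_int(n_spins, "n_spins")
  hemisphere_scope <- match.arg(hemisphere_scope)
  left <- atlas[atlas$hemisphere == "L", ]
  right <- atlas[atlas$hemisphere == "R", ]
  cl <- atlas_centroids(left)
  cr <- if (nrow(right)) atlas_centroids(right) else NULL
  mirror <- diag(c(-1, 1, 1))

  rots <- withr::with_seed(seed, {
    purrr::map(seq_len(n_spins), function(i) random_rotation())
  })

  perms <- matrix(0L, n_spins,
                  if (hemisphere_scope == "left_only") nrow(left) else nrow(atlas))
  for (i in seq_len(n_spins)) {
    r <- rots[[i]]
    pl <- greedy_match(cl %*% t(r), cl)
    if (hemisphere_scope == "left_only") {
      perms[i, ] <- pl
    } else {
      rr <- mirror %*% r %*% mirror
      pr <- greedy_match(cr %*% t(rr), cr)
      perms[i, ] <- c(pl, nrow(left) + pr)
    }
  }
  region_id <- if (hemisphere_scope == "left_only") left$region_id else atlas$region_id
  structure(list(permutations = perms, region_id = region_id,
                 n_spins = n_spins, seed = as.integer(seed),
                 scope = hemisphere_scope),
            class = "spin_set")
}

# Internal: uniform random rotation matrix via a normalized Gaussian quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d),    2 * (b * d + a * c),
    2 * (b * c + a * d),   a^2 - b^2 + c^2 - d^2,  2 * (c * d - a * b),
    2 * (b * d - a * c),   2 * (c * d + a * b),    a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}

# Internal: one-to-one greedy assignment of rotated points to originals in
# ascending distance order; perm[i] = j means original parcel j's value moves
# to position i. Ties resolve by lower linear index, i.e. lower original then
# lower rotated region index.
greedy_match <- function(rotated, original) {
  n <- nrow(original)
  d2 <- outer(rowSums(rotated^2), rowSums(original^2), "+") -
    2 * tcrossprod(rotated, original)
  ord <- order(d2)
  perm <- integer(n)
  row_free <- rep(TRUE, n)
  col_free <- rep(TRUE, n)
  left <- n
  for (idx in ord) {
    i <- ((idx - 1L) %% n) + 1L
    j <- ((idx - 1L) %/% n) + 1L
    if (row_free[i] && col_free[j]) {
      perm[i] <- j
      row_free[i] <- FALSE
      col_free[j] <- FALSE
      left <- left - 1L
      if (left == 0L) break
    }
  }
  perm
}

#' Permutation p-value with add-one correction
#'
#' `(1 + #{null at least as extreme}) / (n + 1)`; the add-one correction
#' keeps p strictly positive so downstream FDR is well behaved. The
#' two-sided value is twice the smaller one-sided value, capped at 1.
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of null statistics.
#' @param alternative "greater", "less" or "two_sided".
#' @return p-value in (0, 1].
#' @export
spin_pvalue <- function(observed, null_values,
                        alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  if (!length(null_values)) stop_msntx("empty null distribution.", "invalid_argument")
  n <- length(null_values)
  pg <- (1 + sum(null_values >= observed)) / (n + 1)
  pl <- (1 + sum(null_values <= observed)) / (n + 1)
  switch(alternative,
         greater = pg,
         less = pl,
         two_sided = min(1, 2 * min(pg, pl)))
}

#' Spin correlation test between two regional maps
#'
#' Correlates `map_a` with `map_b`, builds the null by correlating spun
#' versions of `map_a` with the fixed `map_b`, and returns the add-one
#' corrected permutation p-value.
#'
#' @param map_a,map_b numeric vectors aligned with `spins$region_id` (or
#'   named by region_id, or tibbles with `region_id` + value).
#' @param spins a `spin_set`.
#' @param method "pearson" or "spearman".
#' @param alternative "greater", "less" or "two_sided".
#' @return list (r_observed, p_spin, null) where `null` holds the spun
#'   correlations.
#' @export
spin_correlation_test <- function(map_a, map_b, spins,
                                  method = c("pearson", "spearman"),
                                  alternative = c("greater", "less", "two_sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  a <- as_region_vector(map_a, spins$region_id)
  b <- as_region_vector(map_b, spins$region_id)
  n <- length(a)
  if (ncol(spins$permutations) != n) {
    stop_msntx("map length does not match the spin set.", "invalid_argument")
  }
  if (method == "spearman") { a <- rank(a); b <- rank(b) }
  obs <- cor(a, b)
  # all spun maps share a's mean/sd (permutation preserves the multiset)
  perm <- spins$permutations
  am <- matrix(a[t(perm)], nrow = n)           # regions x spins
  nulls <- as.numeric(crossprod(am - mean(a), b - mean(b))) /
    ((n - 1) * sd(a) * sd(b))
  list(r_observed = obs, p_spin = spin_pvalue(obs, nulls, alternative),
       null = nulls)
}

#' Write / read a spin set (integer TSV + JSON sidecar)
#'
#' @param spins a `spin_set`.
#' @param path base path; writes `<path>.tsv` and `<path>.json`.
#' @return base path invisibly (writer); a `spin_set` (reader).
#' @export
write_spins <- function(spins, path) {
  utils::write.table(spins$permutations, paste0(path, ".tsv"),
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  writeLines(jsonlite::toJSON(
    list(seed = spins$seed, n_spins = spins$n_spins, scope = spins$scope,
         region_id = spins$region_id),
    auto_unbox = TRUE), paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_spins
#' @export
read_spins <- function(path) {
  perms <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
  dimnames(perms) <- NULL
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  structure(list(permutations = perms, region_id = meta$region_id,
                 n_spins = meta$n_spins, seed = meta$seed, scope = meta$scope),
            class = "spin_set")
}
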
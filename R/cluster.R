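#' Distance-threshold hotspot clustering
#'
#' Detects spatial clusters of a selected cell population as the connected
#' components of the graph whose edges join cell pairs at Euclidean distance
#' strictly below `d_max` (chains merge: any two cells linked through
#' intermediate cells share a cluster). Components smaller than `min_cells`
#' are dissolved to non-clustering (cluster id 0). The number of clusters is
#' never specified in advance. Cluster ids of the surviving components are a
#' seeded random permutation, mirroring randomized display colors; the
#' partition itself does not depend on `label_seed`.
#'
#' @param cells Cell table (or data frame) with `x_um`, `y_um` coordinates in
#'   um; typically already subset to one population.
#' @param d_max Maximum link distance in um (pairs at exactly `d_max` do not
#'   link). Default 50.
#' @param min_cells Minimum cluster size, >= 2. Default 10.
#' @param label_seed Seed for the randomized cluster ids. Default 1.
#' @return A list of class `hotspot_clusters`: `cells` (input plus
#'   `component_id` - raw component before the size filter - and
#'   `cluster_id`, 0 = non-clustering), `summary` (tibble: `cluster_id`,
#'   `n_cells`, `centroid_x`, `centroid_y`), and `params`.
#' @export
cluster_hotspots <- function(cells, d_max = 50, min_cells = 10, label_seed = 1) {
  if (d_max <= 0) stopf("d_max must be > 0")
  if (min_cells < 2) stopf("min_cells must be >= 2")
  cells <- tibble::as_tibble(cells)
  if (nrow(cells) && (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um))))
    stopf("non-finite cell coordinates")
  comp <- eps_components_cpp(as.numeric(cells$x_um), as.numeric(cells$y_um), d_max)
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_cells)
  cluster_id <- integer(nrow(cells))
  if (length(keep)) {
    new_id <- integer(max(comp))
    new_id[keep] <- with_seed(label_seed, sample.int(length(keep)))
    big <- comp %in% keep
    cluster_id[big] <- new_id[comp[big]]
  }
  cells$component_id <- comp
  cells$cluster_id <- cluster_id
  summ <- if (any(cluster_id > 0)) {
    inc <- cluster_id > 0
    f <- factor(cluster_id[inc])
    tibble::tibble(cluster_id = as.integer(levels(f)),
                   n_cells = as.integer(table(f)),
                   centroid_x = as.numeric(tapply(cells$x_um[inc], f, mean)),
                   centroid_y = as.numeric(tapply(cells$y_um[inc], f, mean)))
  } else {
    tibble::tibble(cluster_id = integer(), n_cells = integer(),
                   centroid_x = numeric(), centroid_y = numeric())
  }
  structure(list(cells = cells, summary = summ,
                 params = list(d_max = d_max, min_cells = min_cells,
                               label_seed = label_seed)),
            class = "hotspot_clusters")
}

#' @export
print.hotspot_clusters <- function(x, ...) {
  cat(sprintf("<hotspot_clusters> %d cells, %d clusters (d_max = %g um, min %d cells)\n",
              nrow(x$cells), nrow(x$summary), x$params$d_max, x$params$min_cells))
  invisible(x)
}

#' Multi-scale hotspot clustering
#'
#' Runs [cluster_hotspots()] at each link distance in `d_list` (strictly
#' increasing) and summarizes how the scales relate: `n_clusters` per scale,
#' `fragmentation` (clusters at the largest scale that split into two or more
#' clusters at this scale) and `nonspecific` (clusters at this scale that
#' contain no cluster found at the smallest scale, i.e. appear only through
#' the looser linking).
#'
#' @param cells Cell table with `x_um`, `y_um`.
#' @param d_list Strictly increasing link distances in um. Default
#'   `c(30, 50, 75)`.
#' @inheritParams cluster_hotspots
#' @return List of class `multiscale_clusters`: `results` (one
#'   `hotspot_clusters` per scale, named by distance) and `summary` (tibble:
#'   `d_max`, `n_clusters`, `fragmentation`, `nonspecific`).
#' @export
multiscale_cluster <- function(cells, d_list = c(30, 50, 75), min_cells = 10,
                               label_seed = 1) {
  if (any(diff(d_list) <= 0)) stopf("d_list must be strictly increasing")
  results <- lapply(d_list, function(d)
    cluster_hotspots(cells, d_max = d, min_cells = min_cells,
                     label_seed = label_seed))
  names(results) <- as.character(d_list)
  k <- length(d_list)
  frag <- nonspec <- integer(k)
  if (nrow(tibble::as_tibble(cells)) > 0 && k > 1) {
    largest <- results[[k]]$cells$cluster_id
    smallest <- results[[1]]$cells$cluster_id
    for (i in seq_len(k)) {
      ci <- results[[i]]$cells$cluster_id
      # largest-scale clusters split into >= 2 clusters at scale i
      frag[i] <- sum(vapply(setdiff(unique(largest), 0L), function(L) {
        length(setdiff(unique(ci[largest == L]), 0L)) >= 2
      }, FALSE))
      # scale-i clusters containing no smallest-scale cluster
      nonspec[i] <- sum(vapply(setdiff(unique(ci), 0L), function(L) {
        !any(smallest[ci == L] > 0L)
      }, FALSE))
    }
  }
  structure(list(results = results,
                 summary = tibble::tibble(
                   d_max = d_list,
                   n_clusters = unname(vapply(results, function(r) nrow(r$summary), 0L)),
                   fragmentation = frag, nonspecific = nonspec)),
            class = "multiscale_clusters")
}

#' Treatment specificity of hotspot clusters by zone
#'
#' Reports where a population's clusters sit relative to the drug source. A
#' cluster is counted as present in a zone when at least `min_presence` of
#' its member cells lie in that zone (for compact clusters this coincides
#' with the zone of the cluster centroid; for clusters extending across zone
#' boundaries it records every zone the cluster genuinely occupies).
#' Clustering is treatment-specific when at least one cluster is present in
#' the proximal or border zone and none is present in the remote zone.
#'
#' @param result A `hotspot_clusters` whose `cells` carry a `zone` column
#'   (cluster on zoned cells, see [assign_zones()]).
#' @param proximal_zones Zones counting as drug-adjacent. Default
#'   `c("proximal", "border")`.
#' @param remote_zone Zone that must hold no cluster. Default `"remote"`.
#' @param min_presence Member count for a cluster to occupy a zone; defaults
#'   to the clustering's `min_cells`.
#' @return List of class `cluster_specificity`: `zone_counts` (named integer
#'   vector: clusters present per zone), `treatment_specific` (logical), and
#'   `clusters` (summary tibble with the majority `zone` of each cluster).
#' @export
cluster_specificity <- function(result, proximal_zones = c("proximal", "border"),
                                remote_zone = "remote",
                                min_presence = result$params$min_cells) {
  if (!"zone" %in% names(result$cells))
    stopf("clustered cells carry no 'zone' column; run assign_zones before clustering")
  summ <- result$summary
  all_zones <- unique(result$cells$zone)
  present <- matrix(FALSE, nrow(summ), length(all_zones),
                    dimnames = list(NULL, all_zones))
  zone <- character(nrow(summ))
  for (i in seq_len(nrow(summ))) {
    zs <- result$cells$zone[result$cells$cluster_id == summ$cluster_id[i]]
    tab <- sort(table(zs), decreasing = TRUE)
    zone[i] <- names(tab)[1]
    present[i, names(tab)] <- tab >= min_presence
  }
  summ$zone <- zone
  counts <- if (nrow(summ)) {
    cnt <- colSums(present)
    setNames(as.integer(cnt), names(cnt))
  } else setNames(integer(length(all_zones)), all_zones)
  specific <- any(present[, intersect(proximal_zones, all_zones)]) &&
    !any(present[, intersect(remote_zone, all_zones)])
  structure(list(zone_counts = counts, treatment_specific = specific,
                 clusters = summ),
            class = "cluster_specificity")
}
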
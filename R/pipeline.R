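# Orchestration of the two clustering passes: data cleaning (live cells vs
# everything else) and functional-group identification on the cleaned data.

# derive a bounded child seed from the master seed
.child_seed <- function(seed, k) (as.integer(seed) * 97L + k * 1009L) %% 2000000000L

# full-trait matrix of a particle table, with a recorded transform replayed
.samples_matrix <- function(samples, traits, transform_log) {
  parts <- samples$particles
  m <- trait_matrix(as.matrix(parts[, traits, drop = FALSE]),
                    particle_id = parts$particle_id,
                    sample_id = parts$sample_id)
  apply_trait_transform(m, transform_log)
}

#' Flag the clusters that correspond to live phytoplankton cells
#'
#' Live-cell clusters are primarily characterized by high pigment
#' fluorescence, particularly `FL.Red.Range` (the chlorophyll-a proxy).
#' Clusters whose median log10 `FL.Red.Range` exceeds that of the dimmest
#' reference cluster by at least `live_margin_log10` are flagged. The
#' reference is the dimmest cluster holding at least
#' `live_reference_min_fraction` of the data (the pooled non-cell cluster is
#' always large); tiny degenerate clusters — e.g. a handful of dead-flat
#' pulses whose median range is 0, with no finite log — can therefore not
#' hijack the reference, and clusters without a finite median are never
#' flagged. The config may instead name the live clusters explicitly
#' (`live_clusters_override`), the codified form of a manual inspection of
#' the cluster plots.
#'
#' @param model A `flowpeaks_model` from the cleaning pass.
#' @param summary The matching [cluster_summary()], which must include
#'   `FL.Red.Range` centroids.
#' @param cfg An [sfcm_config()].
#' @return Integer vector of live cluster ids (possibly empty).
#' @export
flag_live_clusters <- function(model, summary, cfg = sfcm_config()) {
  if (!is.null(cfg$live_clusters_override)) {
    return(as.integer(cfg$live_clusters_override))
  }
  if (!"FL.Red.Range" %in% colnames(summary$centroids)) {
    stop("cluster summary lacks FL.Red.Range centroids")
  }
  med <- summary$centroids[, "FL.Red.Range"]
  if (!"FL.Red.Range" %in% summary$transform_log) {
    med <- suppressWarnings(log10(med))
  }
  finite <- is.finite(med)
  if (!any(finite)) stop("no cluster has a finite FL.Red.Range centroid")
  ref_pool <- finite & summary$fractions >= cfg$live_reference_min_fraction
  if (!any(ref_pool)) ref_pool <- finite
  flagged <- which(finite & med >= min(med[ref_pool]) + cfg$live_margin_log10)
  as.integer(rownames(summary$centroids)[flagged])
}

#' Data-cleaning pass: separate live cells from other signals
#'
#' Runs the full cleaning protocol on a field series: (1) log10-transform
#' and correlation-prune the lab training traits; (2) rank trait importance
#' for the live-vs-other contrast with a large random forest and keep the
#' top `n_top_clean`; (3) pool an equal-per-sample random subset of the
#' field data; (4) cluster the subset on the selected traits with the
#' density-peak clusterer; (5) flag the high-fluorescence clusters as live;
#' (6) train a classification forest on the cluster labels; (7) classify
#' every particle in every sample and retain those in live clusters.
#'
#' @param samples An [sfcm_samples()] field series.
#' @param train An `sfcm_training` lab training set (live/other labels).
#' @param cfg An [sfcm_config()].
#' @return Object of class `sfcm_cleaning`: `live_clusters`, per-particle
#'   `particles` table (`sample_id`, `particle_id`, `cluster`, `retained`),
#'   per-sample `live_fraction`, the fitted `forest` and `cluster_model`,
#'   the importance `ranking`, selected `traits`, the training
#'   `transform_log`, pruning record and an `audit` log of stage sizes.
#' @export
run_cleaning <- function(samples, train, cfg = sfcm_config()) {
  stopifnot(inherits(samples, "sfcm_samples"), inherits(train, "sfcm_training"))
  seed <- cfg$random_seed
  audit <- audit_empty()

  mt <- log_transform_eligible(train$matrix)
  pr <- prune_correlated(mt, cfg$correlation_threshold)
  audit <- audit_add(audit, "prune_correlated(train)",
                     ncol(mt$values), ncol(pr$matrix$values))
  ranking <- rank_importance(labeled_training(pr$matrix, train$labels$class),
                             cfg$trees_importance, .child_seed(seed, 1L))
  top <- select_top_k(ranking, cfg$n_top_clean)
  sfcm_log("cleaning traits: %s", paste(top, collapse = ", "))

  sub <- pooled_subset(samples, cfg$subset_size, .child_seed(seed, 2L))
  audit <- audit_add(audit, "pooled_subset(raw)", nrow(samples$particles),
                     nrow(sub$values))
  sub_t <- apply_trait_transform(sub, mt$transform_log)
  cp <- cfg$cluster_params
  cp$seed <- .child_seed(seed, 3L)
  model <- flowpeaks_cluster(tm_select(sub_t, top), cp)
  summ <- cluster_summary(model, sub_t)
  live <- flag_live_clusters(model, summ, cfg)
  if (length(live) == 0L) {
    stop("pipeline error: no cluster flagged as live cells; review ",
         "live_margin_log10 or supply live_clusters_override")
  }
  sfcm_log("%d of %d clusters flagged live", length(live), model$n_clusters)

  forest <- fit_classifier(labeled_training(tm_select(sub_t, top), model$labels),
                           cfg$trees_classify, .child_seed(seed, 4L))

  full <- .samples_matrix(samples, top, mt$transform_log)
  cluster <- as.integer(as.character(predict(forest, full)))
  retained <- cluster %in% live
  particles <- data.frame(sample_id = full$sample_id,
                          particle_id = full$particle_id,
                          cluster = cluster, retained = retained,
                          stringsAsFactors = FALSE)
  audit <- audit_add(audit, "retain_live", nrow(particles), sum(retained))

  tab <- table(factor(particles$sample_id, levels = sample_ids(samples)))
  ret <- table(factor(particles$sample_id[retained],
                      levels = sample_ids(samples)))
  live_fraction <- data.frame(sample_id = names(tab),
                              n_particles = as.integer(tab),
                              n_retained = as.integer(ret),
                              live_fraction = ifelse(as.integer(tab) > 0,
                                                     as.integer(ret) / as.integer(tab), 0),
                              stringsAsFactors = FALSE)

  structure(list(live_clusters = live, particles = particles,
                 live_fraction = live_fraction, forest = forest,
                 cluster_model = model, summary = summ, ranking = ranking,
                 traits = top, transform_log = mt$transform_log,
                 pruned = pr$removed, audit = audit),
            class = "sfcm_cleaning")
}

#' @export
print.sfcm_cleaning <- function(x, ...) {
  cat(sprintf(paste0("sfcm_cleaning: %d clusters (%s live), OOB error %.4f, ",
                     "pooled live fraction %.4f\n"),
              x$cluster_model$n_clusters,
              paste(x$live_clusters, collapse = ","),
              x$forest$oob_error,
              sum(x$live_fraction$n_retained) / sum(x$live_fraction$n_particles)))
  invisible(x)
}

#' Assign abundant clusters to phytoplankton functional groups
#'
#' Ordered rule evaluation on the clusters at or above
#' `min_group_fraction`:
#' 1. the cluster with the lowest `Red1Red2.ratio`, if below
#'    `cyano_ratio_ceiling`, is cyanobacteria (phycocyanin fluoresces
#'    strongly under the 642 nm laser);
#' 2. of the rest, the cluster jointly lowest in `X2.FL.Red.Gradient` and
#'    `FL.Red.First` (lowest rank sum) is cryptophytes;
#' 3. of the rest, the cluster with the highest `Red1Red2.ratio` (with its
#'    `FL.Red.Range` recorded in the rationale) is green algae;
#' 4. the most abundant remaining cluster is chrysophytes.
#'
#' Remaining abundant clusters and all clusters below the fraction threshold
#' are `unassigned`. Ties are broken toward the lower cluster id with a
#' warning. Rules 2 and 3 are skipped when no clusters remain for them.
#'
#' @param summary A [cluster_summary()] containing `Red1Red2.ratio`,
#'   `X2.FL.Red.Gradient`, `FL.Red.First` and `FL.Red.Range` centroids.
#' @param cfg An [sfcm_config()].
#' @return data.frame of class `group_assignment`: `cluster`, `group`,
#'   `fraction`, `rationale`.
#' @export
assign_groups <- function(summary, cfg = sfcm_config()) {
  need <- c("Red1Red2.ratio", "X2.FL.Red.Gradient", "FL.Red.First",
            "FL.Red.Range")
  if (!all(need %in% colnames(summary$centroids_natural))) {
    stop("cluster summary lacks trait(s): ",
         paste(setdiff(need, colnames(summary$centroids_natural)),
               collapse = ", "))
  }
  cl <- as.integer(rownames(summary$centroids_natural))
  frac <- as.numeric(summary$fractions)
  cent <- summary$centroids_natural
  out <- data.frame(cluster = cl, group = "unassigned", fraction = frac,
                    rationale = sprintf("fraction %.3f < %.3f", frac,
                                        cfg$min_group_fraction),
                    stringsAsFactors = FALSE)
  abundant <- which(frac >= cfg$min_group_fraction)
  out$rationale[abundant] <- "abundant cluster left unassigned by the rules"
  remaining <- abundant

  pick <- function(score, label) {
    best <- remaining[score[remaining] == min(score[remaining])]
    if (length(best) > 1L) {
      warning("tie for ", label, " between clusters ",
              paste(cl[best], collapse = ", "), "; lower id wins")
      best <- best[which.min(cl[best])]
    }
    best
  }

  # rule 1: cyanobacteria by low Red1Red2.ratio
  if (length(remaining)) {
    i <- pick(cent[, "Red1Red2.ratio"], "cyanobacteria")
    if (cent[i, "Red1Red2.ratio"] < cfg$cyano_ratio_ceiling) {
      out$group[i] <- "cyanobacteria"
      out$rationale[i] <- sprintf(
        "lowest Red1Red2.ratio (%.3g < ceiling %.3g): phycocyanin-rich",
        cent[i, "Red1Red2.ratio"], cfg$cyano_ratio_ceiling)
      remaining <- setdiff(remaining, i)
    }
  }
  # rule 2: cryptophytes by jointly low X2 gradient and FL.Red.First
  if (length(remaining) >= 2L) {
    rs <- rank(cent[remaining, "X2.FL.Red.Gradient"]) +
      rank(cent[remaining, "FL.Red.First"])
    score <- rep(Inf, length(cl)); score[remaining] <- rs
    i <- pick(score, "cryptophytes")
    out$group[i] <- "cryptophytes"
    out$rationale[i] <- sprintf(
      "jointly lowest X2.FL.Red.Gradient (%.3g) and FL.Red.First (%.3g), intermediate ratio %.3g",
      cent[i, "X2.FL.Red.Gradient"], cent[i, "FL.Red.First"],
      cent[i, "Red1Red2.ratio"])
    remaining <- setdiff(remaining, i)
  }
  # rule 3: green algae by highest remaining ratio
  if (length(remaining) >= 2L) {
    i <- pick(-cent[, "Red1Red2.ratio"], "green algae")
    out$group[i] <- "green_algae"
    out$rationale[i] <- sprintf(
      "highest remaining Red1Red2.ratio (%.3g), FL.Red.Range %.3g",
      cent[i, "Red1Red2.ratio"], cent[i, "FL.Red.Range"])
    remaining <- setdiff(remaining, i)
  }
  # rule 4: chrysophytes as the most abundant remaining cluster
  if (length(remaining)) {
    i <- pick(-frac, "chrysophytes")
    out$group[i] <- "chrysophytes"
    out$rationale[i] <- sprintf(
      "most abundant remaining cluster (fraction %.3f)", frac[i])
  }
  class(out) <- c("group_assignment", "data.frame")
  out
}

#' Functional-group identification pass
#'
#' Repeats the cleaning procedure on the cleaned (live-cell) data: trait
#' importance is re-ranked for the between-group contrast on the live lab
#' training rows, the top `n_top_group` traits are clustered over a pooled
#' subset of the retained field particles, abundant clusters are assigned to
#' functional groups by [assign_groups()], and a classification forest
#' labels every retained particle.
#'
#' @param samples The original [sfcm_samples()] field series.
#' @param cleaning The [run_cleaning()] result.
#' @param train An `sfcm_training`; only its live rows are used.
#' @param cfg An [sfcm_config()].
#' @return Object of class `sfcm_grouping`: `assignment`, per-particle
#'   `particles` table (`sample_id`, `particle_id`, `cluster`, `group`),
#'   `forest`, `cluster_model`, `summary`, `ranking`, `traits`, `audit`.
#' @export
run_grouping <- function(samples, cleaning, train, cfg = sfcm_config()) {
  stopifnot(inherits(cleaning, "sfcm_cleaning"), inherits(train, "sfcm_training"))
  seed <- cfg$random_seed
  audit <- audit_empty()

  live_rows <- train$labels$class == "live"
  if (!any(live_rows)) stop("training set has no live rows")
  mt_all <- trait_matrix(train$matrix$values[live_rows, , drop = FALSE],
                         particle_id = train$matrix$particle_id[live_rows])
  mt <- log_transform_eligible(mt_all)
  pr <- prune_correlated(mt, cfg$correlation_threshold)
  audit <- audit_add(audit, "prune_correlated(live train)",
                     ncol(mt$values), ncol(pr$matrix$values))
  ranking <- rank_importance(labeled_training(pr$matrix,
                                              train$labels$group[live_rows]),
                             cfg$trees_importance, .child_seed(seed, 11L))
  top <- select_top_k(ranking, cfg$n_top_group)
  sfcm_log("grouping traits: %s", paste(top, collapse = ", "))

  keep <- cleaning$particles$retained
  cleaned <- sfcm_samples(samples$particles[keep, , drop = FALSE],
                          samples$meta, check_concentration = FALSE)
  sub <- suppressWarnings(pooled_subset(cleaned, cfg$subset_size,
                                        .child_seed(seed, 12L)))
  audit <- audit_add(audit, "pooled_subset(cleaned)", nrow(cleaned$particles),
                     nrow(sub$values))
  sub_t <- apply_trait_transform(sub, mt$transform_log)
  cp <- cfg$cluster_params
  cp$seed <- .child_seed(seed, 13L)
  model <- flowpeaks_cluster(tm_select(sub_t, top), cp)
  summ <- cluster_summary(model, sub_t)
  abundant <- sum(summ$fractions >= cfg$min_group_fraction)
  if (abundant < 2L) {
    warning("fewer than 2 abundant clusters; single-group output")
  }
  assignment <- assign_groups(summ, cfg)

  forest <- fit_classifier(labeled_training(tm_select(sub_t, top), model$labels),
                           cfg$trees_classify, .child_seed(seed, 14L))
  full <- .samples_matrix(cleaned, top, mt$transform_log)
  cluster <- as.integer(as.character(predict(forest, full)))
  group <- assignment$group[match(cluster, assignment$cluster)]
  particles <- data.frame(sample_id = full$sample_id,
                          particle_id = full$particle_id,
                          cluster = cluster, group = group,
                          stringsAsFactors = FALSE)
  audit <- audit_add(audit, "assign_groups", nrow(particles),
                     sum(group != "unassigned"))

  structure(list(assignment = assignment, particles = particles,
                 forest = forest, cluster_model = model, summary = summ,
                 ranking = ranking, traits = top,
                 transform_log = mt$transform_log, audit = audit),
            class = "sfcm_grouping")
}

#' @export
print.sfcm_grouping <- function(x, ...) {
  cat(sprintf("sfcm_grouping: %d clusters, OOB error %.4f\n",
              x$cluster_model$n_clusters, x$forest$oob_error))
  ab <- x$assignment[x$assignment$group != "unassigned", ]
  for (i in seq_len(nrow(ab))) {
    cat(sprintf("  cluster %d -> %s (%.1f%%)\n", ab$cluster[i], ab$group[i],
                100 * ab$fraction[i]))
  }
  invisible(x)
}
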
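# Evaluation harness: truth matching, confusion reports, and the
# nearest-neighbor confusion sweep.

#' Score classified particles against ground truth
#'
#' Greedy nearest matching of predictions to truth centers within
#' `match_tolerance` (closest pairs first, each record used once).
#' Accuracy is the fraction of truth particles matched by a prediction
#' of the correct class; unmatched truth count as misses, unmatched
#' predictions as false positives.
#'
#' @param truth Truth table (`tomo_volume$truth`).
#' @param predicted Data frame from [classify_volume()].
#' @param match_tolerance Maximum center distance for a match, Angstrom
#'   (default 20, two voxels at the 10 Angstrom voxel size).
#' @return An object of class `confusion_report`: list with `accuracy`,
#'   `per_class` (precision/recall per class), `n_truth`, `n_predicted`,
#'   `n_matched`, `misses`, `false_positives`, `match_tolerance`.
#' @export
evaluate_classification <- function(truth, predicted, match_tolerance = 20) {
  if (match_tolerance <= 0) stop("match_tolerance must be positive")
  nt <- nrow(truth); np <- nrow(predicted)
  matched_t <- logical(nt); matched_p <- logical(np)
  correct <- 0L
  class_stats <- list(
    monomer = c(tp = 0L, pred = 0L, truth = sum(truth$class == "monomer")),
    dimer = c(tp = 0L, pred = 0L, truth = sum(truth$class == "dimer"))
  )
  for (cl in names(class_stats)) {
    class_stats[[cl]]["pred"] <- sum(predicted$class == cl)
  }
  if (nt > 0 && np > 0) {
    dm <- outer(seq_len(np), seq_len(nt), Vectorize(function(p, t) {
      sqrt((predicted$x[p] - truth$x[t])^2 +
             (predicted$y[p] - truth$y[t])^2 +
             (predicted$z[p] - truth$z[t])^2)
    }))
    ord <- order(dm)
    for (k in ord) {
      if (dm[k] > match_tolerance) break
      p <- (k - 1) %% np + 1
      t <- (k - 1) %/% np + 1
      if (matched_p[p] || matched_t[t]) next
      matched_p[p] <- matched_t[t] <- TRUE
      if (predicted$class[p] == truth$class[t]) {
        correct <- correct + 1L
        cl <- truth$class[t]
        class_stats[[cl]]["tp"] <- class_stats[[cl]]["tp"] + 1L
      }
    }
  }
  per_class <- lapply(class_stats, function(s) {
    c(precision = if (s["pred"] > 0) unname(s["tp"] / s["pred"]) else NA_real_,
      recall = if (s["truth"] > 0) unname(s["tp"] / s["truth"]) else NA_real_)
  })
  structure(
    list(accuracy = if (nt > 0) correct / nt else NA_real_,
         per_class = per_class,
         n_truth = nt, n_predicted = np, n_matched = sum(matched_t),
         misses = sum(!matched_t), false_positives = sum(!matched_p),
         match_tolerance = match_tolerance),
    class = "confusion_report"
  )
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("Classification accuracy: %.3f (%d truth, %d predicted, tol %g A)\n",
              x$accuracy, x$n_truth, x$n_predicted, x$match_tolerance))
  for (cl in names(x$per_class)) {
    cat(sprintf("  %-8s precision %.3f  recall %.3f\n", cl,
                x$per_class[[cl]]["precision"], x$per_class[[cl]]["recall"]))
  }
  invisible(x)
}

# Build the truth list for one confusion-sweep scene: n_pairs monomer
# pairs at exactly `nn` apart plus n_dimers true dimers, placed without
# overlap between groups.
sweep_truths <- function(spec, nn, n_pairs, n_dimers) {
  extent <- (spec$shape - 1) * spec$pixel_size
  margin <- spec$monomer_radius + max(nn, spec$dimer_separation_mean) / 2 + 10
  group_min <- max(spec$min_center_distance, nn + 2 * spec$monomer_radius)
  centers <- matrix(numeric(0), ncol = 3)
  place <- function() {
    for (try in 1:1000) {
      cand <- stats::runif(3, margin, extent - margin)
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= group_min) {
        centers <<- rbind(centers, cand)
        return(cand)
      }
    }
    stop("could not place sweep scene under spacing constraints")
  }
  truths <- list()
  id <- 0L
  for (i in seq_len(n_pairs)) {
    c0 <- place()
    ax <- drop(random_unit_vectors(1))
    for (s in c(-1, 1)) {
      id <- id + 1L
      truths[[id]] <- particle_truth(id, "monomer", c0 + s * nn / 2 * ax)
    }
  }
  for (i in seq_len(n_dimers)) {
    c0 <- place()
    id <- id + 1L
    truths[[id]] <- particle_truth(id, "dimer", c0,
                                   axis = drop(random_unit_vectors(1)),
                                   separation = draw_separation(spec))
  }
  truths
}

#' Classification accuracy versus monomer nearest-neighbor distance
#'
#' For each nearest-neighbor distance in `nn_grid`, generates `reps`
#' scenes containing monomer pairs placed at exactly that distance plus
#' true dimers, runs the full detection/classification pipeline, and
#' reports the mean classification accuracy with its Monte-Carlo
#' standard error. As the monomer spacing approaches the dimer
#' separation window, monomer pairs become indistinguishable from
#' dimers and accuracy collapses.
#'
#' @param spec A `scene_spec` (its seed is combined with the rep index).
#' @param nn_grid Nearest-neighbor distances to probe, Angstrom.
#' @param reps Scenes per grid point (default 5).
#' @param n_pairs Monomer pairs per scene (default 6).
#' @param n_dimers True dimers per scene (default 6).
#' @param ... Passed to [classify_volume()].
#' @return Data frame: `nn`, `accuracy`, `se`, `dimer_false_rate` (the
#'   fraction of monomer pairs called dimers).
#' @export
nn_confusion_sweep <- function(spec, nn_grid, reps = 5L, n_pairs = 6L,
                               n_dimers = 6L, ...) {
  stopifnot(inherits(spec, "scene_spec"), all(nn_grid > 0), reps >= 1)
  rows <- lapply(nn_grid, function(nn) {
    acc <- fp <- numeric(reps)
    for (r in seq_len(reps)) {
      set.seed(spec$seed + 1000L * r + round(nn))
      truths <- sweep_truths(spec, nn, n_pairs, n_dimers)
      vol <- render_scene(spec, truths)
      pred <- classify_volume(vol, ...)
      rep_report <- evaluate_classification(vol$truth, pred)
      acc[r] <- rep_report$accuracy
      # monomer-pair -> dimer confusion: predicted dimers whose midpoint
      # matches no true dimer
      n_pred_dimer <- sum(pred$class == "dimer")
      true_dimer_tp <- round(rep_report$per_class$dimer["recall"] *
                               sum(vol$truth$class == "dimer"))
      fp[r] <- max(0, n_pred_dimer - true_dimer_tp) / n_pairs
    }
    data.frame(nn = nn, accuracy = mean(acc),
               se = stats::sd(acc) / sqrt(reps),
               dimer_false_rate = mean(fp))
  })
  do.call(rbind, rows)
}
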
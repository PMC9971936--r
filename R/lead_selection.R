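#' Configuration for the forward stepwise lead-subset search
#'
#' @param k_folds cross-validation folds per candidate subset (default 5).
#' @param metric score to optimise (`"F1"`).
#' @param alpha significance level for the descriptive Welch t-tests
#'   (default 0.05).
#' @param max_subset largest subset size to consider (default: all leads).
#' @param fusion how a multi-lead candidate subset enters the classifier:
#'   `"late"` (default) trains one shared three-channel network on every
#'   (record, lead) image of the subset and averages predicted class
#'   probabilities over the subset's leads per record; `"stack"`
#'   concatenates the per-lead images along the channel axis (see
#'   [stack_leads()]); `"average"` averages the per-lead images pixelwise.
#' @param seed integer seed; fixes both fold assignment (identical for all
#'   candidates within a phase, for fair comparison) and model seeds.
#' @return a list of class `selection_config`.
#' @export
selection_config <- function(k_folds = 5L, metric = "F1", alpha = 0.05,
                             max_subset = NULL,
                             fusion = c("late", "stack", "average"),
                             seed = 1L) {
  fusion <- match.arg(fusion)
  stopifnot(k_folds >= 2, alpha > 0, alpha < 1, metric == "F1")
  structure(list(k_folds = as.integer(k_folds), metric = metric,
                 alpha = alpha, max_subset = max_subset, fusion = fusion,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Precompute per-lead recurrence images for a record set
#'
#' Converts every requested lead of every record into a recurrence-plot
#' image once, so that scoring many lead subsets only has to stack cached
#' channels.
#'
#' @param records list of [ecg_record()].
#' @param rp_cfg an [rp_config()].
#' @param prep_cfg a [prep_config()]; its `target_fs`/`segment_len` define
#'   the segment fed into imaging.
#' @param leads lead names to convert (default: all leads of the first
#'   record).
#' @return a list of class `rp_dataset` with `images[[record]][[lead]]`
#'   pixel arrays, `labels`, `record_ids`, `leads`.
#' @export
prepare_rp_dataset <- function(records, rp_cfg = rp_config(),
                               prep_cfg = prep_config(),
                               leads = NULL) {
  if (is.null(leads)) leads <- records[[1]]$lead_names
  images <- lapply(records, function(rec) {
    per_lead <- lapply(leads, function(ld) {
      ecg_to_rp(lead_segment(rec, ld, prep_cfg), cfg = rp_cfg)$pixels
    })
    names(per_lead) <- leads
    per_lead
  })
  structure(list(images = images,
                 labels = vapply(records, function(r) r$label[1],
                                 character(1)),
                 record_ids = vapply(records, function(r) r$record_id,
                                     character(1)),
                 leads = leads, size = rp_cfg$size),
            class = "rp_dataset")
}

#' Assemble multi-channel inputs for a lead subset
#'
#' Stacks the cached per-lead images of each selected record along the
#' channel axis (see [stack_leads()]), yielding the input list used to
#' train or evaluate a multi-lead classifier.
#'
#' @param rpdata a [prepare_rp_dataset()] result.
#' @param leads lead names to include, in order.
#' @param idx record indices (default: all).
#' @return list of `(H, W, 3k)` arrays, one per selected record.
#' @export
stack_subset <- function(rpdata, leads, idx = seq_along(rpdata$images)) {
  lapply(rpdata$images[idx], function(per_lead) {
    stack_leads(per_lead[leads])
  })
}

average_subset <- function(rpdata, leads, idx = seq_along(rpdata$images)) {
  lapply(rpdata$images[idx], function(per_lead) {
    Reduce(`+`, per_lead[leads]) / length(leads)
  })
}

#' Model factory for the shallow parallel CNN
#'
#' Returns a factory compatible with [crossval()] and the stepwise search:
#' calling it with a channel count yields an object whose `$fit` trains a
#' fresh network and whose `$predict` returns hard labels.
#'
#' @param base_cfg a [model_config()] whose `in_channels` is overridden per
#'   call (default the `"fast"` profile, sized for repeated fitting).
#' @param step_budget optional fixed number of optimizer steps per fit;
#'   when set, the epoch count is derived from it and the training-set
#'   size, so candidates with more images (e.g. late-fusion subsets) train
#'   for proportionally fewer epochs at equal optimization effort.
#' @return function `(in_channels, seed)` returning a list with `fit`,
#'   `predict` and `prob` closures.
#' @export
parnet_factory <- function(base_cfg = parnet_profile("fast"),
                           step_budget = NULL) {
  force(base_cfg)
  force(step_budget)
  function(in_channels, seed = base_cfg$seed) {
    cfg <- utils::modifyList(base_cfg,
                             list(in_channels = as.integer(in_channels),
                                  seed = as.integer(seed %% 2147483000)))
    class(cfg) <- "model_config"
    env <- new.env(parent = emptyenv())
    env$model <- NULL
    list(
      fit = function(x, labels) {
        epochs <- if (is.null(step_budget)) cfg$epochs else
          max(3L, ceiling(step_budget / ceiling(length(labels) /
                                                  cfg$batch_size)))
        env$model <- train_model(build_model(cfg), x, labels,
                                 epochs = epochs)
        invisible(NULL)
      },
      predict = function(x) predict_labels(env$model, x),
      prob = function(x) predict_model(env$model, x),
      model = function() env$model
    )
  }
}

#' Ridge-logistic baseline factory on raw pixels
#'
#' Fits a ridge-penalized logistic regression on flattened image pixels
#' (via glmnet). Serves as the linear reference the convolutional model
#' must beat to demonstrate non-trivial feature extraction.
#'
#' @param lambda ridge penalty (default 1e-2).
#' @return a factory with the same interface as [parnet_factory()].
#' @export
logistic_pixel_factory <- function(lambda = 1e-2) {
  function(in_channels, seed = 1L) {
    env <- new.env(parent = emptyenv())
    flatten <- function(x) {
      do.call(rbind, lapply(x, function(a) {
        as.vector(if (inherits(a, "rp_image")) a$pixels else a)
      }))
    }
    list(
      fit = function(x, labels) {
        env$fit <- glmnet::glmnet(flatten(x),
                                  factor(labels, c("NSR", "AF")),
                                  family = "binomial", alpha = 0,
                                  lambda = lambda)
        invisible(NULL)
      },
      predict = function(x) {
        p <- stats::predict(env$fit, flatten(x), type = "response")
        ifelse(p[, 1] > 0.5, "AF", "NSR")
      },
      prob = function(x) {
        p <- stats::predict(env$fit, flatten(x), type = "response")[, 1]
        cbind(AF = p, NSR = 1 - p)
      }
    )
  }
}

fold_f1 <- function(truth, pred) {
  m <- metrics(confusion(truth, pred))
  if (is.na(m$f1)) 0 else m$f1
}

#' Cross-validated F1 scores of one lead subset
#'
#' Scores `leads` with `cfg$k_folds`-fold stratified record-disjoint
#' cross-validation. The fold assignment depends only on `cfg$seed`, so
#' every candidate subset within a phase is scored on identical folds.
#'
#' @param leads character vector of lead names.
#' @param rpdata a [prepare_rp_dataset()] result.
#' @param model_factory see [parnet_factory()].
#' @param cfg a [selection_config()].
#' @return numeric vector of per-fold F1 scores (AF positive).
#' @export
score_subset <- function(leads, rpdata, model_factory = parnet_factory(),
                         cfg = selection_config()) {
  stopifnot(length(leads) >= 1, all(leads %in% rpdata$leads))
  fusion <- if (is.null(cfg$fusion)) "late" else cfg$fusion
  fold <- make_folds(rpdata$labels, cfg$k_folds, cfg$seed)
  scores <- numeric(cfg$k_folds)
  for (f in seq_len(cfg$k_folds)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (length(unique(rpdata$labels[te])) < 2) {
      stop("fold ", f, " contains a single class")
    }
    pred <- if (fusion == "late") {
      fit_predict_late(leads, rpdata, tr, te, model_factory,
                       cfg$seed * 131L + f)
    } else {
      build <- if (fusion == "stack") stack_subset else average_subset
      in_ch <- if (fusion == "stack") 3L * length(leads) else 3L
      mdl <- model_factory(in_ch, seed = cfg$seed * 131L + f)
      mdl$fit(build(rpdata, leads, tr), rpdata$labels[tr])
      mdl$predict(build(rpdata, leads, te))
    }
    scores[f] <- fold_f1(rpdata$labels[te], pred)
  }
  scores
}

# late fusion: one shared 3-channel model fitted on each (record, lead)
# image of the subset; test records are labelled by the subset-mean of the
# per-lead AF probabilities
fit_predict_late <- function(leads, rpdata, tr, te, model_factory, seed) {
  xs <- vector("list", length(tr) * length(leads))
  ys <- character(length(xs))
  k <- 0L
  for (i in tr) {
    for (ld in leads) {
      k <- k + 1L
      xs[[k]] <- rpdata$images[[i]][[ld]]
      ys[k] <- rpdata$labels[i]
    }
  }
  mdl <- model_factory(3L, seed = seed)
  mdl$fit(xs, ys)
  if (is.null(mdl$prob)) stop("late fusion requires a factory with $prob")
  vapply(te, function(i) {
    ps <- vapply(leads, function(ld) {
      mdl$prob(list(rpdata$images[[i]][[ld]]))[1, "AF"]
    }, numeric(1))
    if (mean(ps) > 0.5) "AF" else "NSR"
  }, character(1))
}

#' Welch two-sample t-test p-value
#'
#' Two-sided unequal-variance t-test between two score groups. When both
#' groups are constant the statistic is undefined; by convention the
#' p-value is 1 for equal means (no evidence of difference) and 0
#' otherwise.
#'
#' @param scores_a,scores_b numeric vectors, each of length >= 2.
#' @return p-value in `[0, 1]`.
#' @export
two_sample_t_test <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) >= 2, length(scores_b) >= 2)
  if (stats::sd(scores_a) == 0 && stats::sd(scores_b) == 0) {
    return(if (isTRUE(all.equal(mean(scores_a), mean(scores_b)))) 1 else 0)
  }
  stats::t.test(scores_a, scores_b, var.equal = FALSE)$p.value
}

#' Forward stepwise search for a minimal informative lead subset
#'
#' Phase 1 scores every single lead and seeds the subset with the best
#' mean cross-validated F1. Each later phase scores the incumbent subset
#' extended by each remaining lead and accepts the best extension only if
#' its mean F1 strictly exceeds the incumbent's; the search stops at the
#' first phase with no strict improvement (or at `max_subset`). Ties are
#' broken by canonical lead order. Welch t-test p-values comparing each
#' phase's best candidate against the alternatives are reported
#' descriptively; they do not drive the stopping rule.
#'
#' @inheritParams score_subset
#' @return object of class `selection_report`: list with `phases` (each
#'   phase a list with a `candidates` data frame of per-fold scores, the
#'   chosen candidate and its p-values), `chosen_subset`, `mean_f1`,
#'   `stopped_reason`.
#' @export
forward_stepwise <- function(rpdata, model_factory = parnet_factory(),
                             cfg = selection_config()) {
  leads <- rpdata$leads
  if (length(leads) < 2) stop("need at least 2 leads to search over")
  max_subset <- if (is.null(cfg$max_subset)) length(leads) else
    min(cfg$max_subset, length(leads))
  chosen <- character(0)
  best_mean <- -Inf
  best_scores <- NULL
  phases <- list()
  stopped <- NULL
  while (length(chosen) < max_subset) {
    remaining <- setdiff(leads, chosen)
    # a perfect incumbent cannot be strictly improved; stop without scoring
    if (best_mean >= 1) {
      stopped <- "no_improvement"
      break
    }
    cand_scores <- lapply(remaining, function(ld) {
      score_subset(c(chosen, ld), rpdata, model_factory, cfg)
    })
    means <- vapply(cand_scores, mean, numeric(1))
    best_i <- order(-means, match(remaining, leads))[1]
    cand_df <- data.frame(lead_added = remaining,
                          mean_f1 = means,
                          t(vapply(cand_scores, identity,
                                   numeric(cfg$k_folds))))
    names(cand_df)[-(1:2)] <- paste0("fold", seq_len(cfg$k_folds))
    p_vs_best <- vapply(seq_along(remaining), function(i) {
      if (i == best_i) NA_real_ else
        two_sample_t_test(cand_scores[[best_i]], cand_scores[[i]])
    }, numeric(1))
    cand_df$p_vs_best <- p_vs_best
    p_vs_incumbent <- if (is.null(best_scores)) NA_real_ else
      two_sample_t_test(cand_scores[[best_i]], best_scores)
    phases[[length(phases) + 1]] <- list(
      phase = length(chosen) + 1L,
      incumbent = chosen,
      candidates = cand_df,
      best_lead = remaining[best_i],
      best_mean_f1 = means[best_i],
      p_vs_incumbent = p_vs_incumbent)
    if (means[best_i] > best_mean) {
      chosen <- c(chosen, remaining[best_i])
      best_mean <- means[best_i]
      best_scores <- cand_scores[[best_i]]
    } else {
      stopped <- "no_improvement"
      break
    }
  }
  if (is.null(stopped)) stopped <- "max_subset"
  structure(list(phases = phases, chosen_subset = chosen,
                 mean_f1 = best_mean, fold_scores = best_scores,
                 stopped_reason = stopped, config = cfg),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> chosen subset: {%s}  mean F1 %.4f  (%s)\n",
              paste(x$chosen_subset, collapse = ", "), x$mean_f1,
              x$stopped_reason))
  for (ph in x$phases) {
    cat(sprintf("  phase %d: best +%s  mean F1 %.4f\n", ph$phase,
                ph$best_lead, ph$best_mean_f1))
  }
  invisible(x)
}

#' Serialize a selection report to JSON
#' @param report a `selection_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  jsonlite::write_json(
    list(chosen_subset = report$chosen_subset, mean_f1 = report$mean_f1,
         stopped_reason = report$stopped_reason,
         phases = lapply(report$phases, function(ph) {
           list(phase = ph$phase, incumbent = ph$incumbent,
                best_lead = ph$best_lead, best_mean_f1 = ph$best_mean_f1,
                p_vs_incumbent = ph$p_vs_incumbent,
                candidates = ph$candidates)
         })),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Bar chart of per-phase candidate F1 scores
#'
#' One panel per search phase, bars ordered by canonical lead order, the
#' accepted lead highlighted.
#'
#' @param report a `selection_report`.
#' @param path optional PNG output path; when given the plot is written
#'   there.
#' @return `report`, invisibly.
#' @export
plot_selection_report <- function(report, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 300 * length(report$phases))
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(length(report$phases), 1),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old), add = TRUE)
  for (ph in report$phases) {
    df <- ph$candidates
    cols <- ifelse(df$lead_added == ph$best_lead, "firebrick", "grey60")
    ylim_lo <- max(0, min(df$mean_f1) - 0.05)
    graphics::barplot(df$mean_f1, names.arg = df$lead_added, col = cols,
                      ylim = c(ylim_lo, 1), xpd = FALSE,
                      ylab = "mean CV F1",
                      main = sprintf("phase %d%s", ph$phase,
                                     if (length(ph$incumbent))
                                       paste0("  (seed: ",
                                              paste(ph$incumbent,
                                                    collapse = "+"), ")")
                                     else ""))
  }
  invisible(report)
}
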
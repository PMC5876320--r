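#' @importFrom dplyr group_by summarise mutate arrange bind_rows n
#' @importFrom rlang .data
NULL

new_evaluation_report <- function(task, rows, atlas_id) {
  summary <- rows |>
    group_by(.data$template, .data$unit) |>
    summarise(dplyr::across(dplyr::any_of(c("dice", "msd_um", "hausdorff_um")),
                            ~ mean(.x, na.rm = TRUE)), .groups = "drop") |>
    group_by(.data$template) |>
    summarise(dplyr::across(dplyr::any_of(c("dice", "msd_um", "hausdorff_um")),
                            list(mean = ~ mean(.x, na.rm = TRUE),
                                 sem = ~ safe_sem(.x))),
              n_units = n(), .groups = "drop")
  structure(list(task = task, rows = rows, summary = summary,
                 atlas_id = atlas_id),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: %s task> %d rows\n", x$task, nrow(x$rows)))
  print(x$summary)
  invisible(x)
}

atlas_regions <- function(atl) {
  sort(setdiff(unique(as.vector(atl$labels$values)), 0L))
}

#' Evaluate an atlas on the segmentation task
#'
#' Registers every test subject onto the atlas, warps the atlas labels into
#' each subject's native space through the inverse field, and scores the
#' propagated labels against the subject's own expert labels with Dice, mean
#' symmetric surface distance and symmetric Hausdorff distance per region —
#' all computed in the subject's space, where absolute distances are
#' meaningful.
#'
#' @param atl an [atlas()].
#' @param tests list of [subject_brain()]s with label images.
#' @param cfg a [reg_config()].
#' @param transforms optional pre-computed list of [diffeo_transform()]s (one
#'   per test subject) to reuse registrations across tasks.
#' @return An `evaluation_report`; `$rows` has one row per subject x region.
#' @export
evaluate_segmentation <- function(atl, tests, cfg = reg_config(),
                                  transforms = NULL) {
  if (any(vapply(tests, function(s) is.null(s$labels), logical(1)))) {
    af_stop("every test subject needs a label image", "argument")
  }
  if (is.null(transforms)) {
    transforms <- lapply(tests, function(s) register_subject(atl, s, cfg))
  }
  regions <- atlas_regions(atl)
  aid <- atlas_id(atl)
  rows <- purrr::map2_dfr(tests, transforms, function(s, tr) {
    seg <- apply_diffeo(tr, atl$labels, "to_moving", grid = s$labels)
    region_metrics(s$labels, seg, regions) |>
      mutate(template = aid, unit = s$id, .before = 1)
  })
  new_evaluation_report("segmentation", rows, aid)
}

#' Evaluate an atlas on the registration task
#'
#' Warps every test subject's labels into the atlas coordinate system and
#' computes the Dice coefficient for every unordered pair of subjects and
#' every region. Distance metrics are deliberately not computed here: in
#' template space they would be confounded by template size differences, so
#' only the (size-normalised) overlap is reported.
#'
#' @inheritParams evaluate_segmentation
#' @return An `evaluation_report`; `$rows` has one row per pair x region.
#' @export
evaluate_registration <- function(atl, tests, cfg = reg_config(),
                                  transforms = NULL) {
  if (length(tests) < 2L) {
    af_stop("registration evaluation needs >= 2 test subjects", "argument")
  }
  if (any(vapply(tests, function(s) is.null(s$labels), logical(1)))) {
    af_stop("every test subject needs a label image", "argument")
  }
  if (is.null(transforms)) {
    transforms <- lapply(tests, function(s) register_subject(atl, s, cfg))
  }
  regions <- atlas_regions(atl)
  aid <- atlas_id(atl)
  warped <- purrr::map2(tests, transforms,
                        function(s, tr) apply_diffeo(tr, s$labels, "to_fixed"))
  pairs <- utils::combn(length(tests), 2L)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    purrr::map_dfr(regions, function(r) {
      present <- c(any(warped[[i]]$values == r), any(warped[[j]]$values == r))
      tibble::tibble(
        template = aid,
        unit = paste(tests[[i]]$id, tests[[j]]$id, sep = ":"),
        subject_a = tests[[i]]$id, subject_b = tests[[j]]$id, region = r,
        dice = if (any(present)) dice(warped[[i]], warped[[j]], r) else NA_real_)
    })
  })
  new_evaluation_report("registration", rows, aid)
}

atlas_id <- function(atl) {
  if (!is.null(atl$provenance$id)) atl$provenance$id
  else sprintf("%s_n%d", atl$combination, atl$n_subjects)
}

#' Incremental atlas-size convergence experiment
#'
#' For each of `repeats` series, subjects from the template pool are put in a
#' seeded random order (alternating between group tags when
#' `alternate_groups`, with the starting group balanced across series), and
#' for every `n = 1..max_n` an atlas is built from the first `n` subjects and
#' evaluated on the held-out test set for both the segmentation and the
#' registration task (mean Dice over regions and subjects/pairs). Scores are
#' averaged across series.
#'
#' @param pool list of [subject_brain()]s available for template building.
#' @param tests list of held-out [subject_brain()]s with labels.
#' @param max_n largest atlas size (default 12).
#' @param repeats number of randomised series (default 10).
#' @param alternate_groups alternate group tags along each series.
#' @param combination intensity combination passed to [build_atlas()].
#' @param cfg a [reg_config()].
#' @param outer_iters template refinement passes per atlas.
#' @param seed master seed for the series orders.
#' @return A `convergence_curve`: tibble with columns `n`, `task`,
#'   `mean_dice`, `sem`, `repeats`.
#' @export
incremental_convergence <- function(pool, tests, max_n = 12L, repeats = 10L,
                                    alternate_groups = TRUE,
                                    combination = "median",
                                    cfg = reg_config(), outer_iters = 2L,
                                    seed = cfg$seed) {
  if (length(pool) < max_n) {
    af_stop("template pool smaller than `max_n`", "argument")
  }
  groups <- vapply(pool, function(s) s$group, character(1))
  per_rep <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + 1000L * r)
    order_idx <- if (alternate_groups && length(unique(groups)) > 1L) {
      tags <- sort(unique(groups))
      first <- tags[(r - 1L) %% length(tags) + 1L]  # balanced starting group
      by_tag <- lapply(tags, function(g) sample(which(groups == g)))
      names(by_tag) <- tags
      ord <- integer(0)
      seq_tags <- rep(c(first, setdiff(tags, first)), length.out = length(pool))
      counters <- stats::setNames(rep(1L, length(tags)), tags)
      for (g in seq_tags) {
        if (counters[[g]] <= length(by_tag[[g]])) {
          ord <- c(ord, by_tag[[g]][counters[[g]]])
          counters[[g]] <- counters[[g]] + 1L
        }
      }
      ord
    } else {
      sample(seq_along(pool))
    }
    scores <- purrr::map_dfr(seq_len(max_n), function(n) {
      atl <- build_atlas(pool[order_idx[seq_len(n)]], combination, cfg,
                         outer_iters = outer_iters, seed = seed + r,
                         id = sprintf("inc_n%02d_rep%d", n, r))
      trs <- lapply(tests, function(s) register_subject(atl, s, cfg))
      seg <- evaluate_segmentation(atl, tests, cfg, transforms = trs)
      reg <- evaluate_registration(atl, tests, cfg, transforms = trs)
      tibble::tibble(
        repeat_id = r, n = n,
        task = c("segmentation", "registration"),
        dice = c(mean(seg$rows$dice, na.rm = TRUE),
                 mean(reg$rows$dice, na.rm = TRUE)))
    })
    per_rep[[r]] <- scores
  }
  curve <- bind_rows(per_rep) |>
    group_by(.data$n, .data$task) |>
    summarise(mean_dice = mean(.data$dice),
              sem = if (n() >= 2L) sem(.data$dice) else 0,
              repeats = n(), .groups = "drop") |>
    arrange(.data$task, .data$n)
  structure(curve, class = c("convergence_curve", class(curve)))
}

#' Evaluate trace registration through an atlas
#'
#' Registers each subject onto the atlas, maps its traces into template space
#' with [map_points()], and computes the normalised distance (trace distance
#' divided by the template's equivalent spherical radius) for every pair of
#' subjects within each line (traces sharing an id). Lines with fewer than
#' two subjects are skipped with a warning.
#'
#' @param atl an [atlas()].
#' @param subjects list of [subject_brain()]s carrying `traces`.
#' @param cfg a [reg_config()].
#' @param transforms optional pre-computed registrations.
#' @return A tibble with columns `line`, `subject_a`, `subject_b`,
#'   `distance_um`, `normalized`.
#' @export
evaluate_traces <- function(atl, subjects, cfg = reg_config(),
                            transforms = NULL) {
  has_traces <- vapply(subjects, function(s) !is.null(s$traces), logical(1))
  subjects <- subjects[has_traces]
  if (length(subjects) < 2L) {
    af_stop("need >= 2 subjects with traces", "argument")
  }
  if (is.null(transforms)) {
    transforms <- lapply(subjects, function(s) register_subject(atl, s, cfg))
  }
  radius <- equivalent_spherical_radius(atl$template)
  mapped <- purrr::map2(subjects, transforms,
                        function(s, tr) map_points(tr, s$traces))
  lines <- unique(unlist(lapply(mapped, function(tl) {
    vapply(tl, function(t) t$id, character(1))
  })))
  out <- purrr::map_dfr(lines, function(ln) {
    idx <- which(vapply(mapped, function(tl) {
      any(vapply(tl, function(t) t$id == ln, logical(1)))
    }, logical(1)))
    if (length(idx) < 2L) {
      warning(sprintf("line '%s' has < 2 subjects; skipped", ln))
      return(tibble::tibble())
    }
    get_tr <- function(i) {
      tl <- mapped[[i]]
      tl[[which(vapply(tl, function(t) t$id == ln, logical(1)))[1]]]
    }
    pairs <- utils::combn(idx, 2L)
    purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]
      j <- pairs[2, k]
      d <- trace_distance(get_tr(i), get_tr(j))
      tibble::tibble(line = ln, subject_a = subjects[[i]]$id,
                     subject_b = subjects[[j]]$id, distance_um = d,
                     normalized = d / radius)
    })
  })
  out
}

# ---- statistics -------------------------------------------------------------

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences. Zero differences are dropped; with
#' `n <= exact_limit` remaining pairs the null distribution of the positive
#' rank sum is computed exactly (a dynamic programme over signed midranks,
#' identical to full enumeration of all sign assignments, and valid under
#' ties); above that a normal approximation with continuity and tie
#' correction is used. When all differences are zero the test is degenerate:
#' p = 1 is returned with `degenerate = TRUE`.
#'
#' @param x,y equal-length paired numeric vectors.
#' @param exact_limit largest n for the exact null (default 25).
#' @return List of class `wilcoxon_signed_rank` with `statistic` (positive
#'   rank sum), `n` (pairs after dropping zeros), `p_value`, `method`,
#'   `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25L) {
  if (length(x) != length(y)) af_stop("`x` and `y` must pair up", "argument")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(statistic = 0, n = 0L, p_value = 1,
                          method = "degenerate", degenerate = TRUE),
                     class = "wilcoxon_signed_rank"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of W+ over all 2^n sign assignments, on doubled ranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- numeric(total + 1L)
    dist[1] <- 1
    for (rv in r2) {
      shifted <- c(numeric(rv), dist[seq_len(total + 1L - rv)])
      dist <- dist + shifted
    }
    dist <- dist / sum(dist)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[seq.int(w2 + 1L, total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(list(statistic = w, n = n, p_value = p, method = method,
                 degenerate = FALSE),
            class = "wilcoxon_signed_rank")
}

#' @export
print.wilcoxon_signed_rank <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W+ = %g, n = %d, p = %.4g%s\n",
              x$method, x$statistic, x$n, x$p_value,
              if (x$degenerate) " [degenerate: all differences zero]" else ""))
  invisible(x)
}

safe_sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) NA_real_ else sem(x)
}

#' Standard error of the mean
#' @param values numeric vector with >= 2 values.
#' @return `sd(values) / sqrt(length(values))`.
#' @export
sem <- function(values) {
  if (length(values) < 2L) af_stop("`sem` needs >= 2 values", "argument")
  sd(values) / sqrt(length(values))
}

# ---- report output ----------------------------------------------------------

#' Write an evaluation report as tidy CSV + JSON summary
#'
#' @param report an `evaluation_report`.
#' @param csv_path destination for the per-row table.
#' @param json_path optional destination for the mean / s.e.m. summary.
#' @return `csv_path`, invisibly.
#' @export
write_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(report$rows, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(task = report$task, summary = report$summary),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(csv_path)
}
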
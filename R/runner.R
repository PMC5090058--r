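# Scan execution: repeated docking at every step of the plan, reduced to a
# best-pose-per-step trajectory.

#' Execute a tomographic docking scan
#'
#' Runs `cfg$repetitions` independent docking experiments in every search
#' box of the plan. Each (step, repetition) pair derives its own seed as
#' `cfg$seed + 1000 * step + repetition`, so any single run is reproducible
#' in isolation. Engine failures at a repetition are recorded, not fatal,
#' unless every repetition of a step fails.
#'
#' @param receptor,ligand aligned `tomo_structure` objects.
#' @param plan a [build_scan()] result.
#' @param engine currently `"mock"` (the built-in engine); external-engine
#'   scans are driven through [vina_adapter()] by the command-line tool.
#' @param n_poses poses kept per repetition.
#' @param out_dir optional directory for incremental persistence: poses are
#'   saved per step and reused on a rerun with an identical configuration.
#' @return object of class `scan_result`: `plan`, `poses[[step]][[rep]]`
#'   (each a sorted pose list, or `NULL` on failure), `failures`,
#'   `provenance`.
#' @export
run_scan <- function(receptor, ligand, plan, engine = "mock", n_poses = 5,
                     out_dir = NULL) {
  cfg <- plan$config
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  prov <- list(engine = engine, config = unclass(cfg),
               receptor = attr(receptor, "id"), ligand = attr(ligand, "id"))
  poses <- vector("list", plan$n_steps)
  failures <- list()
  for (k in seq_len(plan$n_steps)) {
    cache <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("step_%03d.rds", k)) else NULL
    if (!is.null(cache) && file.exists(cache)) {
      saved <- readRDS(cache)
      if (identical(saved$provenance, prov)) {
        poses[[k]] <- saved$reps
        next
      }
    }
    reps <- vector("list", cfg$repetitions)
    for (r in seq_len(cfg$repetitions)) {
      seed_kr <- cfg$seed + 1000L * k + r
      params <- engine_params(exhaustiveness = cfg$exhaustiveness,
                              n_poses = n_poses, seed = seed_kr)
      res <- tryCatch(dock(receptor, ligand, plan$boxes[[k]], params,
                           engine = engine),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          list(step = k, repetition = r, message = conditionMessage(res))
        reps[r] <- list(NULL)
      } else {
        res <- lapply(res, function(p) {
          p$step_index <- k; p$repetition <- r; p
        })
        reps[[r]] <- res
      }
    }
    if (all(vapply(reps, is.null, logical(1))))
      stop("all ", cfg$repetitions, " repetitions failed at step ", k)
    poses[[k]] <- reps
    if (!is.null(cache))
      saveRDS(list(provenance = prov, reps = reps), cache)
  }
  structure(list(plan = plan, poses = poses, failures = failures,
                 provenance = prov),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result: %d steps x %d repetitions, engine '%s'%s>\n",
              x$plan$n_steps, x$plan$config$repetitions,
              x$provenance$engine,
              if (length(x$failures))
                sprintf(", %d failed runs", length(x$failures)) else ""))
  invisible(x)
}

#' Best pose per step
#'
#' Reduces a scan result to the representative pose series: at each step,
#' the pose with the lowest score among all repetitions. Exact score ties
#' are broken by lowest repetition index, then lowest pose rank.
#'
#' @param result a [run_scan()] result.
#' @return object of class `tomo_trajectory`: data.frame-like `summary`
#'   (step, score, repetition) plus the selected pose per step.
#' @export
best_pose_per_step <- function(result) {
  n <- result$plan$n_steps
  best <- vector("list", n)
  for (k in seq_len(n)) {
    reps <- result$poses[[k]]
    sel <- NULL
    sel_key <- NULL
    for (r in seq_along(reps)) {
      if (is.null(reps[[r]])) next
      for (j in seq_along(reps[[r]])) {
        p <- reps[[r]][[j]]
        # ties break toward the lowest stored repetition, then pose rank,
        # so the reduction is invariant to repetition storage order
        key <- c(p$score, p$repetition %||% r, j)
        if (is.null(sel) ||
            key[1] < sel_key[1] ||
            (key[1] == sel_key[1] && (key[2] < sel_key[2] ||
              (key[2] == sel_key[2] && key[3] < sel_key[3])))) {
          sel <- p
          sel_key <- key
        }
      }
    }
    if (is.null(sel)) stop("no successful poses at step ", k)
    best[[k]] <- sel
  }
  structure(list(
    summary = data.frame(step = seq_len(n),
                         score = vapply(best, `[[`, numeric(1), "score"),
                         repetition = vapply(best, `[[`, numeric(1),
                                             "repetition")),
    poses = best, plan = result$plan),
    class = "tomo_trajectory")
}

#' @export
print.tomo_trajectory <- function(x, ...) {
  cat(sprintf("<tomo_trajectory: %d steps, best scores %.3f .. %.3f>\n",
              nrow(x$summary), min(x$summary$score), max(x$summary$score)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Plot the best-score series of a trajectory
#'
#' Score versus scan step; when change flags are supplied, steps with a
#' significant pose change are drawn filled.
#'
#' @param x a `tomo_trajectory`.
#' @param flags optional [flag_changes()] output.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tomo_trajectory <- function(x, flags = NULL, ...) {
  s <- x$summary
  graphics::plot(s$step, s$score, type = "b", pch = 1,
                 xlab = "scan step", ylab = "best docking score", ...)
  if (!is.null(flags)) {
    f <- flags$significant
    graphics::points(s$step[f], s$score[f], pch = 16)
  }
  invisible(x)
}

#' Export per-step scores of a scan as TSV
#' @param result a [run_scan()] result.
#' @param path output TSV (step, repetition, rank, score).
#' @export
write_scores <- function(result, path) {
  rows <- list()
  for (k in seq_along(result$poses))
    for (r in seq_along(result$poses[[k]])) {
      reps <- result$poses[[k]][[r]]
      if (is.null(reps)) next
      for (j in seq_along(reps))
        rows[[length(rows) + 1L]] <-
          data.frame(step = k, repetition = r, rank = j,
                     score = reps[[j]]$score)
    }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
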
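#' Configuration of a full synthetic experiment run
#'
#' Describes an end-to-end run mirroring the study's group structure (two
#' transgenic lines, saline vs ouabain, several days-post-injection
#' timepoints): per-group synthetic scenes with programmed imaging effects,
#' a qPCR design with programmed fold changes, and a statistics plan. The
#' whole run is deterministic given `root_seed`: scene seeds are derived as
#' `child_seed(root_seed, 100 + fish_index)` and the qPCR seed as
#' `child_seed(root_seed, 7)`.
#'
#' @param groups data.frame with columns `line`, `treatment`, `dpi`,
#'   `n_fish`.
#' @param scene_base a [scene_config()] used as template for every fish.
#' @param scene_overrides named list: for group label
#'   `"<line>|<treatment>|<dpi>"`, a list of scene_config fields to override
#'   (how programmed imaging effects, e.g. a higher PCNA+ fraction after
#'   lesion, are expressed).
#' @param seg_params a [segmentation_params()].
#' @param qpcr a [qpcr_design()] or `NULL` to skip the qPCR stage.
#' @param qpcr_targets target genes to quantify (default: all non-reference
#'   genes of the design).
#' @param stats_plan list with `value` (column to test, default `"density"`),
#'   `by` (grouping column, default `"line"`), `test`
#'   (`"welch"` or `"kw-conover"`), `adjust` (for Conover), `alpha`.
#' @param out_dir output directory.
#' @param root_seed root seed for the entire run.
#' @return a `run_config` list.
#' @export
run_config <- function(groups = data.frame(
                         line = rep(c("mpeg1:FP", "mpeg1:myd88"), each = 1),
                         treatment = "ouabain", dpi = 4L, n_fish = 6L),
                       scene_base = scene_config(),
                       scene_overrides = list(),
                       seg_params = segmentation_params(),
                       qpcr = NULL, qpcr_targets = NULL,
                       stats_plan = list(value = "density", by = "line",
                                         test = "welch", adjust = "holm",
                                         alpha = 0.05),
                       out_dir = tempfile("retinaquant_run_"),
                       root_seed = 1L) {
  structure(list(groups = groups, scene_base = scene_base,
                 scene_overrides = scene_overrides, seg_params = seg_params,
                 qpcr = qpcr, qpcr_targets = qpcr_targets,
                 stats_plan = stats_plan, out_dir = out_dir,
                 root_seed = as.integer(root_seed)),
            class = "run_config")
}

.group_key <- function(line, treatment, dpi)
  paste(line, treatment, dpi, sep = "|")

#' Run a full synthetic experiment
#'
#' simulate -> count -> qpcr -> stats. Emits `counts.csv`, `folds.csv`
#' (when a qPCR design is configured), `stats.csv` and `run.log` into
#' `config$out_dir`. Deterministic: identical configs give byte-identical
#' CSV outputs. Any stage failure aborts with a stage-named diagnostic and
#' leaves an `INCOMPLETE` marker file.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `counts`, `folds`, `stats` data.frames and
#'   the output paths.
#' @export
run_experiment <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(config$out_dir, "INCOMPLETE")
  file.create(marker)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))
  logf("retinaquant run, root_seed=%d", config$root_seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage: ", name)), log_path)
      stop_retinaquant(sprintf("stage '%s' failed: %s", name,
                               conditionMessage(e)), "pipeline_stage_error")
    })
  }

  # --- simulate + count -------------------------------------------------
  counts <- stage("simulate/count", {
    rows <- list()
    fish_index <- 0L
    for (g in seq_len(nrow(config$groups))) {
      grp <- config$groups[g, ]
      key <- .group_key(grp$line, grp$treatment, grp$dpi)
      over <- config$scene_overrides[[key]]
      for (f in seq_len(grp$n_fish)) {
        fish_index <- fish_index + 1L
        cfg <- config$scene_base
        if (!is.null(over)) cfg <- do.call(scene_config,
                                           modifyList(unclass(cfg), over))
        cfg <- do.call(scene_config, modifyList(
          unclass(cfg),
          list(seed = child_seed(config$root_seed, 100 + fish_index))))
        sec <- generate_section(cfg)
        roi <- roi_polygon(rbind(c(0, 0), c(0, cfg$image_width_px - 1),
                                 c(cfg$image_height_px - 1,
                                   cfg$image_width_px - 1),
                                 c(cfg$image_height_px - 1, 0)),
                           label = "full_field")
        sample_id <- sprintf("fish%03d", fish_index)
        grp_lab <- list(line = grp$line, treatment = grp$treatment,
                        dpi = grp$dpi)
        rec <- count_coloc(sec$stack, "DAPI", "PCNA", roi,
                           config$seg_params, sample_id, grp_lab)
        logf("%s %s: DAPI&PCNA count=%d (truth %d)", sample_id, key,
             rec$raw_count, sec$truth$counts[["DAPI&PCNA"]])
        rows[[length(rows) + 1]] <- rec
        if ("TUNEL" %in% sec$stack$channel_names) {
          rows[[length(rows) + 1]] <-
            count_single_marker(sec$stack, "TUNEL", roi, config$seg_params,
                                sample_id, grp_lab)
        }
      }
    }
    do.call(rbind, lapply(rows, as.data.frame))
  })
  counts_path <- file.path(config$out_dir, "counts.csv")
  write.csv(counts, counts_path, row.names = FALSE)
  logf("wrote %s (%d records)", counts_path, nrow(counts))

  # --- qPCR -------------------------------------------------------------
  folds <- NULL
  if (!is.null(config$qpcr)) {
    folds <- stage("qpcr", {
      d <- config$qpcr
      d$seed <- child_seed(config$root_seed, 7)
      class(d) <- "qpcr_design"
      tab <- generate_qpcr(d)
      targets <- config$qpcr_targets %||%
        setdiff(d$genes, d$reference_gene)
      do.call(rbind, lapply(targets, function(g)
        as.data.frame(delta_delta_ct(tab, g, d$reference_gene))))
    })
    folds_path <- file.path(config$out_dir, "folds.csv")
    write.csv(folds, folds_path, row.names = FALSE)
    logf("wrote %s (%d records)", folds_path, nrow(folds))
  }

  # --- stats ------------------------------------------------------------
  stats_df <- stage("stats", {
    plan <- config$stats_plan
    pieces <- list()
    run_test <- function(df, value_col, label) {
      groups <- split(df[[value_col]], df[[plan$by]])
      groups <- groups[lengths(groups) >= 2]
      if (length(groups) < 2) return(NULL)
      if (plan$test == "welch" && length(groups) == 2) {
        r <- welch_test(groups[[1]], groups[[2]])
        data.frame(comparison = label,
                   test = "welch",
                   contrast = paste(names(groups), collapse = " vs "),
                   statistic = r$statistic, p_value = r$p_value,
                   significant = r$p_value < plan$alpha)
      } else {
        r <- conover_posthoc(groups, adjust = plan$adjust %||% "holm")
        ut <- which(upper.tri(r$pairwise_p), arr.ind = TRUE)
        data.frame(comparison = label,
                   test = "kw-conover",
                   contrast = paste(rownames(r$pairwise_p)[ut[, 1]],
                                    colnames(r$pairwise_p)[ut[, 2]],
                                    sep = " vs "),
                   statistic = r$statistic,
                   p_value = r$pairwise_p[ut],
                   significant = r$pairwise_p[ut] < plan$alpha)
      }
    }
    for (combo in unique(counts$marker_combo)) {
      sub <- counts[counts$marker_combo == combo, ]
      pieces[[length(pieces) + 1]] <-
        run_test(sub, plan$value %||% "density", paste0("counts:", combo))
    }
    if (!is.null(folds)) {
      for (g in unique(folds$gene)) {
        sub <- folds[folds$gene == g & folds$treatment != "saline", ]
        pieces[[length(pieces) + 1]] <-
          run_test(sub, "fold_change", paste0("qpcr:", g))
      }
    }
    out <- do.call(rbind, pieces)
    if (is.null(out)) out <- data.frame(comparison = character(0),
                                        test = character(0),
                                        contrast = character(0),
                                        statistic = numeric(0),
                                        p_value = numeric(0),
                                        significant = logical(0))
    out
  })
  stats_path <- file.path(config$out_dir, "stats.csv")
  write.csv(stats_df, stats_path, row.names = FALSE)
  logf("wrote %s (%d comparisons)", stats_path, nrow(stats_df))

  writeLines(log_lines, log_path)
  file.remove(marker)
  invisible(list(counts = counts, folds = folds, stats = stats_df,
                 out_dir = config$out_dir,
                 paths = list(counts = counts_path,
                              stats = stats_path, log = log_path)))
}
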
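group_pairs <- list(c("phobic", "fearful"), c("phobic", "non_fearful"),
                    c("fearful", "non_fearful"))

tr_list <- function(x) {
  if (inherits(x, "test_result") || inherits(x, "anova_result"))
    return(lapply(unclass(x), tr_list))
  if (is.data.frame(x)) return(x)
  x
}

safe_analysis <- function(expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

posthoc_pairs <- function(readouts, col, test = c("t", "mwu")) {
  test <- match.arg(test)
  out <- list()
  for (pr in group_pairs) {
    a <- readouts[[col]][readouts$group == pr[1]]
    b <- readouts[[col]][readouts$group == pr[2]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) next
    key <- paste(pr, collapse = "_vs_")
    out[[key]] <- tr_list(if (test == "t") t_test_report(a, b)
                          else mann_whitney_u(a, b))
  }
  out
}

# long table from wide per-cell columns named paste0(prefix, key[, suffix])
long_from_cells <- function(readouts, cells, col_of) {
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cc <- col_of(cells[i, , drop = FALSE])
    if (!cc %in% names(readouts)) return(NULL)
    block <- data.frame(subject = readouts$participant_id,
                        group = readouts$group,
                        value = readouts[[cc]], stringsAsFactors = FALSE)
    for (w in names(cells)) block[[w]] <- cells[[w]][i]
    rows[[i]] <- block
  }
  do.call(rbind, rows)
}

rm_analysis <- function(readouts, cells, col_of, within, exclude = NULL) {
  long <- long_from_cells(readouts, cells, col_of)
  if (is.null(long)) return(list(error = "required columns absent"))
  drop_ids <- unique(c(
    exclude,
    long$subject[is.na(long$value)]
  ))
  long <- long[!long$subject %in% drop_ids, ]
  if (length(unique(long$subject)) < 6 ||
      length(unique(long$group)) < 2)
    return(list(error = "too few complete subjects for rmANOVA",
                excluded = drop_ids))
  res <- mixed_rm_anova(long, dv = "value", subject = "subject",
                        within = within, between = "group")
  c(tr_list(res), list(excluded = as.list(drop_ids)))
}

#' Group-level statistical report
#'
#' Runs the full analysis battery on a readout table: the valence
#' manipulation check (Kruskal-Wallis + pairwise Mann-Whitney with U3),
#' per-task group comparisons (ANOVA with eta-squared and post hoc t tests
#' with Glass' delta for the search and approach readouts; Kruskal-Wallis
#' with Mann-Whitney post hocs for the ordinal avoidance score),
#' repeated-measures ANOVAs (glances, orientation, per-side physiology,
#' path thirds, acceleration changes, pre-touch pupil and RR) with partial
#' and generalized eta-squared, FSQ correlations, the cross-task Spearman
#' matrix, and the questionnaire correlation table with partial Spearman
#' columns controlling for FSQ and for spider valence. Participants flagged
#' by exclusion rules (never entered the spider side; closed eyes before
#' the touch; missing RR) are excluded per analysis and listed.
#'
#' @param readouts data frame from [compute_readouts()].
#' @param alpha significance level (default 0.05).
#' @param bonferroni_m comparisons in the questionnaire family
#'   (default 162 = 3 readouts x 54 scales).
#' @return nested list (serializable to `stats_report.json`), or `NULL`
#'   with a warning when fewer than two groups are present.
#' @export
compute_stats <- function(readouts, alpha = 0.05, bonferroni_m = 162) {
  gtab <- table(readouts$group)
  if (sum(gtab >= 2) < 2) {
    warning("fewer than two groups with >= 2 participants; group statistics skipped")
    return(NULL)
  }
  rep_ <- list()
  rep_$n <- list(total = nrow(readouts), per_group = as.list(gtab))

  rep_$valence <- safe_analysis(list(
    kruskal = tr_list(kruskal_wallis(readouts$valence_diff, readouts$group)),
    posthoc = posthoc_pairs(readouts, "valence_diff", "mwu"),
    fsq_spearman = tr_list(cor_report(readouts$valence_diff, readouts$fsq,
                                      "spearman"))))

  rep_$fishing <- safe_analysis(list(
    anova = tr_list(oneway_anova(readouts$fishing_min_dist_diff,
                                 readouts$group)),
    posthoc = posthoc_pairs(readouts, "fishing_min_dist_diff", "t"),
    fsq_pearson = tr_list(cor_report(readouts$fishing_min_dist_diff,
                                     readouts$fsq, "pearson"))))

  if ("fishing_glances_spider" %in% names(readouts)) {
    cells <- data.frame(stimulus = c("spider", "turtle"))
    rep_$fishing_glances <- safe_analysis(c(
      rm_analysis(readouts, cells,
                  function(cl) paste0("fishing_glances_", cl$stimulus),
                  within = "stimulus"),
      list(posthoc = posthoc_pairs(readouts, "fishing_glance_diff", "t"),
           fsq_pearson = tr_list(cor_report(readouts$fishing_glance_diff,
                                            readouts$fsq, "pearson")))))
  }

  if ("fishing_angle_spider" %in% names(readouts)) {
    excl <- readouts$participant_id[
      isTRUE(readouts$excl_never_entered_spider_side) |
        readouts$excl_never_entered_spider_side %in% TRUE]
    cells <- data.frame(stimulus = c("spider", "turtle"))
    rep_$fishing_orientation <- safe_analysis(c(
      rm_analysis(readouts, cells,
                  function(cl) paste0("fishing_angle_", cl$stimulus),
                  within = "stimulus", exclude = excl),
      list(posthoc = posthoc_pairs(readouts, "fishing_angle_diff", "t"),
           fsq_pearson = tr_list(cor_report(readouts$fishing_angle_diff,
                                            readouts$fsq, "pearson")))))
  }

  for (ph in c("rr", "pupil")) {
    col <- paste0("fishing_", ph, "_spider_side")
    if (!col %in% names(readouts)) next
    cells <- data.frame(side = c("spider", "turtle"))
    rep_[[paste0("fishing_", ph, "_by_side")]] <- safe_analysis(
      rm_analysis(readouts, cells,
                  function(cl) paste0("fishing_", ph, "_", cl$side, "_side"),
                  within = "side"))
  }

  if ("path_choice_score" %in% names(readouts))
    rep_$path_choice <- safe_analysis(list(
      kruskal = tr_list(kruskal_wallis(readouts$path_choice_score,
                                       readouts$group)),
      posthoc = posthoc_pairs(readouts, "path_choice_score", "mwu"),
      fsq_spearman = tr_list(cor_report(readouts$path_choice_score,
                                        readouts$fsq, "spearman"))))

  if ("touch_time_diff" %in% names(readouts))
    rep_$touch <- safe_analysis(list(
      anova = tr_list(oneway_anova(readouts$touch_time_diff,
                                   readouts$group)),
      posthoc = posthoc_pairs(readouts, "touch_time_diff", "t"),
      fsq_pearson = tr_list(cor_report(readouts$touch_time_diff,
                                       readouts$fsq, "pearson"))))

  if ("thirds_spider1_1" %in% names(readouts)) {
    cells <- expand.grid(area = c("1", "2", "3"), trial = c("1", "2"),
                         stimulus = c("spider", "turtle"),
                         stringsAsFactors = FALSE)[, c("stimulus", "trial",
                                                       "area")]
    rep_$touch_thirds <- safe_analysis(
      rm_analysis(readouts, cells,
                  function(cl) paste0("thirds_", cl$stimulus, cl$trial, "_",
                                      cl$area),
                  within = c("stimulus", "trial", "area")))
  }

  if ("accel_spider1" %in% names(readouts)) {
    cells <- expand.grid(trial = c("1", "2"),
                         stimulus = c("spider", "turtle"),
                         stringsAsFactors = FALSE)[, c("stimulus", "trial")]
    rep_$touch_accel <- safe_analysis(
      rm_analysis(readouts, cells,
                  function(cl) paste0("accel_", cl$stimulus, cl$trial),
                  within = c("stimulus", "trial")))
  }

  for (ph in c("pupil", "rr")) {
    col <- paste0("pretouch_", ph, "_spider1")
    if (!col %in% names(readouts)) next
    flag <- if (ph == "pupil") "excl_closed_eyes" else "excl_missing_rr"
    excl <- if (flag %in% names(readouts))
      readouts$participant_id[readouts[[flag]] %in% TRUE] else NULL
    cells <- expand.grid(trial = c("1", "2"),
                         stimulus = c("spider", "turtle"),
                         stringsAsFactors = FALSE)[, c("stimulus", "trial")]
    rep_[[paste0("pretouch_", ph)]] <- safe_analysis(
      rm_analysis(readouts, cells,
                  function(cl) paste0("pretouch_", ph, "_", cl$stimulus,
                                      cl$trial),
                  within = c("stimulus", "trial"), exclude = excl))
  }

  task_cols <- c(fishing = "fishing_min_dist_diff",
                 path_choice = "path_choice_score",
                 touch = "touch_time_diff")
  task_cols <- task_cols[task_cols %in% names(readouts)]
  if (length(task_cols) >= 2) {
    ct <- list()
    nm <- names(task_cols)
    for (i in seq_along(task_cols)[-length(task_cols)])
      for (j in (i + 1):length(task_cols)) {
        key <- paste(nm[i], nm[j], sep = "_vs_")
        ct[[key]] <- safe_analysis(tr_list(
          cor_report(readouts[[task_cols[i]]], readouts[[task_cols[j]]],
                     "spearman")))
      }
    rep_$across_tasks <- ct
  }

  scale_cols <- c("fsq", grep("^scale_", names(readouts), value = TRUE),
                  "valence_spider", "valence_diff")
  qt <- list()
  for (rd in names(task_cols)) {
    for (sc in scale_cols) {
      key <- paste(rd, sc, sep = "_x_")
      qt[[key]] <- safe_analysis(list(
        spearman = tr_list(cor_report(readouts[[task_cols[rd]]],
                                      readouts[[sc]], "spearman")),
        partial_given_fsq = if (sc == "fsq") NULL else
          tr_list(partial_spearman(readouts[[task_cols[rd]]],
                                   readouts[[sc]], readouts$fsq)),
        partial_given_valence = if (sc == "valence_spider") NULL else
          tr_list(partial_spearman(readouts[[task_cols[rd]]],
                                   readouts[[sc]],
                                   readouts$valence_spider))))
    }
  }
  rep_$questionnaires <- qt

  rep_$thresholds <- list(alpha = alpha,
                          bonferroni = bonferroni_threshold(alpha,
                                                            bonferroni_m),
                          bonferroni_m = bonferroni_m)
  rep_
}

#' Write the statistical report as JSON
#'
#' @param report list from [compute_stats()].
#' @param path output path (`stats_report.json`).
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input_dir directory of session containers, or `NULL` to
#'   simulate.
#' @param cohort a [cohort_config()] used when simulating.
#' @param output_dir where `readouts.csv`, `stats_report.json`, and
#'   `run_log.txt` are written (`NULL` = don't write).
#' @param include analysis toggles, see [compute_readouts()].
#' @param touch_cap,accel_cap,glance_gap thresholds (20 s, 100, 0.2 s).
#' @param alpha,bonferroni_m significance thresholds (0.05, 162).
#' @param seed overrides the cohort seed when not `NULL`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, cohort = cohort_config(),
                            output_dir = NULL,
                            include = c("fishing", "path_choice", "touch",
                                        "physiology"),
                            touch_cap = 20, accel_cap = 100,
                            glance_gap = 0.2, alpha = 0.05,
                            bonferroni_m = 162, seed = NULL) {
  stopifnot(touch_cap > 0, accel_cap > 0, glance_gap > 0)
  if (!is.null(seed)) cohort$seed <- seed
  structure(list(input_dir = input_dir, cohort = cohort,
                 output_dir = output_dir, include = include,
                 touch_cap = touch_cap, accel_cap = accel_cap,
                 glance_gap = glance_gap, alpha = alpha,
                 bonferroni_m = bonferroni_m),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulate (or load) sessions, compute the per-participant readout table,
#' and run the group-level statistics. Malformed sessions are skipped with
#' a logged reason; if every session fails, the run errors. With fewer
#' than two groups the statistics step is skipped with a warning. Outputs
#' (`readouts.csv`, `stats_report.json`, `run_log.txt`) are written when
#' `output_dir` is set; every number in the report is reproducible from
#' `readouts.csv` by re-running [compute_stats()] alone.
#'
#' @param config a [pipeline_config()].
#' @return list with `readouts`, `stats`, `log` (character vector), and
#'   `paths` of any files written, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message(msg)
  }
  if (is.null(config$input_dir)) {
    say("simulating cohort (seed %d)", config$cohort$seed)
    sessions <- generate_cohort(config$cohort)$sessions
  } else {
    dirs <- list.dirs(config$input_dir, recursive = FALSE)
    say("loading %d session containers from %s", length(dirs),
        config$input_dir)
    sessions <- list()
    for (d in dirs) {
      s <- tryCatch(load_session(d), error = function(e) e)
      if (inherits(s, "error")) {
        say("skipping %s: %s", basename(d), conditionMessage(s))
      } else sessions[[length(sessions) + 1]] <- s
    }
    if (length(sessions) == 0) stop("no loadable session in ", config$input_dir)
  }
  say("computing readouts for %d sessions", length(sessions))
  readouts <- withCallingHandlers(
    compute_readouts(sessions, include = config$include,
                     touch_cap = config$touch_cap,
                     accel_cap = config$accel_cap,
                     glance_gap = config$glance_gap, on_error = "skip"),
    warning = function(w) {
      log <<- c(log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  validate_readouts(readouts)
  for (id in names(attr(readouts, "skipped")))
    say("excluded %s: %s", id, attr(readouts, "skipped")[[id]])

  stats <- withCallingHandlers(
    compute_stats(readouts, alpha = config$alpha,
                  bonferroni_m = config$bonferroni_m),
    warning = function(w) {
      log <<- c(log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  paths <- list()
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    paths$readouts <- file.path(config$output_dir, "readouts.csv")
    write_readouts(readouts, paths$readouts)
    if (!is.null(stats)) {
      paths$stats <- file.path(config$output_dir, "stats_report.json")
      write_stats_report(stats, paths$stats)
    }
    paths$log <- file.path(config$output_dir, "run_log.txt")
    writeLines(log, paths$log)
    say("outputs written to %s", config$output_dir)
  }
  invisible(list(readouts = readouts, stats = stats, log = log,
                 paths = paths))
}
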
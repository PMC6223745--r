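#' Build a study configuration
#'
#' A study is a list of treatment groups (cell line x treatment x culture
#' system, each with replicate structure and either a generative population
#' spec or an input CSV) plus analysis settings and one global seed. The
#' configuration can be written as a YAML document (see
#' `system.file("extdata", "example_study.yaml", package = "embryosync")`)
#' or built in code.
#'
#' @param groups List of group definitions. Each group is a list with:
#'   `label` (unique), `cell_line`, `treatment` (`"dispersed"` or
#'   `"non_dispersed"`), `culture` (`"bioreactor"` or `"solid"`),
#'   `n_replicates`, and either `population` (arguments for
#'   [population_spec()], per replicate) or `lengths_csv`; optionally
#'   `sampled_fraction`, `initial_fw_g` (for yield extrapolation),
#'   `germination` (list `p_start`, `p_root_given_start`, `n_collected`) or
#'   `germination_csv`, and `render_images = TRUE` to route lengths through
#'   the image-rendering + morphometry path.
#' @param analysis List: `delta` (mm, default 1), `origin` (mm, default 0),
#'   `fractions` (default `c(0.5, 0.66, 0.75)`), `ci_level` (default 0.90),
#'   `welch` (default `FALSE`), `mm_per_px` (default 0.02, used when
#'   rendering).
#' @param seed Global integer seed; per-stage seeds are derived with
#'   [derive_seed()].
#' @param output_dir Where [run_study()] writes artifacts.
#' @return An object of class `study_config`.
#' @export
study_config <- function(groups, analysis = list(), seed = 1L,
                         output_dir = tempfile("embryosync_run_")) {
  defaults <- list(delta = 1, origin = 0, fractions = c(0.50, 0.66, 0.75),
                   ci_level = 0.90, welch = FALSE, mm_per_px = 0.02)
  analysis <- utils::modifyList(defaults, analysis)
  labels <- vapply(groups, function(g) g$label, character(1))
  if (anyDuplicated(labels)) stop("group labels must be unique")
  for (g in groups)
    if (is.null(g$population) && is.null(g$lengths_csv))
      stop("group '", g$label,
           "' has neither a population spec nor a lengths CSV")
  structure(list(groups = groups, analysis = analysis,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' @param path Path to a YAML document with top-level keys `groups`,
#'   `analysis` (optional), `seed`, `output_dir` (optional).
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  study_config(groups = y$groups,
               analysis = if (is.null(y$analysis)) list() else y$analysis,
               seed = if (is.null(y$seed)) 1L else y$seed,
               output_dir = if (is.null(y$output_dir))
                 tempfile("embryosync_run_") else y$output_dir)
}

group_lengths <- function(g, analysis, seed, out_dir, log) {
  if (!is.null(g$lengths_csv)) {
    log("group ", g$label, ": reading lengths from ", g$lengths_csv)
    return(read_length_sample(g$lengths_csv))
  }
  pop <- do.call(population_spec, utils::modifyList(
    g$population, list(label = g$label,
                       n_replicates = if (is.null(g$n_replicates)) 1L
                                      else g$n_replicates)))
  s <- sample_lengths(pop, derive_seed(seed, paste0("lengths/", g$label)))
  write_length_sample(s, file.path(out_dir, paste0(g$label, "_lengths.csv")))
  if (isTRUE(g$render_images)) {
    log("group ", g$label, ": rendering plates and re-measuring")
    measured <- lapply(split(s$length_mm, s$replicate), function(ls) {
      # plate sized to hold the replicate without touching at low density
      amax <- max(ls) / analysis$mm_per_px
      side <- max(512L, ceiling(sqrt(10 * sum(
        pi * (ls / analysis$mm_per_px / 2)^2 * 0.5)) + 2 * amax))
      ps <- plate_image_spec(side, side, mm_per_px = analysis$mm_per_px)
      r <- render_plate_image(ps, ls,
                              derive_seed(seed, paste0("render/", g$label)))
      m <- measure_all(r$image, analysis$mm_per_px)
      m$major_mm
    })
    s <- data.frame(
      replicate = rep(seq_along(measured), lengths(measured)),
      treatment = g$label, length_mm = unlist(measured))
    class(s) <- c("length_sample", "data.frame")
    write_length_sample(
      s, file.path(out_dir, paste0(g$label, "_lengths_measured.csv")))
  }
  s
}

summarize_group <- function(g, lengths, analysis, seed, warnings_env) {
  x <- lengths$length_mm
  withCallingHandlers(
    check_normality(x),
    warning = function(w) {
      warnings_env$msgs <- c(warnings_env$msgs,
                             paste0(g$label, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  ci <- mckay_ci(cv(x), length(x), analysis$ci_level)
  wsum <- replicate_width_summary(lengths, analysis$delta, analysis$origin,
                                  analysis$fractions)
  per_rep_n <- as.integer(table(lengths$replicate))
  yield <- NULL
  if (!is.null(g$sampled_fraction) && !is.null(g$initial_fw_g))
    yield <- yield_per_gfw(length(x), g$sampled_fraction, g$initial_fw_g)
  germ <- NULL
  if (!is.null(g$germination_csv)) {
    gg <- read.csv(g$germination_csv)
    germ <- germination_record(gg$collected[1], gg$started[1], gg$rooted[1],
                               g$label)
  } else if (!is.null(g$germination)) {
    germ <- simulate_germination(
      germination_spec(g$germination$p_start,
                       g$germination$p_root_given_start),
      g$germination$n_collected,
      derive_seed(seed, paste0("germination/", g$label)), g$label)
  }
  list(label = g$label, cell_line = g$cell_line, treatment = g$treatment,
       culture = g$culture,
       n = length(x), n_replicates = length(per_rep_n),
       per_replicate_n = per_rep_n,
       mean_length_mm = mean(x), sd_length_mm = sd(x),
       cv = ci, widths = wsum, yield = yield, germination = germ)
}

#' Run a configured study end to end
#'
#' Generates (or loads) each group's data, optionally routes it through
#' plate rendering and morphometry, computes the full statistics battery
#' (mean/SD, CV with McKay CI, per-replicate widths at the configured
#' fractions, yield extrapolation, germination rates), and writes report
#' tables, a JSON summary and a run log under the configured output
#' directory. Deterministic for a fixed seed: re-running yields a
#' byte-identical `summary.json`.
#'
#' @param config A [study_config()] or path to a YAML config.
#' @return A `run_report`: list with `groups` (named list of per-group
#'   summaries), `config`, `warnings`, and the output paths in `files`.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  log <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ..., "\n",
        sep = "", file = log_path, append = TRUE)
  }
  log("run_study start, seed = ", config$seed)
  warnings_env <- new.env(); warnings_env$msgs <- character(0)
  summaries <- list()
  for (g in config$groups) {
    stage <- "lengths"
    res <- tryCatch({
      lens <- group_lengths(g, config$analysis, config$seed, out_dir, log)
      stage <- "statistics"
      summarize_group(g, lens, config$analysis, config$seed, warnings_env)
    }, error = function(e)
      stop("group '", g$label, "' failed at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE))
    summaries[[g$label]] <- res
    log("group ", g$label, ": n = ", res$n, ", mean = ",
        round(res$mean_length_mm, 3), " mm, CV = ", round(res$cv$cv, 4))
  }
  report <- structure(
    list(groups = summaries, config = config,
         warnings = warnings_env$msgs,
         provenance = list(seed = config$seed,
                           package_version =
                             as.character(packageVersion("embryosync")))),
    class = "run_report")
  report$files <- write_report_tables(report, out_dir)
  log("run_study done: ", length(summaries), " groups")
  report
}

round_or_na <- function(x, d) if (is.null(x)) NA_real_ else round(x, d)

write_report_tables <- function(report, out_dir) {
  gs <- report$groups
  # lengths + CV table (2 dp, matching conventional reporting precision)
  t1 <- do.call(rbind, lapply(gs, function(s) data.frame(
    label = s$label, cell_line = s$cell_line %||% NA,
    treatment = s$treatment %||% NA, culture = s$culture %||% NA,
    n = s$n, mean_length_mm = round(s$mean_length_mm, 2),
    sd_length_mm = round(s$sd_length_mm, 2),
    cv = round(s$cv$cv, 2),
    cv_ci_low = round(s$cv$ci_low, 2), cv_ci_high = round(s$cv$ci_high, 2))))
  t2 <- do.call(rbind, lapply(gs, function(s) {
    w <- s$widths
    data.frame(label = s$label, fraction = w$fraction,
               mean_width_mm = round(w$mean_width_mm, 2),
               sd_width_mm = round(w$sd_width_mm, 2),
               n_replicates = w$n_replicates)
  }))
  t3 <- do.call(rbind, lapply(gs, function(s) {
    if (is.null(s$germination)) return(NULL)
    r <- germination_rates(s$germination)
    data.frame(label = s$label, collected = s$germination$collected,
               started = s$germination$started,
               rooted = s$germination$rooted,
               pct_started = r$pct_started, pct_rooted = r$pct_rooted)
  }))
  files <- list(
    table1 = file.path(out_dir, "table1_lengths_cv.csv"),
    table2 = file.path(out_dir, "table2_widths.csv"),
    summary = file.path(out_dir, "summary.json"))
  write.csv(t1, files$table1, row.names = FALSE)
  write.csv(t2, files$table2, row.names = FALSE)
  if (!is.null(t3)) {
    files$table3 <- file.path(out_dir, "table3_germination.csv")
    write.csv(t3, files$table3, row.names = FALSE)
  }
  json <- lapply(gs, function(s) list(
    n = s$n, n_replicates = s$n_replicates,
    mean_length_mm = s$mean_length_mm, sd_length_mm = s$sd_length_mm,
    cv = s$cv$cv, cv_ci = c(s$cv$ci_low, s$cv$ci_high),
    ci_level = s$cv$level,
    widths = list(fraction = s$widths$fraction,
                  mean_mm = s$widths$mean_width_mm,
                  sd_mm = s$widths$sd_width_mm),
    embryos_per_gfw = if (is.null(s$yield)) NULL
                      else s$yield$embryos_per_gfw,
    germination = if (is.null(s$germination)) NULL else {
      r <- germination_rates(s$germination)
      list(collected = s$germination$collected,
           started = s$germination$started,
           rooted = s$germination$rooted,
           pct_started = r$pct_started, pct_rooted = r$pct_rooted)
    }))
  jsonlite::write_json(
    list(seed = report$provenance$seed,
         package_version = report$provenance$package_version,
         warnings = report$warnings, groups = json),
    files$summary, auto_unbox = TRUE, digits = NA, null = "null")
  files
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("embryosync run report:", length(x$groups), "groups, seed",
      x$provenance$seed, "\n")
  for (s in x$groups)
    cat(sprintf(
      "  %-28s n=%5d  mean %.2f +/- %.2f mm  CV %.2f [%.2f, %.2f]\n",
      s$label, s$n, s$mean_length_mm, s$sd_length_mm,
      s$cv$cv, s$cv$ci_low, s$cv$ci_high))
  if (length(x$warnings))
    cat("warnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  invisible(x)
}

#' Compare dispersed vs non-dispersed treatments within a cell line
#'
#' Pooled (or Welch) two-sample t tests on embryo lengths and — when both
#' groups carry replicate counts — on per-replicate embryo counts, with
#' significance flags at the conventional alpha levels 0.01, 0.05 and 0.10.
#'
#' @param report A `run_report` from [run_study()].
#' @param cell_line,culture Select the matched pair of groups.
#' @param lengths_by_group Named list of the raw `length_sample`s used in
#'   the run (needed for the length-level test); if omitted, only the
#'   per-replicate count comparison is made.
#' @param alphas Significance levels to flag.
#' @return Data frame with one row per comparison: `quantity`, `t`, `df`,
#'   `p`, and one logical column per alpha (`sig_0.01`, ...).
#' @export
compare_treatments <- function(report, cell_line, culture,
                               lengths_by_group = NULL,
                               alphas = c(0.01, 0.05, 0.10)) {
  sel <- Filter(function(s) identical(s$cell_line, cell_line) &&
                  identical(s$culture, culture), report$groups)
  trts <- vapply(sel, function(s) s$treatment, character(1))
  if (!all(c("dispersed", "non_dispersed") %in% trts))
    stop("need both a 'dispersed' and a 'non_dispersed' group for ",
         cell_line, " / ", culture)
  d <- sel[[which(trts == "dispersed")[1]]]
  nd <- sel[[which(trts == "non_dispersed")[1]]]
  welch <- isTRUE(report$config$analysis$welch)
  rows <- list()
  if (!is.null(lengths_by_group)) {
    tt <- ttest_two_sample(lengths_by_group[[d$label]]$length_mm,
                           lengths_by_group[[nd$label]]$length_mm, welch)
    rows$length <- data.frame(quantity = "length_mm", t = tt$t, df = tt$df,
                              p = tt$p)
  }
  if (d$n_replicates >= 2 && nd$n_replicates >= 2 &&
      !(sd(d$per_replicate_n) == 0 && sd(nd$per_replicate_n) == 0 &&
        mean(d$per_replicate_n) != mean(nd$per_replicate_n))) {
    # degenerate case (constant counts, unequal means) has no finite t;
    # it arises for generated data with fixed per-replicate n and is skipped
    tt <- ttest_two_sample(d$per_replicate_n, nd$per_replicate_n, welch)
    rows$count <- data.frame(quantity = "embryos_per_replicate", t = tt$t,
                             df = tt$df, p = tt$p)
  }
  if (length(rows) == 0) stop("nothing to compare")
  out <- do.call(rbind, rows)
  for (a in alphas) out[[paste0("sig_", a)]] <- out$p < a
  rownames(out) <- NULL
  out
}
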
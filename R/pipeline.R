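#' Analyse a hut trial end to end
#'
#' Runs the full endpoint and inference pipeline on a set of hut-night
#' records: the arm summary table (entries, deaths, daily means/SDs,
#' mortality and trap-attributable percentages), the increased
#' killing-effect table in both formulations, Kruskal-Wallis tests with
#' Conover-Iman pairwise comparisons and significance letters on daily
#' entries and deaths, rank-sum tests of the candidate arm against every
#' other arm, and per-night mean death series for plotting.
#'
#' @param records Hut-night records data frame (see [read_records()] or
#'   [simulate_trial()]).
#' @param species_group Species group analysed (default `"an_gambiae"`);
#'   `NULL` pools species.
#' @param candidate_arm Candidate (trapping-net) arm label.
#' @param untreated_arm Untreated-control arm label (denominator of the
#'   control-adjusted killing effect); `NULL` to skip that variant.
#' @param alpha Significance level for letters and pairwise flags.
#' @param arms Optional arm display order.
#' @return An object of class `hut_trial_analysis` with components
#'   `summary`, `killing_effects` (list with `control_adjusted` and
#'   `methods`), `entry_test`, `death_test` (each: Kruskal-Wallis result,
#'   pairwise table, letters), `candidate_vs_rest` (rank-sum tests on
#'   daily deaths), and `daily_death` (night x arm mean matrix).
#' @export
#' @examples
#' d <- build_schedule(default_arms(), n_nights = 12, seed = 1)
#' rec <- simulate_trial(d, reference_trial_params(), seed = 7)
#' fit <- hut_trial_analysis(rec)
#' print(fit)
hut_trial_analysis <- function(records,
                               species_group = "an_gambiae",
                               candidate_arm = "T-LLIN",
                               untreated_arm = "control",
                               alpha = 0.05,
                               arms = NULL) {
  validate_records(records)
  arms <- arms %||% unique(records$arm)
  rec <- filter_records(records, species_group = species_group)
  summ <- summarize_arms(rec, arms = arms)

  if (!is.null(untreated_arm) && !untreated_arm %in% arms) {
    stop("lookup error: untreated arm '", untreated_arm,
         "' not in records", call. = FALSE)
  }
  ke <- list()
  if (candidate_arm %in% arms) {
    if (!is.null(untreated_arm)) {
      ke$control_adjusted <- killing_effect_table(
        summ, candidate_arm, untreated_arm = untreated_arm,
        variant = "control_adjusted")
    }
    ke$methods <- killing_effect_table(
      summ, candidate_arm,
      reference_arms = setdiff(arms, c(candidate_arm, untreated_arm)),
      variant = "methods")
  }

  # per-hut-night entry and death values grouped by arm
  hn_key <- paste(rec$night, rec$hut, sep = "\r")
  hn_arm <- rec$arm[!duplicated(hn_key)]
  names(hn_arm) <- hn_key[!duplicated(hn_key)]
  entry_hn <- tapply(total_entry(rec), hn_key, sum)
  death_hn <- tapply(death_count(rec), hn_key, sum)
  grp <- factor(hn_arm[names(entry_hn)], levels = arms)
  entry_groups <- split(as.numeric(entry_hn), grp)
  death_groups <- split(as.numeric(death_hn), grp)

  run_block <- function(groups) {
    if (length(groups) < 2L) {
      return(list(kruskal_wallis = NULL, pairwise = NULL,
                  letters = stats::setNames(rep("a", length(groups)),
                                            names(groups))))
    }
    kw <- kruskal_wallis(groups)
    pw <- conover_iman(groups, alpha = alpha)
    list(kruskal_wallis = kw, pairwise = pw,
         letters = compact_letter_display(pw))
  }
  entry_test <- run_block(entry_groups)
  death_test <- run_block(death_groups)

  others <- setdiff(arms, candidate_arm)
  cvr <- NULL
  if (candidate_arm %in% arms && length(others)) {
    cvr <- do.call(rbind, lapply(others, function(a) {
      ts <- rank_sum_test(death_groups[[candidate_arm]], death_groups[[a]])
      data.frame(arm = a, statistic = ts$statistic, p.value = ts$p.value,
                 method = ts$method, significant = ts$p.value < alpha,
                 stringsAsFactors = FALSE)
    }))
  }

  nights <- sort(unique(rec$night))
  daily <- sapply(arms, function(a) {
    ra <- rec[rec$arm == a, ]
    d <- tapply(death_count(ra), ra$night, sum)
    nh <- tapply(ra$hut, ra$night, function(h) length(unique(h)))
    out <- rep(NA_real_, length(nights))
    out[match(names(d), nights)] <- d / nh
    out
  })
  rownames(daily) <- nights

  structure(
    list(summary = summ,
         killing_effects = ke,
         entry_test = entry_test,
         death_test = death_test,
         candidate_vs_rest = cvr,
         daily_death = daily,
         species_group = species_group,
         candidate_arm = candidate_arm,
         untreated_arm = untreated_arm,
         alpha = alpha),
    class = "hut_trial_analysis"
  )
}

#' @export
print.hut_trial_analysis <- function(x, digits = 1, ...) {
  cat("Experimental hut trial analysis",
      if (!is.null(x$species_group)) paste0(" (", x$species_group, ")"),
      "\n\n", sep = "")
  s <- x$summary
  tab <- data.frame(
    arm = s$arm,
    `hut-nights` = s$n_hut_nights,
    entry = s$total_entry,
    `entry/night` = paste0(round(s$mean_daily_entry, digits),
                           x$entry_test$letters[s$arm]),
    death = s$total_death,
    `death/night` = paste0(round(s$mean_daily_death, digits),
                           x$death_test$letters[s$arm]),
    `mortality%` = round(s$mortality_pct, digits),
    `trap%` = round(s$trap_attributable_pct, digits),
    check.names = FALSE)
  print(tab, row.names = FALSE)
  cat("\nLetters: arms not sharing a letter differ (Conover-Iman,",
      "Bonferroni, alpha =", x$alpha, ")\n")
  for (v in names(x$killing_effects)) {
    ke <- x$killing_effects[[v]]
    if (nrow(ke)) {
      cat("\nIncreased killing effect of", x$candidate_arm,
          paste0("(", v, "):"), "\n")
      for (i in seq_len(nrow(ke))) {
        cat(sprintf("  vs %-8s %6.1f%%\n", ke$reference_arm[i],
                    ke$value_pct[i]))
      }
    }
  }
  invisible(x)
}

#' @export
summary.hut_trial_analysis <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$candidate_vs_rest)) {
    cat("\nRank-sum tests of daily deaths,", object$candidate_arm,
        "vs each arm:\n")
    print(object$candidate_vs_rest, row.names = FALSE)
  }
  invisible(object)
}

#' Plot a hut trial analysis
#'
#' Two base-graphics panels: per-arm daily mean deaths over the trial
#' nights, and a barplot of the increased killing effects of the
#' candidate arm.
#'
#' @param x A `hut_trial_analysis`.
#' @param which `"daily"`, `"killing"` or both.
#' @param ... Passed to [graphics::matplot()] / [graphics::barplot()].
#' @export
plot.hut_trial_analysis <- function(x, which = c("daily", "killing"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (length(which) > 1) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op))
  }
  if ("daily" %in% which) {
    graphics::matplot(as.numeric(rownames(x$daily_death)), x$daily_death,
                      type = "l", lty = 1, xlab = "night",
                      ylab = "mean deaths per hut", ...)
    graphics::legend("topright", legend = colnames(x$daily_death),
                     lty = 1, col = seq_len(ncol(x$daily_death)),
                     cex = 0.8, bty = "n")
  }
  if ("killing" %in% which && length(x$killing_effects)) {
    ke <- x$killing_effects[[1]]
    if (nrow(ke)) {
      graphics::barplot(ke$value_pct, names.arg = ke$reference_arm,
                        ylab = paste0("increased killing effect of ",
                                      x$candidate_arm, " (%)"), ...)
    }
  }
  invisible(x)
}

#' Run the pipeline from files or a simulation and write a report
#'
#' Either reads a records CSV or simulates a trial from a design/params
#' configuration, analyses it, and (optionally) writes the summary
#' table, killing-effect tables, pairwise test results and a plain-text
#' report to an output directory. Outputs are deterministic given the
#' inputs and seed.
#'
#' @param records_path Path to a records CSV (exclusive with
#'   `sim_params`).
#' @param sim_params A `simulation_params` (or path to a params YAML) to
#'   simulate from.
#' @param design A `trial_design`; defaults to
#'   `build_schedule(params$arms)` when simulating.
#' @param seed Seed for simulation.
#' @param out_dir Optional output directory (created if needed).
#' @param ... Passed to [hut_trial_analysis()].
#' @return The `hut_trial_analysis`, invisibly; with attribute `files`
#'   naming anything written.
#' @export
run_pipeline <- function(records_path = NULL, sim_params = NULL,
                         design = NULL, seed = NULL, out_dir = NULL, ...) {
  if (is.null(records_path) == is.null(sim_params)) {
    stop("config error: supply exactly one of 'records_path' or ",
         "'sim_params'", call. = FALSE)
  }
  if (!is.null(records_path)) {
    records <- read_records(records_path)
  } else {
    if (is.character(sim_params)) sim_params <- read_params_config(sim_params)
    if (!inherits(sim_params, "simulation_params")) {
      stop("config error: 'sim_params' must be a simulation_params or a ",
           "YAML path", call. = FALSE)
    }
    design <- design %||% build_schedule(sim_params$arms,
                                         seed = seed %||% 1L)
    records <- simulate_trial(design, sim_params, seed = seed)
  }
  fit <- hut_trial_analysis(records, ...)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.csv(df, p, row.names = FALSE)
      files <<- c(files, p)
    }
    wr(fit$summary, "arm_summary.csv")
    for (v in names(fit$killing_effects)) {
      wr(fit$killing_effects[[v]], paste0("killing_effect_", v, ".csv"))
    }
    wr(fit$death_test$pairwise, "death_pairwise.csv")
    wr(fit$entry_test$pairwise, "entry_pairwise.csv")
    if (!is.null(fit$candidate_vs_rest)) {
      wr(fit$candidate_vs_rest, "candidate_vs_rest.csv")
    }
    p <- file.path(out_dir, "records.csv")
    write_records(records, p)
    files <- c(files, p)
    rp <- file.path(out_dir, "report.txt")
    txt <- utils::capture.output(summary(fit))
    writeLines(txt, rp)
    files <- c(files, rp)
  }
  attr(fit, "files") <- files
  invisible(fit)
}
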
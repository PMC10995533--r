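#' Mosquitoes counted as killed in a record
#'
#' Trial mortality counts every trapped mosquito as killed, even when it
#' was alive at collection (a trapped mosquito dies of insecticide,
#' starvation or desiccation and is removed from the biting population),
#' together with immediate and delayed insecticide deaths:
#' `trapped + dead_untrapped + alive_delayed_dead`.
#'
#' @param counts Data frame (or one-row list) with the fate-count columns.
#' @return Integer vector of death counts, one per row.
#' @export
#' @examples
#' death_count(data.frame(trapped = 4, dead_untrapped = 3,
#'                        alive_delayed_dead = 1, alive_survived = 2))
death_count <- function(counts) {
  as.integer(counts[["trapped"]] + counts[["dead_untrapped"]] +
               counts[["alive_delayed_dead"]])
}

#' Summarise one arm of a hut trial
#'
#' Aggregates records to per-hut-night entry and death values, then
#' reports totals, daily means and standard deviations (denominator
#' n - 1) over hut-nights, the mortality percentage
#' (100 x deaths / entries) and the trap-attributable share of mortality
#' (100 x trapped / deaths; 0 when there are no deaths). Hut-nights
#' present in the records with zero catch count as real observation
#' nights.
#'
#' @param records Records data frame.
#' @param arm Arm label to summarise.
#' @param species_group Optional species group restriction
#'   (`"an_gambiae"` or `"other"`); `NULL` pools both.
#' @return A one-row data frame (an arm summary: the row of a Table-1
#'   style summary).
#' @export
summarize_arm <- function(records, arm, species_group = NULL) {
  rec <- filter_records(records, species_group = species_group, arm = arm)
  if (nrow(rec) == 0) {
    stop("empty-data error: no hut-nights for arm '", arm, "'",
         call. = FALSE)
  }
  entry <- total_entry(rec)
  death <- death_count(rec)
  hn <- paste(rec$night, rec$hut, sep = "\r")
  entry_hn <- tapply(entry, hn, sum)
  death_hn <- tapply(death, hn, sum)
  trapped_hn <- tapply(rec$trapped, hn, sum)
  n <- length(entry_hn)
  tot_entry <- sum(entry_hn)
  tot_death <- sum(death_hn)
  tot_trapped <- sum(trapped_hn)
  data.frame(
    arm = arm,
    n_hut_nights = n,
    total_entry = tot_entry,
    mean_daily_entry = tot_entry / n,
    sd_daily_entry = if (n > 1) stats::sd(entry_hn) else 0,
    total_death = tot_death,
    mean_daily_death = tot_death / n,
    sd_daily_death = if (n > 1) stats::sd(death_hn) else 0,
    mortality_pct = if (tot_entry > 0) 100 * tot_death / tot_entry else 0,
    trapped_total = tot_trapped,
    trap_attributable_pct =
      if (tot_death > 0) 100 * tot_trapped / tot_death else 0,
    stringsAsFactors = FALSE
  )
}

#' Summarise all arms of a hut trial
#'
#' @param records Records data frame.
#' @param arms Arm labels in display order; defaults to order of first
#'   appearance in the records.
#' @inheritParams summarize_arm
#' @return Data frame with one [summarize_arm()] row per arm.
#' @export
summarize_arms <- function(records, arms = NULL, species_group = NULL) {
  arms <- arms %||% unique(records$arm)
  if (inherits(arms[[1]], "hut_arm")) arms <- arm_names(arms)
  out <- do.call(rbind, lapply(arms, summarize_arm, records = records,
                               species_group = species_group))
  rownames(out) <- NULL
  out
}

new_killing_effect <- function(candidate_arm, reference_arm, variant,
                               k_candidate, k_reference,
                               t_reference = NA_real_,
                               k_untreated = NA_real_,
                               t_untreated = NA_real_, value_pct) {
  data.frame(candidate_arm = candidate_arm, reference_arm = reference_arm,
             variant = variant, k_candidate = k_candidate,
             k_reference = k_reference, t_reference = t_reference,
             k_untreated = k_untreated, t_untreated = t_untreated,
             value_pct = value_pct, stringsAsFactors = FALSE)
}

#' Increased killing effect, reference-catch formulation
#'
#' The excess number of mosquitoes killed by the candidate net over a
#' reference net, as a percentage of the total catch of the reference
#' arm: `100 * (k_candidate - k_reference) / t_reference`. May be
#' negative when the candidate kills fewer mosquitoes.
#'
#' @param k_candidate Mosquitoes killed in the candidate (trapping-net)
#'   huts.
#' @param k_reference Mosquitoes killed in the reference-net huts.
#' @param t_reference Total mosquitoes collected from the reference-net
#'   huts (must be > 0).
#' @param candidate_arm,reference_arm Optional arm labels carried in the
#'   result.
#' @return A one-row killing-effect data frame with the inputs, the
#'   variant and `value_pct`.
#' @seealso [killing_effect_control_adjusted()] for the variant that
#'   scales by the untreated-control catch.
#' @export
#' @examples
#' killing_effect_methods(678, 413, 509)$value_pct  # 52.06
killing_effect_methods <- function(k_candidate, k_reference, t_reference,
                                   candidate_arm = NA_character_,
                                   reference_arm = NA_character_) {
  if (!is.numeric(t_reference) || t_reference <= 0) {
    stop("division-domain error: `t_reference` must be > 0", call. = FALSE)
  }
  new_killing_effect(candidate_arm, reference_arm, "methods",
                     k_candidate, k_reference, t_reference = t_reference,
                     value_pct = 100 * (k_candidate - k_reference) /
                       t_reference)
}

#' Increased killing effect, control-adjusted formulation
#'
#' Subtracts the untreated-control kill from both the candidate and the
#' reference kill and scales by the untreated-control catch:
#' `100 * ((k_candidate - k_untreated) - (k_reference - k_untreated)) /
#' t_untreated`. The control kill cancels algebraically, so the value
#' equals `100 * (k_candidate - k_reference) / t_untreated`; the shared
#' denominator makes values comparable across reference nets.
#'
#' @inheritParams killing_effect_methods
#' @param k_untreated Mosquitoes killed in the untreated-control huts.
#' @param t_untreated Total mosquitoes collected from the
#'   untreated-control huts (must be > 0).
#' @return A one-row killing-effect data frame.
#' @export
#' @examples
#' killing_effect_control_adjusted(678, 413, 118, 450)$value_pct  # 58.89
killing_effect_control_adjusted <- function(k_candidate, k_reference,
                                            k_untreated, t_untreated,
                                            candidate_arm = NA_character_,
                                            reference_arm = NA_character_) {
  if (!is.numeric(t_untreated) || t_untreated <= 0) {
    stop("division-domain error: `t_untreated` must be > 0", call. = FALSE)
  }
  value <- 100 * ((k_candidate - k_untreated) -
                    (k_reference - k_untreated)) / t_untreated
  new_killing_effect(candidate_arm, reference_arm, "control_adjusted",
                     k_candidate, k_reference,
                     k_untreated = k_untreated, t_untreated = t_untreated,
                     value_pct = value)
}

#' Killing-effect table over reference arms
#'
#' Computes the increased killing effect of the candidate arm over each
#' reference arm from arm summaries, using total deaths as the kill
#' counts and total entries as the catches.
#'
#' @param summaries Output of [summarize_arms()].
#' @param candidate_arm Candidate arm label.
#' @param reference_arms Labels of the reference arms; defaults to every
#'   arm except the candidate and the untreated control.
#' @param untreated_arm Untreated-control arm label (required for the
#'   control-adjusted variant).
#' @param variant `"control_adjusted"` (default) or `"methods"`.
#' @return Data frame with one killing-effect row per reference arm.
#' @export
killing_effect_table <- function(summaries, candidate_arm,
                                 reference_arms = NULL,
                                 untreated_arm = NULL,
                                 variant = c("control_adjusted", "methods")) {
  variant <- match.arg(variant)
  row_of <- function(a) {
    i <- match(a, summaries$arm)
    if (is.na(i)) stop("lookup error: arm '", a, "' not in summaries",
                       call. = FALSE)
    summaries[i, ]
  }
  cand <- row_of(candidate_arm)
  reference_arms <- reference_arms %||%
    setdiff(summaries$arm, c(candidate_arm, untreated_arm))
  if (!length(reference_arms)) {
    return(new_killing_effect(character(0), character(0), character(0),
                              numeric(0), numeric(0), numeric(0),
                              numeric(0), numeric(0), numeric(0)))
  }
  if (variant == "control_adjusted") {
    if (is.null(untreated_arm)) {
      stop("lookup error: `untreated_arm` required for the ",
           "control-adjusted variant", call. = FALSE)
    }
    un <- row_of(untreated_arm)
  }
  out <- lapply(reference_arms, function(a) {
    ref <- row_of(a)
    if (variant == "methods") {
      killing_effect_methods(cand$total_death, ref$total_death,
                             ref$total_entry,
                             candidate_arm = candidate_arm,
                             reference_arm = a)
    } else {
      killing_effect_control_adjusted(cand$total_death, ref$total_death,
                                      un$total_death, un$total_entry,
                                      candidate_arm = candidate_arm,
                                      reference_arm = a)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
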
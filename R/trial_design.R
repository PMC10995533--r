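#' Define a treatment arm of an experimental hut trial
#'
#' An arm is one bednet treatment under evaluation, deployed as one or more
#' physical net instances (replicates), each occupying one hut per night.
#'
#' @param name Short unique label, e.g. `"T-LLIN"` or `"control"`.
#' @param treatment_class One of `"untreated"`, `"pyrethroid"`,
#'   `"pyrethroid+PBO"`, `"pyrethroid+pyrrole"`.
#' @param has_trap_compartment Logical; `TRUE` for hybrid trapping nets that
#'   carry an insecticide-free upper trap compartment.
#' @param n_replicate_nets Number of physical net instances (>= 1); each
#'   replicate occupies its own hut every night.
#'
#' @return An object of class `hut_arm`.
#' @seealso [default_arms()], [build_schedule()]
#' @export
#' @examples
#' hut_arm("T-LLIN", "pyrethroid", has_trap_compartment = TRUE,
#'         n_replicate_nets = 2)
hut_arm <- function(name,
                    treatment_class = c("untreated", "pyrethroid",
                                        "pyrethroid+PBO",
                                        "pyrethroid+pyrrole"),
                    has_trap_compartment = FALSE,
                    n_replicate_nets = 1L) {
  treatment_class <- match.arg(treatment_class)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (!is_count(n_replicate_nets) || n_replicate_nets < 1) {
    stop("`n_replicate_nets` must be a positive integer", call. = FALSE)
  }
  structure(
    list(name = name,
         treatment_class = treatment_class,
         has_trap_compartment = isTRUE(has_trap_compartment),
         n_replicate_nets = as.integer(n_replicate_nets)),
    class = "hut_arm"
  )
}

#' Standard five-arm layout of a trapping-bednet hut trial
#'
#' Three WHO-recommended positive controls (a pyrethroid-only net, a
#' pyrethroid+PBO net, a chlorfenapyr+pyrethroid net), one untreated
#' negative control, and the candidate hybrid trapping net, each deployed
#' in two replicate huts (10 huts total).
#'
#' @return A list of five [hut_arm()] objects.
#' @export
default_arms <- function() {
  list(
    hut_arm("IG2", "pyrethroid+pyrrole", n_replicate_nets = 2L),
    hut_arm("Tsara", "pyrethroid+PBO", n_replicate_nets = 2L),
    hut_arm("PN2.0", "pyrethroid", n_replicate_nets = 2L),
    hut_arm("T-LLIN", "pyrethroid", has_trap_compartment = TRUE,
            n_replicate_nets = 2L),
    hut_arm("control", "untreated", n_replicate_nets = 2L)
  )
}

arm_names <- function(arms) vapply(arms, `[[`, character(1), "name")

check_arms <- function(arms) {
  if (!is.list(arms) || !length(arms) ||
      !all(vapply(arms, inherits, logical(1), "hut_arm"))) {
    stop("`arms` must be a non-empty list of `hut_arm` objects",
         call. = FALSE)
  }
  nm <- arm_names(arms)
  if (anyDuplicated(nm)) {
    stop("arm names must be unique; duplicated: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  invisible(arms)
}

#' Generate a random Latin square
#'
#' Produces an n x n matrix of the symbols `1:n` in which every symbol
#' occurs exactly once in each row and each column, by applying random
#' row, column and symbol permutations to the cyclic square. Used to
#' rotate net positions across huts.
#'
#' @param n Side length (positive integer).
#' @param seed Optional integer; the square is deterministic given `seed`.
#' @return An `n` x `n` integer matrix.
#' @export
#' @examples
#' latin_square(4, seed = 1)
latin_square <- function(n, seed = NULL) {
  if (!is_count(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  base <- outer(seq_len(n), seq_len(n), function(i, j) (i + j - 2L) %% n + 1L)
  with_seed(seed, {
    rows <- sample.int(n)
    cols <- sample.int(n)
    syms <- sample.int(n)
    matrix(syms[base[rows, cols, drop = FALSE]], n, n)
  })
}

#' Build the rotation schedule of an experimental hut trial
#'
#' Assigns one sleeper and one net (hence one arm) to every hut on every
#' night. Sleepers rotate through huts by a daily cyclic shift; physical
#' net instances move between huts every `net_rotation_period_nights`
#' nights, following rows of a random Latin square so that over a full
#' cycle each net instance visits each hut exactly once.
#'
#' @param arms List of [hut_arm()] objects; their replicate counts must sum
#'   to the number of huts.
#' @param n_nights Number of trial nights (default 34, roughly a six-week
#'   trial with a 10-hut rotation).
#' @param net_rotation_period_nights Nights between net moves (default 3).
#' @param seed Integer seed; the schedule is deterministic given it.
#' @param n_huts Number of huts; defaults to the summed replicate counts.
#'
#' @return An object of class `trial_design`: a list with the arms, the
#'   dimensions, and a `schedule` data frame with columns
#'   `night, hut, sleeper, arm, net_id` (one row per hut-night).
#' @export
#' @examples
#' d <- build_schedule(default_arms(), n_nights = 12, seed = 1)
#' head(as.data.frame(d))
build_schedule <- function(arms,
                           n_nights = 34L,
                           net_rotation_period_nights = 3L,
                           seed = 1L,
                           n_huts = NULL) {
  check_arms(arms)
  if (!is_count(n_nights) || n_nights < 1) {
    stop("`n_nights` must be a positive integer", call. = FALSE)
  }
  if (!is_count(net_rotation_period_nights) ||
      net_rotation_period_nights < 1) {
    stop("`net_rotation_period_nights` must be a positive integer",
         call. = FALSE)
  }
  reps <- vapply(arms, `[[`, integer(1), "n_replicate_nets")
  n_huts <- as.integer(n_huts %||% sum(reps))
  if (sum(reps) != n_huts) {
    stop("design inconsistency: arm replicate counts (",
         sum(reps), ") must sum to `n_huts` (", n_huts, ")", call. = FALSE)
  }
  n_nights <- as.integer(n_nights)
  period <- as.integer(net_rotation_period_nights)

  # net instance i belongs to arm net_arm[i]
  net_arm <- rep(arm_names(arms), times = reps)
  sq <- latin_square(n_huts, seed = seed)

  night <- rep(seq_len(n_nights), each = n_huts)
  hut <- rep(seq_len(n_huts), times = n_nights)
  block_row <- ((night - 1L) %/% period) %% n_huts + 1L
  net_id <- sq[cbind(block_row, hut)]
  sleeper <- (hut - night) %% n_huts + 1L

  schedule <- data.frame(
    night = night,
    hut = hut,
    sleeper = sleeper,
    arm = net_arm[net_id],
    net_id = net_id,
    stringsAsFactors = FALSE
  )
  structure(
    list(arms = arms,
         n_huts = n_huts,
         n_sleepers = n_huts,
         n_nights = n_nights,
         net_rotation_period_nights = period,
         seed = seed,
         schedule = schedule),
    class = "trial_design"
  )
}

#' @export
as.data.frame.trial_design <- function(x, ...) x$schedule

#' @export
print.trial_design <- function(x, ...) {
  cat("Experimental hut trial design\n")
  cat(sprintf("  %d arms (%s)\n", length(x$arms),
              paste(arm_names(x$arms), collapse = ", ")))
  cat(sprintf("  %d huts, %d sleepers, %d nights; nets rotate every %d nights\n",
              x$n_huts, x$n_sleepers, x$n_nights,
              x$net_rotation_period_nights))
  v <- validate_schedule(x)
  cat(if (length(v)) sprintf("  INVALID: %d violation(s)\n", length(v))
      else "  schedule valid\n")
  invisible(x)
}

#' Check a trial design against its rotation invariants
#'
#' Validation never raises: it returns a character vector of violations,
#' empty when the schedule is consistent. Checked invariants: replicate
#' counts sum to the hut count; each night every hut holds exactly one
#' sleeper and one arm and every sleeper occupies exactly one hut; an
#' arm's hut assignment changes only on rotation-period boundaries; within
#' a full rotation cycle no net instance (or, if net identities are
#' absent, no arm slot) revisits a hut.
#'
#' @param design A `trial_design` object.
#' @return Character vector of violation messages (empty if valid).
#' @export
validate_schedule <- function(design) {
  out <- character(0)
  say <- function(...) out <<- c(out, sprintf(...))
  s <- design$schedule
  n_huts <- design$n_huts
  period <- design$net_rotation_period_nights

  reps <- vapply(design$arms, `[[`, integer(1), "n_replicate_nets")
  if (sum(reps) != n_huts) {
    say("arm replicate counts sum to %d, not n_huts = %d", sum(reps), n_huts)
  }

  for (t in sort(unique(s$night))) {
    st <- s[s$night == t, ]
    if (anyDuplicated(st$hut) || !setequal(st$hut, seq_len(n_huts))) {
      say("night %d: huts are not each occupied exactly once", t)
    }
    if (anyDuplicated(st$sleeper) ||
        !setequal(st$sleeper, seq_len(design$n_sleepers))) {
      say("night %d: sleepers do not each occupy exactly one hut", t)
    }
  }

  # arm changes only on rotation boundaries
  for (h in seq_len(n_huts)) {
    sh <- s[s$hut == h, ]
    sh <- sh[order(sh$night), ]
    chg <- which(sh$arm[-1] != sh$arm[-nrow(sh)])
    bad <- sh$night[chg + 1L]
    bad <- bad[(bad - 1L) %% period != 0L]
    for (t in bad) say("night %d: hut %d changes arm off-rotation", t, h)
  }

  # within each full cycle of n_huts blocks a net instance must not
  # revisit a hut; when net identities are absent the check degrades to
  # the arm level, where up to n_replicate_nets visits per hut are
  # legitimate (sibling nets of one arm may cover the same hut in
  # different blocks)
  has_net <- "net_id" %in% names(s)
  key <- if (has_net) as.character(s$net_id) else s$arm
  allowed <- if (has_net) {
    function(k) 1L
  } else {
    rp <- stats::setNames(reps, arm_names(design$arms))
    function(k) rp[[k]] %||% 1L
  }
  blk <- (s$night - 1L) %/% period
  per_block <- unique(data.frame(block = blk, cycle = blk %/% n_huts,
                                 key = key, hut = s$hut,
                                 stringsAsFactors = FALSE))
  visits <- table(paste(per_block$cycle, per_block$key, per_block$hut,
                        sep = "\r"))
  for (v in names(visits)) {
    parts <- strsplit(v, "\r", fixed = TRUE)[[1]]
    if (visits[[v]] > allowed(parts[2])) {
      say("rotation coverage: '%s' occupies hut %s more than %d time(s) in cycle %s",
          parts[2], parts[3], allowed(parts[2]), parts[1])
    }
  }
  out
}

#' Write or read a rotation schedule as CSV
#'
#' The CSV has columns `night,hut,sleeper,arm` with 1-based night indices.
#' `read_schedule()` rebuilds a `trial_design` from such a file plus the
#' arm definitions (net identities are not stored in the CSV).
#'
#' @param design A `trial_design`.
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `trial_design`.
#' @export
write_schedule <- function(design, path) {
  utils::write.csv(design$schedule[c("night", "hut", "sleeper", "arm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @param arms List of [hut_arm()] objects matching the arm labels in the
#'   file.
#' @param net_rotation_period_nights Rotation period of the stored design.
#' @export
read_schedule <- function(path, arms,
                          net_rotation_period_nights = 3L) {
  check_arms(arms)
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("night", "hut", "sleeper", "arm")
  if (!all(need %in% names(s))) {
    stop("schedule file must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  structure(
    list(arms = arms,
         n_huts = length(unique(s$hut)),
         n_sleepers = length(unique(s$sleeper)),
         n_nights = max(s$night),
         net_rotation_period_nights = as.integer(net_rotation_period_nights),
         seed = NA_integer_,
         schedule = s[order(s$night, s$hut), need]),
    class = "trial_design"
  )
}

#' Read a trial design from a YAML configuration file
#'
#' The file names the arms (each with `name`, `treatment_class`, optional
#' `has_trap_compartment` and `n_replicate_nets`), plus `n_nights`,
#' `net_rotation_period_nights` and `seed`.
#'
#' @param path YAML file path.
#' @return A `trial_design` built by [build_schedule()].
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$arms)) stop("config error: missing key 'arms'", call. = FALSE)
  arms <- lapply(cfg$arms, function(a) {
    if (is.null(a$name)) stop("config error: arm without 'name'", call. = FALSE)
    hut_arm(a$name,
            a$treatment_class %||% "untreated",
            a$has_trap_compartment %||% FALSE,
            a$n_replicate_nets %||% 1L)
  })
  build_schedule(arms,
                 n_nights = cfg$n_nights %||% 34L,
                 net_rotation_period_nights =
                   cfg$net_rotation_period_nights %||% 3L,
                 seed = cfg$seed %||% 1L)
}
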
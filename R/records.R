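#' @name hut_records
#' @title Hut-night collection records
#'
#' @description
#' The unit of observation is one hut on one night, stratified by species
#' group. Records are kept as a plain data frame with columns
#'
#' * `night` — positive integer night index,
#' * `hut`, `sleeper` — identifiers,
#' * `arm` — treatment arm label,
#' * `species_group` — `"an_gambiae"` or `"other"`,
#' * `trapped` — mosquitoes found in the net's trap compartment (counted
#'   as killed regardless of status),
#' * `dead_untrapped` — found dead in the room or window traps,
#' * `alive_delayed_dead` — collected alive but dead after the 24-36 h
#'   holding period,
#' * `alive_survived` — collected alive and still alive after holding.
#'
#' The total hut entry of a record is the sum of its four fate counts.
NULL

RECORD_COLUMNS <- c("night", "hut", "sleeper", "arm", "species_group",
                    "trapped", "dead_untrapped", "alive_delayed_dead",
                    "alive_survived")
FATE_COLUMNS <- c("trapped", "dead_untrapped", "alive_delayed_dead",
                  "alive_survived")
SPECIES_GROUPS <- c("an_gambiae", "other")

#' Validate hut-night records
#'
#' Checks the schema, count non-negativity, species-group labels,
#' uniqueness of (night, hut, species_group) and, when arms are supplied,
#' arm membership. Problems are reported with the offending row numbers.
#'
#' @param records Data frame of hut-night records.
#' @param arms Optional list of [hut_arm()] objects to check arm labels
#'   against.
#' @return The records, invisibly, if valid; otherwise an error.
#' @export
validate_records <- function(records, arms = NULL) {
  if (!is.data.frame(records)) {
    stop("records must be a data frame", call. = FALSE)
  }
  missing_cols <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0) return(invisible(records))
  for (col in FATE_COLUMNS) {
    v <- records[[col]]
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      stop("validation error: column '", col,
           "' has negative or non-integer count at row ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  bad_sp <- which(!records$species_group %in% SPECIES_GROUPS)
  if (length(bad_sp)) {
    stop("validation error: unknown species_group at row ",
         paste(bad_sp, collapse = ", "), call. = FALSE)
  }
  bad_night <- which(!is.finite(records$night) | records$night < 1 |
                       records$night != floor(records$night))
  if (length(bad_night)) {
    stop("validation error: invalid night index at row ",
         paste(bad_night, collapse = ", "), call. = FALSE)
  }
  key <- paste(records$night, records$hut, records$species_group, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("validation error: duplicate (night, hut, species_group) at row ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!is.null(arms)) {
    known <- arm_names(arms)
    bad_arm <- which(!records$arm %in% known)
    if (length(bad_arm)) {
      stop("validation error: unknown arm at row ",
           paste(bad_arm, collapse = ", "), call. = FALSE)
    }
  }
  invisible(records)
}

#' Total hut entry per record
#'
#' @param records Data frame with the four fate-count columns.
#' @return Integer vector: the sum of the four fate counts per row.
#' @export
total_entry <- function(records) {
  as.integer(rowSums(records[FATE_COLUMNS]))
}

#' Read hut-night records from CSV
#'
#' The file must carry the documented header
#' `night,hut,sleeper,arm,species_group,trapped,dead_untrapped,alive_delayed_dead,alive_survived`.
#' Rows failing validation are reported with their row numbers.
#'
#' @param path CSV file path.
#' @param arms Optional arm list for arm-label validation.
#' @return A validated records data frame.
#' @export
read_records <- function(path, arms = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_records(rec, arms = arms)
  rec[RECORD_COLUMNS]
}

#' Write hut-night records to CSV
#'
#' Output is canonical: fixed column order and rows sorted by
#' (night, hut, species_group), so two permutations of the same records
#' produce byte-identical files.
#'
#' @param records Validated records data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  validate_records(records)
  rec <- records[order(records$night, records$hut, records$species_group),
                 RECORD_COLUMNS, drop = FALSE]
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter hut-night records
#'
#' Subsets by species group, arm and/or an inclusive night range; filters
#' compose as set intersection and preserve row order.
#'
#' @param records Records data frame.
#' @param species_group Optional species group to keep.
#' @param arm Optional arm label(s) to keep; an unknown label is an error.
#' @param nights Optional length-2 inclusive night range `c(from, to)`.
#' @return The filtered records.
#' @export
filter_records <- function(records, species_group = NULL, arm = NULL,
                           nights = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(species_group)) {
    species_group <- match.arg(species_group, SPECIES_GROUPS, several.ok = TRUE)
    keep <- keep & records$species_group %in% species_group
  }
  if (!is.null(arm)) {
    unknown <- setdiff(arm, unique(records$arm))
    if (length(unknown)) {
      stop("lookup error: unknown arm(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    keep <- keep & records$arm %in% arm
  }
  if (!is.null(nights)) {
    if (length(nights) != 2L) {
      stop("`nights` must be an inclusive range c(from, to)", call. = FALSE)
    }
    keep <- keep & records$night >= nights[1] & records$night <= nights[2]
  }
  records[keep, , drop = FALSE]
}
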
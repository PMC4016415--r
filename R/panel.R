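#' Construct a person-year panel
#'
#' A person-year panel holds one health-state observation per person per
#' calendar year: columns `person_id`, `year`, `gender` (`"F"`/`"M"`),
#' `age` (completed years), `state` (one of [health_states()]), and an
#' optional `cost` column with the annual healthcare cost in euros.
#'
#' Validation enforces the panel invariants: at most one record per
#' (person, year); ages and years co-increment (for consecutive records of
#' one person, both advance by exactly 1); death is terminal (no record
#' after a `DEAD` record). Gaps in a person's year sequence are allowed —
#' they represent censoring by migration — and are counted in the
#' validation report attached as the `"validation"` attribute.
#'
#' @param records data.frame with the columns above.
#' @return An object of class `py_panel` (a validated data.frame, sorted by
#'   person and year) with a `"validation"` attribute.
#' @seealso [read_panel()], [write_panel()], [validate_panel()]
#' @export
person_year_panel <- function(records) {
  required <- c("person_id", "year", "gender", "age", "state")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$person_id <- as.character(records$person_id)
  records$year <- as.integer(records$year)
  records$gender <- as.character(records$gender)
  records$age <- as.integer(records$age)
  records$state <- as.character(records$state)
  if (nrow(records)) {
    gender_index(records$gender)   # errors on unknown labels
    state_index(records$state)
    if (any(is.na(records$year)) || any(is.na(records$age))) {
      stop("year and age must be integral and non-missing")
    }
    if (any(records$age < 0)) stop("negative age in panel")
    if ("cost" %in% names(records)) {
      records$cost <- as.numeric(records$cost)
      if (any(!is.na(records$cost) & records$cost < 0)) {
        stop("negative cost in panel")
      }
    }
  }
  records <- records[order(records$person_id, records$year), , drop = FALSE]
  rownames(records) <- NULL
  report <- validate_panel(records)
  fatal <- report[report$severity == "error", , drop = FALSE]
  if (nrow(fatal)) {
    stop("invalid panel: ", paste(fatal$message, collapse = "; "))
  }
  structure(records, class = c("py_panel", "data.frame"),
            validation = report)
}

#' Validate person-year panel records
#'
#' Side-effect-free check of the panel invariants. Fatal problems
#' (duplicate (person, year) keys, records after death, age/year
#' co-increment violations) are reported with severity `"error"`;
#' year gaps (censoring by migration) with severity `"note"`.
#'
#' @param records a data.frame of person-year records, sorted or not.
#' @return data.frame with columns `severity`, `person_id`, `message`
#'   (zero rows if the panel is clean and gap-free).
#' @export
validate_panel <- function(records) {
  issues <- list()
  add <- function(severity, person_id, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, person_id = person_id, message = message,
      stringsAsFactors = FALSE)
  }
  if (nrow(records)) {
    records <- records[order(records$person_id, records$year), , drop = FALSE]
    key <- paste(records$person_id, records$year, sep = "\r")
    dup <- duplicated(key)
    for (k in unique(records$person_id[dup])) {
      add("error", k, sprintf("duplicate (person, year) record for person %s", k))
    }
    # per-person sequential checks, vectorized over adjacent row pairs
    same_person <- records$person_id[-1L] == records$person_id[-nrow(records)]
    if (any(same_person)) {
      dy <- records$year[-1L] - records$year[-nrow(records)]
      da <- records$age[-1L] - records$age[-nrow(records)]
      consec <- same_person & dy == 1L
      bad_age <- consec & da != 1L
      for (k in unique(records$person_id[-1L][bad_age])) {
        add("error", k,
            sprintf("age does not advance with year for person %s", k))
      }
      gap <- same_person & dy > 1L
      for (k in unique(records$person_id[-1L][gap])) {
        add("note", k, sprintf("year gap (censoring) for person %s", k))
      }
    }
    dead <- records$state == "DEAD"
    if (any(dead)) {
      # any record for the same person after a DEAD record is fatal
      idx_dead <- which(dead)
      nxt <- idx_dead + 1L
      after <- nxt <= nrow(records) &
        records$person_id[pmin(nxt, nrow(records))] == records$person_id[idx_dead]
      for (k in unique(records$person_id[idx_dead][after])) {
        add("error", k, sprintf("record after DEAD for person %s", k))
      }
    }
  }
  if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(severity = character(0), person_id = character(0),
               message = character(0), stringsAsFactors = FALSE)
  }
}

#' @export
print.py_panel <- function(x, ...) {
  yrs <- sort(unique(x$year))
  cat(sprintf("person-year panel: %d records, %d persons, years %s\n",
              nrow(x), length(unique(x$person_id)),
              if (length(yrs)) paste(range(yrs), collapse = "-") else "(none)"))
  report <- attr(x, "validation")
  if (!is.null(report) && nrow(report)) {
    cat(sprintf("  %d validation note(s)\n", nrow(report)))
  }
  print(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat(sprintf("  ... %d more records\n", nrow(x) - 8L))
  invisible(x)
}

#' Years present in a panel
#'
#' @param panel a `py_panel`.
#' @return Sorted integer vector of calendar years with observations.
#' @export
panel_years <- function(panel) {
  sort(unique(panel$year))
}

#' Read a person-year panel from CSV
#'
#' The file dialect is comma-separated UTF-8 with a header row naming the
#' columns `person_id, year, gender, age, state` (and optionally `cost`,
#' euros with `.` decimal separator). The returned panel has passed full
#' validation; files violating a panel invariant are rejected with the
#' offending person named in the error message.
#'
#' @param path path to the CSV file.
#' @return A [person_year_panel()].
#' @export
read_panel <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(person_id = "character"),
                             fileEncoding = "UTF-8")
  person_year_panel(records)
}

#' Write a person-year panel to CSV
#'
#' Inverse of [read_panel()]: the written file reads back to an identical
#' record set. Costs are written with 2 decimals.
#'
#' @param panel a `py_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- as.data.frame(panel)
  if ("cost" %in% names(out)) out$cost <- sprintf("%.2f", out$cost)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
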
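# Event-table IO and end-to-end pipeline orchestration. The canonical event
# format is plain CSV with header event_id,det,E_MeV,t_ns,x_cm,y_cm,z_cm (one
# row per registered gamma); units are fixed (cm, ns, MeV).

.EVENT_COLS <- c("event_id", "det", "E_MeV", "t_ns", "x_cm", "y_cm", "z_cm")

#' Write an event table to CSV
#'
#' @param events Event table `data.frame`.
#' @param path Output path.
#' @export
write_event_table <- function(events, path) {
  stopifnot(all(.EVENT_COLS %in% names(events)))
  write.csv(events[, .EVENT_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate an event table
#'
#' Validates the header and column types, rejects rows with non-finite values
#' (reporting the first offending line), and returns the table sorted by time
#' then event id.
#'
#' @param path CSV path.
#' @return Validated, time-sorted event `data.frame`.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("event table not found: ", path)
  ev <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.EVENT_COLS, names(ev))
  if (length(missing_cols) > 0)
    stop("event table header is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  ev <- ev[, .EVENT_COLS]
  for (cl in .EVENT_COLS) {
    if (!is.numeric(ev[[cl]]))
      stop("event table column '", cl, "' is not numeric")
    bad <- which(!is.finite(ev[[cl]]))
    if (length(bad) > 0)
      stop("non-finite value in column '", cl, "' at data line ", bad[1])
  }
  if (any(ev$E_MeV <= 0)) {
    bad <- which(ev$E_MeV <= 0)[1]
    stop("non-positive energy at data line ", bad)
  }
  ev <- ev[order(ev$t_ns, ev$event_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Write / read the truth sidecar
#'
#' @param truth Truth `data.frame` (`event_id, x_cm, y_cm, z_cm, E0_MeV,
#'   n_detected`).
#' @param path CSV path.
#' @export
write_truth_table <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Run the full pipeline: simulate, reconstruct, fit
#'
#' Executes the event generator, couple selection, torus construction, the
#' all-pairs intersection, and the Gaussian range fit. Fully deterministic
#' given `cfg$seed`. When `out_dir` is given, all intermediate artifacts are
#' written there (events.csv, truth.csv, positions.csv, config.yaml,
#' summary.json), each run stamped with the configuration hash.
#'
#' @param cfg A [pg_config()].
#' @param out_dir Optional output directory.
#' @param quiet Suppress progress messages.
#' @return A `pg_range_result` (see [range_report()]) with an extra `counts`
#'   element carrying the stage-by-stage bookkeeping.
#' @export
run_pipeline <- function(cfg = pg_config(), out_dir = NULL, quiet = TRUE) {
  stopifnot(inherits(cfg, "pg_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  sim <- tryCatch(generate_event_table(cfg), error = function(e)
    stop("generator stage: ", conditionMessage(e), call. = FALSE))
  say("generated %d gammas from %d couples (%d complete)",
      sim$summary$n_detected, sim$summary$n_couples, sim$summary$n_complete)

  windows <- energy_windows(escape_peaks = isTRUE(cfg$escape_peaks))
  couples <- select_couples(sim$events, windows, cfg)
  if (nrow(couples) == 0)
    stop("selection stage: no gamma couples selected", call. = FALSE)
  say("selected %d couples", nrow(couples))

  tori <- couples_to_tori(couples, cfg)
  if (length(tori) < 2)
    stop("couple-analysis stage: fewer than 2 valid tori", call. = FALSE)
  say("built %d tori (%d couples dropped)", length(tori),
      attr(tori, "n_dropped"))

  vps <- reconstruct_virtual_positions(tori, cfg)
  say("stored %d virtual positions (%d null pairs of %d)",
      vps$n_positions, vps$n_nan, vps$n_pairs)

  res <- range_report(vps, cfg)
  res$counts <- list(n_couples_generated = sim$summary$n_couples,
                     n_gammas_detected = sim$summary$n_detected,
                     n_complete_couples = sim$summary$n_complete,
                     n_couples_selected = nrow(couples),
                     n_tori = length(tori),
                     n_couples_dropped_degenerate = attr(tori, "n_dropped"),
                     seed = as.integer(cfg$seed),
                     config_hash = config_hash(cfg))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_event_table(sim$events, file.path(out_dir, "events.csv"))
    write_truth_table(sim$truth, file.path(out_dir, "truth.csv"))
    pos <- as.data.frame(vps$positions)
    names(pos) <- c("x_cm", "y_cm", "z_cm")
    write.csv(pos, file.path(out_dir, "positions.csv"), row.names = FALSE,
              quote = FALSE)
    pg_write_config(cfg, file.path(out_dir, "config.yaml"))
    smry <- c(summary(res), res$counts["config_hash"],
              list(package_version = as.character(utils::packageVersion("pgrange"))))
    jsonlite::write_json(smry, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
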
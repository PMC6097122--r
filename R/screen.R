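#' Run a multi-line dosage screen
#'
#' End-to-end orchestration of the analysis on a mutation-breeding screen:
#' for every line, each replicate's bin counts are converted to RSRC
#' against the control, discretized, and scanned for events; per-line
#' events are then filtered by replicate concordance. A failing line is
#' recorded and skipped; the remaining lines proceed.
#'
#' @param lines A named list; each element is a list of bin-count tibbles
#'   (one per clonal replicate of that line), all on the same grid.
#' @param control A bin-count tibble (`control_mode = "single"`), or
#'   `NULL` with `control_mode = "mean"` to use the mean fraction profile
#'   of all replicates of all lines as a pseudo-control.
#' @param ploidy Baseline ploidy (default 3).
#' @param min_run Minimum run length in bins for an event (default 3).
#' @param control_mode `"single"` or `"mean"`.
#' @param deadband Optional discretization deadband (see [discretize()]).
#' @return An object of class `cnv_screen`: a list with `events` (tibble
#'   of concordant events with a `line` column), `dosage` (named list of
#'   per-replicate dosage tibbles per line), `summary` (per-line event
#'   counts), and `errors` (named character vector of failed lines).
#'   [tidy()][generics::tidy] returns the event table,
#'   [glance()][generics::glance] the one-row screen summary.
#' @examples
#' \donttest{
#' layout <- musa_layout(scale = 0.1)
#' cfg <- sim_config(layout, seed = 3)
#' ctrl <- bin_counts(simulate_sample(cfg, stream = 0), layout, "control")
#' ev <- truth_events("1", 1000001, 1500000, -1)
#' line1 <- lapply(1:2, function(r)
#'   bin_counts(simulate_sample(cfg, ev, r, stream = 10 + r), layout, "L1"))
#' scr <- run_cnv_screen(list(L1 = line1), ctrl)
#' glance(scr)
#' }
#' @export
run_cnv_screen <- function(lines, control = NULL, ploidy = 3L, min_run = 3L,
                           control_mode = c("single", "mean"),
                           deadband = NULL) {
  control_mode <- rlang::arg_match(control_mode)
  if (length(lines) == 0) rlang::abort("`lines` is empty")
  if (is.null(names(lines)) || any(names(lines) == "")) {
    names(lines) <- paste0("line", seq_along(lines))
  }
  if (control_mode == "mean") {
    control <- control_from_mean(purrr::flatten(lines))
  }
  if (is.null(control)) {
    rlang::abort("`control` is required with control_mode = \"single\"")
  }

  errors <- character()
  dosage_by_line <- list()
  events_by_line <- purrr::imap(lines, function(reps, line) {
    tryCatch({
      dts <- purrr::map(reps, rsrc, control = control, ploidy = ploidy)
      dosage_by_line[[line]] <<- dts
      per_rep <- purrr::map(dts, function(dt) {
        call_events(discretize(dt, ploidy = ploidy, deadband = deadband),
                    min_run = min_run)
      })
      concordant_events(per_rep)
    }, error = function(e) {
      errors[[line]] <<- conditionMessage(e)
      NULL
    })
  })
  ok <- !purrr::map_lgl(events_by_line, is.null)
  events <- purrr::imap_dfr(events_by_line[ok], function(ev, line) {
    if (nrow(ev) == 0) return(ev)
    dplyr::mutate(ev, line = line, .before = 1)
  })
  if (nrow(events) == 0) {
    events <- dplyr::mutate(empty_events(), line = character(), .before = 1)
  }
  summary <- tibble::tibble(
    line = names(lines)[ok],
    n_replicates = purrr::map_int(lines[ok], length),
    n_events = purrr::map_int(names(lines)[ok],
                              ~ sum(events$line == .x)),
    has_event = .data$n_events > 0
  )
  structure(
    list(events = events, dosage = dosage_by_line, summary = summary,
         errors = errors, ploidy = as.integer(ploidy),
         min_run = as.integer(min_run)),
    class = "cnv_screen"
  )
}

#' @export
print.cnv_screen <- function(x, ...) {
  cat("CNV dosage screen: ", nrow(x$summary), " line(s), ",
      sum(x$summary$has_event), " with >=1 concordant event, ",
      nrow(x$events), " event(s) total\n", sep = "")
  if (length(x$errors) > 0) {
    cat("failed lines:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cnv_screen <- function(x, ...) {
  x$events
}

#' @export
glance.cnv_screen <- function(x, ...) {
  tibble::tibble(
    n_lines = nrow(x$summary),
    lines_with_events = sum(x$summary$has_event),
    total_events = nrow(x$events),
    n_failed = length(x$errors)
  )
}
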
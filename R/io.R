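#' Trace set container
#'
#' A `fret_trace_set` is a list of `fret_trace` data frames (one immobilized
#' molecule each) sharing a frame interval.
#'
#' @param traces List of `fret_trace` objects.
#' @return A `fret_trace_set`.
#' @export
as_trace_set <- function(traces) {
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, TRUE, "fret_trace")))
  structure(traces, class = "fret_trace_set")
}

#' @export
print.fret_trace_set <- function(x, ...) {
  cat(sprintf("<fret_trace_set: %d molecules, %d frames each (first)>\n",
              length(x), nrow(x[[1L]])))
  invisible(x)
}

#' Write / read a trace cohort as delimited text
#'
#' One comma-delimited file per cohort with header
#' `molecule_id,frame,time_s,laser,ch_donor,ch_acceptor,ch_blue` (`ch_blue`
#' empty for two-color data), plus an optional JSON sidecar holding the
#' ground truth (jump times, bleach frames, injection waits) when the cohort
#' was simulated.
#'
#' @param set A `fret_trace_set`.
#' @param file Path of the CSV trace table.
#' @param truth_file Optional path of the JSON ground-truth sidecar.
#' @return `write_traces` returns `file` invisibly; `read_traces` returns a
#'   `fret_trace_set`.
#' @export
write_traces <- function(set, file, truth_file = NULL) {
  stopifnot(inherits(set, "fret_trace_set"))
  tab <- do.call(rbind, lapply(set, as.data.frame))
  write.csv(tab, file, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_file)) {
    truth <- lapply(set, function(tr) {
      tt <- attr(tr, "truth")
      if (is.null(tt)) return(NULL)
      list(molecule_id = tr$molecule_id[1L],
           jumps = tt$jumps,
           donor_bleach_frame = tt$donor_bleach_frame,
           acceptor_bleach_frame = tt$acceptor_bleach_frame,
           blue_bleach_frame = tt$blue_bleach_frame,
           wait = tt$wait, bind_time = tt$bind_time, stable = tt$stable)
    })
    jsonlite::write_json(
      list(frame_interval = attr(set[[1L]], "frame_interval"),
           molecules = truth),
      truth_file, auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(file)
}

#' @rdname write_traces
#' @export
read_traces <- function(file, truth_file = NULL) {
  tab <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("molecule_id", "frame", "time_s", "laser", "ch_donor",
            "ch_acceptor")
  if (!all(need %in% names(tab))) {
    stop("trace table lacks required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (!"ch_blue" %in% names(tab)) tab$ch_blue <- NA_real_
  truth <- NULL
  if (!is.null(truth_file) && file.exists(truth_file)) {
    truth <- jsonlite::read_json(truth_file, simplifyVector = TRUE)
  }
  ids <- unique(tab$molecule_id)
  traces <- lapply(ids, function(id) {
    tr <- tab[tab$molecule_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    rownames(tr) <- NULL
    dt <- if (nrow(tr) > 1L) median(diff(tr$time_s)) else 0.2
    attr(tr, "frame_interval") <- dt
    if (!is.null(truth) && is.data.frame(truth$molecules)) {
      mols <- truth$molecules
      idx <- which(mols$molecule_id == id)
      if (length(idx) == 1L) {
        tt <- as.list(mols[idx, setdiff(names(mols), "jumps"), drop = FALSE])
        if ("jumps" %in% names(mols)) tt$jumps <- mols$jumps[[idx]]
        attr(tr, "truth") <- tt
      }
    }
    class(tr) <- c("fret_trace", "data.frame")
    tr
  })
  as_trace_set(traces)
}

#' Write FRET trajectories as delimited text
#'
#' Columns `molecule_id, frame, time_s, fret`, one row per retained
#' (pre-photobleach) frame.
#'
#' @param trajs List of `fret_trajectory` objects.
#' @param file Output CSV path.
#' @export
write_fret_trajectories <- function(trajs, file) {
  tab <- do.call(rbind, lapply(trajs, function(tj) {
    data.frame(molecule_id = tj$molecule_id,
               frame = seq_along(tj$fret) - 1L,
               time_s = tj$time_s,
               fret = tj$fret)
  }))
  write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
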
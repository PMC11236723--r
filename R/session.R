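#' Session I/O and pipeline orchestration
#'
#' A session directory holds delimited-text tables sharing one master clock:
#' \code{spikes.csv} (\code{unit_id,trial,t}), \code{head.csv}
#' (\code{t,yaw,pitch,roll}, seconds and degrees), \code{events.csv}
#' (\code{trial,kind,onset,offset,angle,x,y,colour}), optionally
#' \code{eye.csv} (\code{t,x,y}), plus \code{config.csv} (key,value) and
#' \code{ground_truth.csv} when written by the generators.
#'
#' @name session
NULL

#' Write a synthetic session to a directory
#'
#' @param dir output directory (created if missing)
#' @param spikes named list: unit_id -> named list trial -> spike times
#' @param head named list: trial -> [head_trace()]
#' @param events data.frame of stimulus events (with a \code{trial} column)
#' @param eye optional data.frame \code{t,x,y}
#' @param ground_truth optional data.frame
#' @param config named list of analysis parameters/seeds to record
#' @return \code{dir}, invisibly.
#' @export
write_session <- function(dir, spikes, head, events = NULL, eye = NULL,
                          ground_truth = NULL, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- do.call(rbind, lapply(names(spikes), function(u) {
    do.call(rbind, lapply(names(spikes[[u]]), function(tr) {
      st <- spikes[[u]][[tr]]
      if (!length(st)) return(NULL)
      data.frame(unit_id = u, trial = tr, t = st)
    }))
  }))
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  hd <- do.call(rbind, lapply(names(head), function(tr) {
    cbind(trial = tr, as.data.frame(head[[tr]]))
  }))
  utils::write.csv(hd, file.path(dir, "head.csv"), row.names = FALSE)
  if (!is.null(events)) utils::write.csv(events, file.path(dir, "events.csv"), row.names = FALSE)
  if (!is.null(eye)) utils::write.csv(eye, file.path(dir, "eye.csv"), row.names = FALSE)
  if (!is.null(ground_truth)) {
    utils::write.csv(ground_truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  if (length(config)) {
    utils::write.csv(data.frame(key = names(config),
                                value = vapply(config, function(x) paste(x, collapse = ";"), "")),
                     file.path(dir, "config.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Load and validate a session directory
#'
#' @param dir session directory written by [write_session()] (or any
#'   directory with the declared layout)
#' @return list of class \code{session_bundle}: \code{spikes} (list of
#'   [spike_train()]s), \code{head} (list of [head_trace()]s per trial),
#'   \code{events}, \code{eye}, \code{ground_truth}, \code{config}.
#' @export
load_session <- function(dir) {
  need <- file.path(dir, "spikes.csv")
  if (!file.exists(need)) stop("schema error: missing spikes.csv in ", dir)
  sp <- utils::read.csv(need, stringsAsFactors = FALSE)
  for (col in c("unit_id", "trial", "t")) {
    if (!col %in% names(sp)) stop("schema error: spikes.csv lacks column '", col, "'")
  }
  head_path <- file.path(dir, "head.csv")
  head <- NULL
  if (file.exists(head_path)) {
    hd <- utils::read.csv(head_path, stringsAsFactors = FALSE)
    for (col in c("trial", "t", "yaw", "pitch", "roll")) {
      if (!col %in% names(hd)) stop("schema error: head.csv lacks column '", col, "'")
    }
    head <- lapply(split(hd, hd$trial), function(d) {
      head_trace(d$t, d$yaw, d$pitch, d$roll)
    })
  }
  durations <- if (!is.null(head)) {
    vapply(head, function(h) max(h$t) + 1 / attr(h, "fs"), 0)
  } else {
    tapply(sp$t, sp$trial, max) + 1
  }
  spikes <- lapply(split(sp, sp$unit_id), function(d) {
    trials <- lapply(split(d$t, d$trial), function(tt) {
      if (is.unsorted(tt, strictly = TRUE)) stop("schema error: unsorted spike times in spikes.csv")
      tt
    })
    spike_train(d$unit_id[1], trials, durations[names(trials)])
  })
  read_opt <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  structure(list(spikes = spikes, head = head, events = read_opt("events.csv"),
                 eye = read_opt("eye.csv"), ground_truth = read_opt("ground_truth.csv"),
                 config = read_opt("config.csv"), dir = dir),
            class = "session_bundle")
}

#' Run analysis stages on a session bundle
#'
#' Stages: \code{motion} (STA + shuffled-null motion tuning per unit, needs
#' a head trace per trial), \code{visual} (grating selectivity and tuning
#' classification, needs grating events), \code{alignment} (gaze projection
#' of motor STAs vs grating preference, needs both). Results are per-unit
#' tables; the effective thresholds and seeds are recorded alongside.
#'
#' @param bundle a [load_session()] result
#' @param stages subset of \code{c("motion", "visual", "alignment")}
#' @param geometry a [geometry_config()] for the alignment stage
#' @param n_shuffles shuffled-null replicates (default 1000)
#' @param baseline_rate baseline rate (Hz) used to normalize visual
#'   responses; per-unit mean rate when NULL
#' @return list of class \code{pipeline_report}: per-stage tables plus
#'   \code{settings}.
#' @export
run_pipeline <- function(bundle, stages = c("motion", "visual", "alignment"),
                         geometry = geometry_config(), n_shuffles = 1000,
                         baseline_rate = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- list()
  if ("alignment" %in% stages) stages <- union(stages, c("motion", "visual"))
  if ("motion" %in% stages && is.null(bundle$head)) {
    stop("dependency error: motion analysis requested but no head trace in the session")
  }
  units <- names(bundle$spikes)
  if ("motion" %in% stages) {
    rows <- lapply(units, function(u) {
      tr <- bundle$spikes[[u]]
      common <- intersect(names(tr$trials), names(bundle$head))
      stas <- lapply(stats::setNames(nm = common), function(nm) {
        compute_sta(tr$trials[[nm]], bundle$head[[nm]])
      })
      vecs <- t(vapply(stas, sta_displacement_vectors, numeric(3)))
      data.frame(unit_id = u, trial = rownames(vecs),
                 yaw = vecs[, "yaw"], pitch = vecs[, "pitch"], roll = vecs[, "roll"])
    })
    out$motion <- do.call(rbind, rows)
  }
  if ("visual" %in% stages && !is.null(bundle$events) && "angle" %in% names(bundle$events)) {
    ev <- bundle$events[is.finite(bundle$events$angle), ]
    rows <- lapply(units, function(u) {
      tr <- bundle$spikes[[u]]
      st <- sort(unlist(tr$trials, use.names = FALSE))
      br <- if (is.null(baseline_rate)) length(st) / sum(tr$durations) else baseline_rate
      gr <- grating_responses(st, ev, br)
      sel <- tryCatch(selectivity(gr$mean_response, gr$angles, "direction"),
                      error = function(e) list(si = NA_real_, preferred_deg = NA_real_))
      data.frame(unit_id = u, dsi = sel$si, preferred_deg = sel$preferred_deg)
    })
    out$visual <- do.call(rbind, rows)
  }
  out$settings <- list(stages = stages, n_shuffles = n_shuffles,
                       thresholds = c(motion_deg = 5, eye_deg = 1, si = 0.1,
                                      angular_deviation_rad = 0.8, null_rank = 0.95,
                                      rf_z = 2, run_deg_s = 20, saccade_deg_s = 350))
  class(out) <- "pipeline_report"
  out
}

#' Write result tables with a versioned header
#'
#' Each table goes to \code{<out>/<name>.csv} preceded by comment lines
#' recording the package version and a hash of the settings, so identical
#' inputs and seeds reproduce byte-identical outputs.
#'
#' @param report a [run_pipeline()] report (or any named list of data.frames)
#' @param out output directory
#' @return paths of the written files, invisibly.
#' @export
write_results <- function(report, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tabs <- Filter(is.data.frame, report)
  ver <- as.character(utils::packageVersion("collikinetics"))
  cfg_hash <- if (!is.null(report$settings)) {
    sum(utils::head(utf8ToInt(paste(deparse(report$settings), collapse = "")), 10000) *
          seq_len(min(10000, nchar(paste(deparse(report$settings), collapse = ""))))) %% 1e9
  } else 0
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(out, paste0(nm, ".csv"))
    con <- file(p, "w")
    writeLines(c(paste0("# collikinetics ", ver),
                 paste0("# config_hash ", cfg_hash)), con)
    utils::write.csv(tabs[[nm]], con, row.names = FALSE)
    close(con)
    paths <- c(paths, p)
  }
  invisible(paths)
}
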
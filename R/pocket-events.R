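#' Pocket event log container
#'
#' Holds what a trajectory pocket tracker emits per frame: pocket volumes
#' (zero when the pocket was not detected) and merge / split events between
#' ordered pocket pairs.
#'
#' @param pocket_names Character vector of pocket labels.
#' @param volumes `frames x pockets` numeric matrix of volumes in cubic
#'   angstrom; 0 means undetected.
#' @param merges,splits Tibbles with columns `frame`, `from`, `to` (pocket
#'   names), one row per event.
#' @param frame_spacing_ps Frame spacing in picoseconds (default 100).
#' @return An object of class `pocket_event_log`.
#' @export
new_pocket_event_log <- function(pocket_names, volumes, merges, splits,
                                 frame_spacing_ps = 100) {
  pocket_names <- as.character(pocket_names)
  volumes <- as.matrix(volumes)
  if (ncol(volumes) != length(pocket_names)) {
    stop_field("volumes", "must have one column per pocket")
  }
  if (any(volumes < 0)) stop_field("volumes", "volumes must be >= 0")
  colnames(volumes) <- pocket_names
  check_events <- function(ev, field) {
    ev <- tibble::as_tibble(ev)
    if (nrow(ev) == 0) {
      return(tibble::tibble(frame = integer(), from = character(), to = character()))
    }
    if (!all(c("frame", "from", "to") %in% names(ev))) {
      stop_field(field, "needs columns frame, from, to")
    }
    bad <- !(ev$from %in% pocket_names) | !(ev$to %in% pocket_names)
    if (any(bad)) {
      stop_field(field, sprintf("unknown pocket name at frame %d",
                                ev$frame[which(bad)[1]]))
    }
    if (any(ev$from == ev$to)) stop_field(field, "self-pair events are not allowed")
    ev[c("frame", "from", "to")]
  }
  structure(
    list(pocket_names = pocket_names, volumes = volumes,
         merges = check_events(merges, "merges"),
         splits = check_events(splits, "splits"),
         frame_spacing_ps = frame_spacing_ps),
    class = "pocket_event_log"
  )
}

#' @export
print.pocket_event_log <- function(x, ...) {
  cat(sprintf("<pocket_event_log> %d frames, %d pockets (%s), %d merges, %d splits\n",
              nrow(x$volumes), length(x$pocket_names),
              paste(x$pocket_names, collapse = ", "),
              nrow(x$merges), nrow(x$splits)))
  invisible(x)
}

#' Generate a synthetic pocket event stream
#'
#' Per frame, each pocket is detected independently with its presence
#' probability and, when detected, carries a lognormal volume (median
#' `volume_mu`, log-sd `volume_sigma`); undetected pockets have volume 0.
#' Each ordered pocket pair independently emits
#' Poisson(`link_rate`) merge events and Poisson(`link_rate`) split events
#' per frame. Fully deterministic given the spec's seed.
#'
#' @param spec A [pocket_sim_spec()].
#' @return A [new_pocket_event_log()] object.
#' @export
#' @examples
#' log <- gen_pocket_events(pocket_sim_spec(n_frames = 200, seed = 11))
#' time_averaged_volumes(log)
gen_pocket_events <- function(spec) {
  if (!inherits(spec, "pocket_sim_spec")) stop_field("spec", "must be a pocket_sim_spec")
  np <- length(spec$pocket_names)
  nf <- spec$n_frames
  withr::with_seed(spec$seed, {
    present <- matrix(runif(nf * np), nf, np) <
      matrix(spec$presence_prob, nf, np, byrow = TRUE)
    vols <- matrix(0, nf, np)
    for (p in seq_len(np)) {
      idx <- which(present[, p])
      if (length(idx)) {
        vols[idx, p] <- stats::rlnorm(length(idx),
                                      meanlog = log(spec$volume_mu[p]),
                                      sdlog = spec$volume_sigma[p])
      }
    }
    make_events <- function() {
      rows <- list(); r <- 1L
      for (i in seq_len(np)) for (j in seq_len(np)) {
        if (i == j || spec$link_rate[i, j] == 0) next
        counts <- rpois(nf, spec$link_rate[i, j])
        hit <- which(counts > 0)
        if (length(hit)) {
          rows[[r]] <- tibble::tibble(
            frame = rep(hit, counts[hit]),
            from = spec$pocket_names[i],
            to = spec$pocket_names[j]
          )
          r <- r + 1L
        }
      }
      ev <- if (length(rows)) dplyr::arrange(dplyr::bind_rows(rows), .data$frame)
            else tibble::tibble(frame = integer(), from = character(), to = character())
      ev
    }
    merges <- make_events()
    splits <- make_events()
    new_pocket_event_log(spec$pocket_names, vols, merges, splits,
                         frame_spacing_ps = spec$frame_spacing_ps)
  })
}

#' Write / read a pocket event log as JSON
#'
#' The JSON dialect is a list of frame-indexed records
#' `{"frame": f, "volumes": {"ATP": v, ...}, "merges": [["A","B"], ...],
#' "splits": [...]}` plus top-level `pockets` and `frame_spacing_ps`
#' fields.
#'
#' @param log A `pocket_event_log`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); a `pocket_event_log` (reader).
#' @export
write_pocket_events_json <- function(log, path) {
  nf <- nrow(log$volumes)
  pair_list <- function(ev, f) {
    sub <- ev[ev$frame == f, , drop = FALSE]
    if (nrow(sub) == 0) return(list())
    lapply(seq_len(nrow(sub)), function(i) c(sub$from[i], sub$to[i]))
  }
  frames <- lapply(seq_len(nf), function(f) {
    list(frame = f,
         volumes = as.list(log$volumes[f, ]),
         merges = pair_list(log$merges, f),
         splits = pair_list(log$splits, f))
  })
  obj <- list(pockets = log$pocket_names,
              frame_spacing_ps = log$frame_spacing_ps,
              frames = frames)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' @rdname write_pocket_events_json
#' @export
read_pocket_events_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  pockets <- as.character(unlist(obj$pockets))
  nf <- length(obj$frames)
  vols <- matrix(0, nf, length(pockets), dimnames = list(NULL, pockets))
  ev_rows <- function(rec, key) {
    evs <- rec[[key]]
    if (length(evs) == 0) return(NULL)
    tibble::tibble(frame = rec$frame,
                   from = vapply(evs, function(e) as.character(e[[1]]), ""),
                   to = vapply(evs, function(e) as.character(e[[2]]), ""))
  }
  merges <- list(); splits <- list()
  for (k in seq_len(nf)) {
    rec <- obj$frames[[k]]
    v <- unlist(rec$volumes)
    vols[rec$frame, names(v)] <- v
    merges[[k]] <- ev_rows(rec, "merges")
    splits[[k]] <- ev_rows(rec, "splits")
  }
  bind_or_empty <- function(lst) {
    lst <- lst[!vapply(lst, is.null, TRUE)]
    if (length(lst)) dplyr::bind_rows(lst)
    else tibble::tibble(frame = integer(), from = character(), to = character())
  }
  new_pocket_event_log(pockets, vols, bind_or_empty(merges), bind_or_empty(splits),
                       frame_spacing_ps = obj$frame_spacing_ps %||% 100)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
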
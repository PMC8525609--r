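# Shared fixtures and independent oracles.
#
# The march oracle re-derives everything from the raw behavior lists with
# per-second set arithmetic (never through episode_behaviors() or the
# package's interval code), enumerating candidate chains exhaustively and
# checking the four march rules literally.  The CI oracle inverts the
# binomial tails by bisection on pbinom().

# -- small episode builders ---------------------------------------------------

mk_behavior <- function(event_type, label, start, end, parts = list(),
                        quals = list(), postictal = FALSE, note = "") {
  ds_behavior(event_type, label, start, end, body_parts = parts,
              qualifiers = quals, postictal = postictal, note = note)
}

bp <- function(part, side) body_part_ref(part, side)

# one event wrapping the given behaviors, spanning the episode
wrap_episode <- function(..., duration = 60L, flags = ds_flags(), id = "t1",
                         label = NULL) {
  behaviors <- list(...)
  events <- lapply(behaviors, function(b) {
    ds_event(b$event_type, 0L, duration, list(b))
  })
  ds_episode(id, duration, flags = flags, events = events, label = label)
}

# episode holding clonic behaviors only (for march tests)
clonic_episode <- function(specs, duration = 60L) {
  behaviors <- lapply(specs, function(s) {
    ds_behavior("simple_motor", "clonic", s$start, s$end,
                body_parts = list(body_part_ref(s$part, s$side)))
  })
  ds_episode("march", duration,
             events = list(ds_event("simple_motor", 0L, duration, behaviors)))
}

# -- brute-force Jacksonian march oracle --------------------------------------

.oracle_station <- c(face = "face",
                     upper_limb_proximal = "arm_proximal",
                     upper_limb_distal = "arm_distal",
                     hand = "hand", fingers = "fingers",
                     lower_limb_proximal = "leg_proximal",
                     lower_limb_distal = "leg_distal", foot = "foot")

oracle_jacksonian <- function(episode, min_sep = 1L) {
  # raw (side, station, start, end) straight from the nested structure
  raw <- list()
  for (ev in episode$events) {
    for (b in ev$behaviors) {
      if (b$label != "clonic" || isTRUE(b$postictal)) next
      for (part in b$body_parts) {
        st <- .oracle_station[part$part]
        if (is.na(st)) next
        sides <- if (part$side == "bilateral") c("left", "right") else
          if (part$side %in% c("left", "right")) part$side else character(0)
        for (s in sides) {
          raw[[length(raw) + 1L]] <- list(side = s, station = unname(st),
                                          start = b$start_s, end = b$end_s)
        }
      }
    }
  }
  # rule 4: drop intervals exactly synchronous with a contralateral one
  keep <- vapply(raw, function(r) {
    !any(vapply(raw, function(o) {
      o$side != r$side && o$start == r$start && o$end == r$end
    }, FALSE))
  }, FALSE)
  raw <- raw[keep]

  out <- list()
  for (side in c("left", "right")) {
    rs <- Filter(function(r) r$side == side, raw)
    if (!length(rs)) next
    # per-station active-second sets; contiguous runs are candidate steps
    stations <- unique(vapply(rs, `[[`, "", "station"))
    secs <- lapply(stations, function(st) {
      sort(unique(unlist(lapply(
        Filter(function(r) r$station == st, rs),
        function(r) seq.int(r$start, r$end - 1L)))))
    })
    names(secs) <- stations
    steps <- list()
    for (st in stations) {
      v <- secs[[st]]
      run_id <- cumsum(c(1L, diff(v) != 1L))
      for (g in split(v, run_id)) {
        steps[[length(steps) + 1L]] <- list(station = st, secs = g,
                                            onset = g[1L],
                                            end = g[length(g)] + 1L)
      }
    }
    n <- length(steps)
    if (n < 2L) next
    face_secs <- secs[["face"]]
    leg_secs <- sort(unique(unlist(
      secs[intersect(names(secs), c("leg_proximal", "leg_distal", "foot"))])))
    blocking <- intersect(face_secs, leg_secs)

    valid <- list()
    for (mask in seq_len(2^n - 1L)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
      if (length(idx) < 2L) next
      ch <- steps[idx][order(vapply(steps[idx], `[[`, 0L, "onset"))]
      stns <- vapply(ch, `[[`, "", "station")
      if (anyDuplicated(stns)) next
      onsets <- vapply(ch, `[[`, 0L, "onset")
      if (any(diff(onsets) < min_sep)) next
      span <- seq.int(onsets[1L], onsets[length(onsets)] - 1L)
      covered <- sort(unique(unlist(lapply(ch, `[[`, "secs"))))
      if (!all(span %in% covered)) next
      blocked <- any(vapply(blocking, function(m) {
        m >= onsets[1L] && any(onsets > m)
      }, FALSE))
      if (blocked) next
      valid[[length(valid) + 1L]] <- idx
    }
    if (!length(valid)) next
    maximal <- Filter(function(idx) {
      !any(vapply(valid, function(o) length(o) > length(idx) &&
                    all(idx %in% o), FALSE))
    }, valid)
    for (idx in maximal) {
      ch <- steps[idx][order(vapply(steps[idx], `[[`, 0L, "onset"))]
      out[[length(out) + 1L]] <- list(
        side = side,
        station = vapply(ch, `[[`, "", "station"),
        onset = vapply(ch, `[[`, 0L, "onset"),
        end = vapply(ch, `[[`, 0L, "end"))
    }
  }
  out
}

# canonical string form of sequences, for set comparison
march_key <- function(seqs) {
  sort(vapply(seqs, function(s) {
    if (inherits(s, "march_sequence")) {
      paste(s$side, paste(sprintf("%s@%d-%d", s$steps$station, s$steps$start_s,
                                  s$steps$end_s), collapse = ","))
    } else {
      paste(s$side, paste(sprintf("%s@%d-%d", s$station, s$onset, s$end),
                          collapse = ","))
    }
  }, ""))
}

# random small clonic episode for oracle-agreement tests
random_clonic_episode <- function() {
  n <- sample(1:6, 1L)
  parts <- names(.oracle_station)
  specs <- lapply(seq_len(n), function(k) {
    start <- sample(0:15, 1L)
    list(part = sample(parts, 1L),
         side = sample(c("left", "right", "bilateral"), 1L,
                       prob = c(0.4, 0.4, 0.2)),
         start = start, end = start + sample(1:10, 1L))
  })
  clonic_episode(specs, duration = 40L)
}

# -- Clopper-Pearson oracle by tail bisection ---------------------------------

oracle_exact_ci <- function(x, n, level = 0.95, tol = 1e-10) {
  alpha <- 1 - level
  bisect <- function(f, target, lo, hi) {
    # f monotone increasing in p; solve f(p) = target
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) < target) lo <- mid else hi <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    bisect(function(p) stats::pbinom(x - 1L, n, p, lower.tail = FALSE),
           alpha / 2, 0, 1)
  upper <- if (x == n) 1 else
    bisect(function(p) 1 - stats::pbinom(x, n, p), 1 - alpha / 2, 0, 1)
  c(lower = lower, upper = upper)
}
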